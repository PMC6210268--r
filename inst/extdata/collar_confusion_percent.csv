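"",grazing,non_eating,ruminating
grazing,30.06,1.65,0.53
non_eating,0.68,39.16,1.55
ruminating,0.42,2.96,22.98
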