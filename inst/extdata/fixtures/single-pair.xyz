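2
box_xy=7,7 h=12 seed=NA sweep=NA
S 2 2 2
S 2.5 2 2
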