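4
box_xy=7,7 h=12 seed=NA sweep=NA
B1* 1 1 0
B1 1 1 0.5
B1* 1.3 1 0
B1 1.3 1 0.5
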