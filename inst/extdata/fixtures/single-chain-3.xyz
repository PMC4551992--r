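3
box_xy=7,7 h=12 seed=NA sweep=NA
B1* 3 3 0
B1 3 3 0.1
B1 3 3 0.2
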