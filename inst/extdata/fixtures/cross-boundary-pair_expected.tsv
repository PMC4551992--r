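# pair at minimum-image distance 0.2 rc across x
# expected energies in kBT
pair	bond	wall_surface	wall_tip	total
8	0	0	0	8
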