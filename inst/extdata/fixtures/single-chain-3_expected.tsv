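# 3-bead chain, beads 0.1 rc apart, kappa = 100
# expected energies in kBT
pair	bond	wall_surface	wall_tip	total
28.25	1	18.125	0	47.375
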