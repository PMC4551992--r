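# two solvent beads at r = 0.5 rc, far from walls
# expected energies in kBT
pair	bond	wall_surface	wall_tip	total
3.125	0	0	0	3.125
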