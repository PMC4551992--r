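# one solvent bead at zero gap from the surface wall
# expected energies in kBT
pair	bond	wall_surface	wall_tip	total
0	0	12.5	0	12.5
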