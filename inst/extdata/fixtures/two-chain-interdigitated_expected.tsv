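# two 2-bead chains 0.3 rc apart, all pairs in range
# expected energies in kBT
pair	bond	wall_surface	wall_tip	total
22.8452405257735	25	6.25	0	54.0952405257735
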