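locus	class
X_0001	X
X_0002	X
X_0003	X
X_0004	X
rearranged_0001	rearranged
rearranged_0002	rearranged
rearranged_0003	rearranged
rearranged_0004	rearranged
non_rearranged_0001	non_rearranged
non_rearranged_0002	non_rearranged
non_rearranged_0003	non_rearranged
non_rearranged_0004	non_rearranged
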