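individual	taxon	group
a1_1	a1	gA
a1_2	a1	gA
a2_1	a2	gA
a2_2	a2	gA
a3_1	a3	gA
a3_2	a3	gA
a4_1	a4	gA
a4_2	a4	gA
b1_1	b1	gB
b1_2	b1	gB
b2_1	b2	gB
b2_2	b2	gB
b3_1	b3	gB
b3_2	b3	gB
b4_1	b4	gB
b4_2	b4	gB
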