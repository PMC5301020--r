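taxon,char001,char002,char003,char004
a1,i,a,m,m
a2,a,a,a,sm
a3,a,a,a,m
a4,a,a,a,m
b1,a,a,m,sm
b2,a,i,m,m
b3,sm,a,a,sm
b4,a,i,a,m
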