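character	branch	event	from	to
char001	b3	1	a	sm
char001	a1	1	a	i
char002	b4	1	a	sm
char002	b4	2	sm	i
char002	b2	1	a	i
char003	node13	1	a	i
char003	node13	2	i	a
char003	b4	1	a	sm
char003	b4	2	sm	a
char003	node14	1	a	m
char003	b3	1	m	a
char003	a1	1	a	m
char004	node13	1	a	sm
char004	b4	1	sm	m
char004	b2	1	sm	m
char004	node10	1	a	sm
char004	a4	1	sm	a
char004	a4	2	a	m
char004	a3	1	sm	m
char004	a1	1	sm	m
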