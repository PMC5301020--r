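character	hotspot	root_state	n_events
char001	FALSE	a	2.000000
char002	FALSE	a	3.000000
char003	TRUE	a	7.000000
char004	TRUE	a	8.000000
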