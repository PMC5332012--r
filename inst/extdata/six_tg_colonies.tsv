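gene	colonies	insertion_sites	mismatch_repair
Msh6	33	14	TRUE
Msh2	8	4	TRUE
Mlh1	1	1	TRUE
Pms2	1	1	TRUE
Csmd1	2	1	FALSE
Eif1a	2	1	FALSE
none	2	2	FALSE
other	29	1	FALSE
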