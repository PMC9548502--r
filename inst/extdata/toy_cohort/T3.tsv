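junction_aa	v_call	j_call	duplicate_count
CASSLAPGATNEKLFF	TRBV5-1	TRBJ1-4	18
CASSPDRGAYEQYF	TRBV4-1	TRBJ2-7	14
CASSLKQGNTEAFF	TRBV7-9	TRBJ1-1	9
CASSEARTGELFF	TRBV2	TRBJ2-2	7
CASSQDLNTEAFF	TRBV3-1	TRBJ1-1	2
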