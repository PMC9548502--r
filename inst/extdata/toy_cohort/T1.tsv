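junction_aa	v_call	j_call	duplicate_count
CASSLAPGATNEKLFF	TRBV5-1	TRBJ1-4	40
CASSSGGSSYEQYF	TRBV6-2	TRBJ2-7	25
CASSLKQGNTEAFF	TRBV7-9	TRBJ1-1	12
CASRDDWGAFF	TRBV28	TRBJ1-1	8
CASSPTSGTYGYTF	TRBV12-3	TRBJ1-2	5
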