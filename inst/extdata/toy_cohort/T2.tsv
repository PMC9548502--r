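junction_aa	v_call	j_call	duplicate_count
CASSSGGSSYEQYF	TRBV6-2	TRBJ2-7	33
CASSLAPGATNEKLFF	TRBV5-1	TRBJ1-4	20
CASSPDRGAYEQYF	TRBV4-1	TRBJ2-7	15
CASSYQGGDTQYF	TRBV11-2	TRBJ2-3	6
CASSFGREQFF	TRBV27	TRBJ2-1	3
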