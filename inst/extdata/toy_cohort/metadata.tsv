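subject_id	label	stage	ggn	nodule_size_mm	age_years	sex
T1	malignant	I	TRUE	14.5	61.0	F
T2	malignant	I	FALSE	22.0	57.5	M
T3	malignant	II	FALSE	18.0	64.0	M
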