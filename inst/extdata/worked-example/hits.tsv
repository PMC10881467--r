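variant_id	bin	is_sv	ucne	enhancer_state	genes	in_unsolved
v1	ultrarare	FALSE	U2	sustained_adult	GENE1	FALSE
v2	ultrarare	FALSE	U4	marked	GENE3	TRUE
v3	rare	FALSE	U4	marked	GENE3	FALSE
v4	ultrarare	FALSE	U5	open_only	GENE3	TRUE
sv1	ultrarare	TRUE	U4	marked	GENE3	FALSE
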