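variant_id	bin	is_sv	ucne	enhancer_state	genes	in_unsolved	disease_genes
v2	ultrarare	FALSE	U4	marked	GENE3	TRUE	GENE3
v3	rare	FALSE	U4	marked	GENE3	FALSE	GENE3
sv1	ultrarare	TRUE	U4	marked	GENE3	FALSE	GENE3
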