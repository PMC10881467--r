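ucne	gene	tss_distance	tad_consistent
U1	GENE1	9650	TRUE
U2	GENE1	-10000	TRUE
U4	GENE3	19750	TRUE
U5	GENE3	-5000	TRUE
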