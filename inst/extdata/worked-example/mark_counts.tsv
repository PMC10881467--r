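FW13/14	FW15/16	FW18/20	FW23/24	adult	Unique
H3K27ac	1	0	0	0	1	1
H3K27me3	0	0	0	0	0	0
H3K36me3	0	0	0	0	0	0
H3K4me1	1	1	0	0	0	2
H3K4me2	0	0	0	0	0	0
H3K4me3	0	0	0	0	0	0
H3K9/14Ac	0	0	0	0	0	0
H3K9me3	0	0	0	0	0	0
PolII	0	0	0	0	0	0
CTCF	0	0	0	0	0	0
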