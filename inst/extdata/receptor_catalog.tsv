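receptor	family	chain_class	pSTAT1	pSTAT3	pSTAT4	pSTAT5	pSTAT6
gcommon	cytokine_common	common	0	0	0	0.5	0
bcommon	cytokine_common	common	0	0	0	0.5	0
gp130	cytokine_common	common	0	0.5	0	0	0
IL10Rb	cytokine_common	common	0	0.3	0	0	0
IL12Rb1	cytokine_common	common	0	0	0.4	0	0
IFNAR1	cytokine_common	common	0.4	0	0	0	0
IFNAR2	cytokine_private	private	0.6	0.2	0	0	0
TSLPR	cytokine_private	private	0	0	0	0.8	0
IL4Ra	cytokine_private	private	0	0	0	0	0.9
IL2Rb	cytokine_private	private	0	0	0	0.9	0
IL7Ra	cytokine_private	private	0	0	0	0.9	0
IL10Ra	cytokine_private	private	0	0.9	0	0	0
IL17Ra	cytokine_private	private	0	0	0	0	0
IL21Ra	cytokine_private	private	0.1	0.7	0	0	0
IL23Ra	cytokine_private	private	0	0.6	0.3	0	0
IFNLR	cytokine_private	private	0.7	0.2	0	0	0
OX40	tnf_family	non_cytokine	0	0	0	0	0
41BB	tnf_family	non_cytokine	0	0	0	0	0
TNFR1	tnf_family	non_cytokine	0	0	0	0	0
TNFR2	tnf_family	non_cytokine	0	0	0	0	0
CTLA4	checkpoint	non_cytokine	0	0	0	0	0
PDL1	checkpoint	non_cytokine	0	0	0	0	0
cKit	growth_factor	non_cytokine	0	0	0	0	0
IGF1R	growth_factor	non_cytokine	0	0	0	0	0
HER2	growth_factor	non_cytokine	0	0	0	0	0
FGFR	growth_factor	non_cytokine	0	0	0	0	0
EGFR	growth_factor	non_cytokine	0	0	0	0	0
BMPR2	growth_factor	non_cytokine	0	0	0	0	0
ActRII	growth_factor	non_cytokine	0	0	0	0	0
INSR	growth_factor	non_cytokine	0	0	0	0	0
TrkA	growth_factor	non_cytokine	0	0	0	0	0
TGFbR2	growth_factor	non_cytokine	0	0	0	0	0
ALK1	growth_factor	non_cytokine	0	0	0	0	0
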