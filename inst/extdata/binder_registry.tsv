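binder_id	target_receptor	receptor_family	chain_class	length_aa	kd_nM	origin	blocks_native_site
gcommon_bd	gcommon	cytokine_common	common	62	4.2	rosetta	TRUE
bcommon_bd	bcommon	cytokine_common	common	61	17.8	rosetta	FALSE
IFNAR1_bd	IFNAR1	cytokine_common	common	60	8.5	rosetta	TRUE
TSLPR_bd	TSLPR	cytokine_private	private	63	2.9	rosetta	FALSE
IL12Rb1_bd	IL12Rb1	cytokine_common	common	99	44.1	rosetta	FALSE
IFNAR2_bd	IFNAR2	cytokine_private	private	78	12.6	rfdiffusion	FALSE
IL10Rb_bd	IL10Rb	cytokine_common	common	82	61.3	rfdiffusion	FALSE
IL4Ra_bd	IL4Ra	cytokine_private	private	129	23.4	redesigned_agonist	FALSE
IL2Rb_bd	IL2Rb	cytokine_private	private	100	5.7	redesigned_agonist	FALSE
IL7Ra_bd	IL7Ra	cytokine_private	private	64	NA	prior_work	FALSE
IL10Ra_bd	IL10Ra	cytokine_private	private	65	NA	prior_work	FALSE
IL17Ra_bd	IL17Ra	cytokine_private	private	60	NA	prior_work	FALSE
IL21Ra_bd	IL21Ra	cytokine_private	private	66	NA	prior_work	FALSE
IL23Ra_bd	IL23Ra	cytokine_private	private	70	NA	prior_work	FALSE
gp130_bd	gp130	cytokine_common	common	62	NA	prior_work	FALSE
IFNLR_bd	IFNLR	cytokine_private	private	61	NA	prior_work	FALSE
OX40_bd	OX40	tnf_family	non_cytokine	58	NA	prior_work	FALSE
41BB_bd	41BB	tnf_family	non_cytokine	59	NA	prior_work	FALSE
TNFR1_bd	TNFR1	tnf_family	non_cytokine	60	NA	prior_work	FALSE
TNFR2_bd	TNFR2	tnf_family	non_cytokine	60	NA	prior_work	FALSE
CTLA4_bd	CTLA4	checkpoint	non_cytokine	57	NA	prior_work	FALSE
PDL1_bd	PDL1	checkpoint	non_cytokine	57	NA	prior_work	FALSE
cKit_bd	cKit	growth_factor	non_cytokine	65	NA	prior_work	FALSE
IGF1R_bd	IGF1R	growth_factor	non_cytokine	64	NA	prior_work	FALSE
HER2_bd	HER2	growth_factor	non_cytokine	58	NA	prior_work	FALSE
FGFR_bd	FGFR	growth_factor	non_cytokine	63	NA	prior_work	FALSE
EGFR_bd	EGFR	growth_factor	non_cytokine	56	NA	prior_work	FALSE
BMPR2_bd	BMPR2	growth_factor	non_cytokine	62	NA	prior_work	FALSE
ActRII_bd	ActRII	growth_factor	non_cytokine	61	NA	prior_work	FALSE
INSR_bd	INSR	growth_factor	non_cytokine	66	NA	prior_work	FALSE
TrkA_bd	TrkA	growth_factor	non_cytokine	64	NA	prior_work	FALSE
TGFbR2_bd	TGFbR2	growth_factor	non_cytokine	60	NA	prior_work	FALSE
ALK1_bd	ALK1	growth_factor	non_cytokine	59	NA	prior_work	FALSE
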