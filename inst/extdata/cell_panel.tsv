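cell_type	receptor	density
T_CD4	gcommon	3000
T_CD4	bcommon	1000
T_CD4	gp130	2000
T_CD4	IL10Rb	1500
T_CD4	IL12Rb1	1500
T_CD4	IFNAR1	2000
T_CD4	IFNAR2	1500
T_CD4	IL4Ra	1000
T_CD4	IL2Rb	800
T_CD4	IL7Ra	2500
T_CD4	IL10Ra	500
T_CD4	IL17Ra	800
T_CD4	IL21Ra	1000
T_CD4	IL23Ra	600
T_CD4	OX40	500
T_CD4	41BB	300
T_CD4	TNFR1	1000
T_CD4	TNFR2	500
T_CD4	CTLA4	200
T_CD4	TrkA	200
T_CD4	INSR	300
T_CD4	IGF1R	300
T_CD4	BMPR2	200
T_CD4	ActRII	200
T_CD4	TGFbR2	500
T_CD8	gcommon	3000
T_CD8	bcommon	1000
T_CD8	gp130	2000
T_CD8	IL10Rb	1500
T_CD8	IL12Rb1	1500
T_CD8	IFNAR1	2000
T_CD8	IFNAR2	1500
T_CD8	IL4Ra	1000
T_CD8	IL2Rb	2000
T_CD8	IL7Ra	2500
T_CD8	IL10Ra	500
T_CD8	IL17Ra	800
T_CD8	IL21Ra	1000
T_CD8	IL23Ra	600
T_CD8	OX40	300
T_CD8	41BB	500
T_CD8	TNFR1	1000
T_CD8	TNFR2	500
T_CD8	CTLA4	200
T_CD8	TrkA	200
T_CD8	INSR	300
T_CD8	IGF1R	300
T_CD8	BMPR2	200
T_CD8	ActRII	200
T_CD8	TGFbR2	500
NK	gcommon	2500
NK	bcommon	1500
NK	gp130	2000
NK	IL10Rb	1500
NK	IL12Rb1	1500
NK	IFNAR1	2000
NK	IFNAR2	1500
NK	IL4Ra	1000
NK	IL2Rb	2500
NK	IL7Ra	300
NK	IL10Ra	400
NK	IL17Ra	800
NK	IL21Ra	1000
NK	IL23Ra	500
NK	41BB	400
NK	TNFR1	1000
NK	TNFR2	500
NK	cKit	200
NK	INSR	300
NK	IGF1R	300
NK	BMPR2	200
NK	ActRII	200
NK	TGFbR2	500
B	gcommon	2000
B	bcommon	500
B	gp130	2000
B	IL10Rb	1500
B	IL12Rb1	300
B	IFNAR1	2000
B	IFNAR2	1500
B	IL4Ra	1000
B	IL7Ra	400
B	IL10Ra	800
B	IL17Ra	800
B	IL21Ra	2000
B	IFNLR	300
B	TSLPR	300
B	TNFR1	1000
B	PDL1	200
B	INSR	300
B	IGF1R	300
B	BMPR2	200
B	ActRII	200
B	TGFbR2	500
monocyte	gcommon	500
monocyte	bcommon	2000
monocyte	gp130	2000
monocyte	IL10Rb	1500
monocyte	IL12Rb1	200
monocyte	IFNAR1	2000
monocyte	IFNAR2	1500
monocyte	IL4Ra	1000
monocyte	IL10Ra	2000
monocyte	IL17Ra	800
monocyte	IFNLR	200
monocyte	TSLPR	800
monocyte	TNFR1	1000
monocyte	TNFR2	800
monocyte	PDL1	800
monocyte	TrkA	400
monocyte	FGFR	100
monocyte	INSR	300
monocyte	IGF1R	300
monocyte	BMPR2	200
monocyte	ActRII	200
monocyte	TGFbR2	500
DC	gcommon	500
DC	bcommon	1500
DC	gp130	2000
DC	IL10Rb	1500
DC	IL12Rb1	300
DC	IFNAR1	2000
DC	IFNAR2	1500
DC	IL4Ra	1000
DC	IL10Ra	1500
DC	IL17Ra	800
DC	IL21Ra	300
DC	IL23Ra	400
DC	IFNLR	800
DC	TSLPR	1500
DC	TNFR1	1000
DC	PDL1	800
DC	cKit	100
DC	INSR	300
DC	IGF1R	300
DC	BMPR2	200
DC	ActRII	200
DC	TGFbR2	500
U937_like	gcommon	2000
U937_like	bcommon	2000
U937_like	gp130	2000
U937_like	IL10Rb	2000
U937_like	IL12Rb1	2000
U937_like	IFNAR1	2000
U937_like	IFNAR2	2000
U937_like	TSLPR	2000
U937_like	IL4Ra	2000
U937_like	IL2Rb	2000
U937_like	IL7Ra	2000
U937_like	IL10Ra	2000
U937_like	IL17Ra	2000
U937_like	IL21Ra	2000
U937_like	IL23Ra	2000
U937_like	IFNLR	2000
U937_like	OX40	2000
U937_like	41BB	2000
U937_like	TNFR1	2000
U937_like	TNFR2	2000
U937_like	CTLA4	2000
U937_like	PDL1	2000
U937_like	cKit	2000
U937_like	IGF1R	2000
U937_like	HER2	2000
U937_like	FGFR	2000
U937_like	EGFR	2000
U937_like	BMPR2	2000
U937_like	ActRII	2000
U937_like	INSR	2000
U937_like	TrkA	2000
U937_like	TGFbR2	2000
U937_like	ALK1	2000
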