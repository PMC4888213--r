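#oncointerp-kb v1
panel	gene
chpv2_like_hotspot	KRAS
chpv2_like_hotspot	NRAS
chpv2_like_hotspot	BRAF
chpv2_like_hotspot	EGFR
chpv2_like_hotspot	PIK3CA
chpv2_like_hotspot	RET
chpv2_like_hotspot	TP53
chpv2_like_hotspot	APC
chpv2_like_hotspot	AKT1
chpv2_like_hotspot	ALK
chpv2_like_hotspot	CDKN2A
chpv2_like_hotspot	ERBB2
chpv2_like_hotspot	FLT3
chpv2_like_hotspot	KIT
ocp_like	KRAS
ocp_like	NRAS
ocp_like	BRAF
ocp_like	PIK3CA
ocp_like	PTEN
ocp_like	EGFR
ocp_like	TP53
ocp_like	RET
ocp_like	ALK
ocp_like	AKT1
ocp_like	CCND1
ocp_like	CDK4
ocp_like	CDK6
ocp_like	CDKN2A
ocp_like	ERBB2
ocp_like	FGFR1
ocp_like	FLT3
ocp_like	KIT
ocp_like	MTOR
ocp_like	NF1
ocp_like	NF2
ocp_like	RB1
ocp_like	TSC1
ocp_like	ESR1
ocp_like	CTNNB1
f1_like	KRAS
f1_like	NRAS
f1_like	BRAF
f1_like	PIK3CA
f1_like	PTEN
f1_like	EGFR
f1_like	TP53
f1_like	RET
f1_like	ALK
f1_like	AKT1
f1_like	CCND1
f1_like	CDK4
f1_like	CDK6
f1_like	CDKN2A
f1_like	ERBB2
f1_like	FGFR1
f1_like	FLT3
f1_like	KIT
f1_like	MTOR
f1_like	NF1
f1_like	NF2
f1_like	RB1
f1_like	TSC1
f1_like	ESR1
f1_like	CTNNB1
f1_like	APC
f1_like	MAP3K1
f1_like	MAP2K4
f1_like	AXIN1
f1_like	BRCA1
f1_like	BRCA2
f1_like	SMAD4
f1_like	RASA1
f1_like	AKT3
f1_like	CDK1
f1_like	PIK3R1
f1_like	INPP5D
f1_like	INPPL1
f1_like	KDR
f1_like	VHL
f1_like	MAP2K1
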