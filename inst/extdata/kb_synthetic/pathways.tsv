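#oncointerp-kb v1
pathway	gene
WNT	APC
WNT	DKK1
WNT	DKK2
WNT	CSNK1A1
WNT	AXIN1
WNT	CTNNB1
ERK	KRAS
ERK	NRAS
ERK	BRAF
ERK	MAP2K1
ERK	NF1
ERK	RASA1
PI3K_AKT_MTOR	PIK3CA
PI3K_AKT_MTOR	PIK3R1
PI3K_AKT_MTOR	PTEN
PI3K_AKT_MTOR	AKT1
PI3K_AKT_MTOR	AKT3
PI3K_AKT_MTOR	MTOR
PI3K_AKT_MTOR	TSC1
PI3K_AKT_MTOR	NF2
PI3K_AKT_MTOR	INPP5D
PI3K_AKT_MTOR	INPPL1
CELL_CYCLE	CCND1
CELL_CYCLE	CDK4
CELL_CYCLE	CDK6
CELL_CYCLE	CDK1
CELL_CYCLE	CDKN2A
CELL_CYCLE	RB1
RTK	EGFR
RTK	ERBB2
RTK	RET
RTK	ALK
RTK	FLT3
RTK	FGFR1
RTK	KDR
RTK	EREG
RTK	AREG
RTK	KIT
DNA_REPAIR	TP53
DNA_REPAIR	BRCA1
DNA_REPAIR	BRCA2
DNA_REPAIR	ERCC1
DNA_REPAIR	ERCC2
DNA_REPAIR	ERCC5
DNA_REPAIR	XRCC1
DNA_REPAIR	DCLRE1C
JNK_STRESS	MAP3K1
JNK_STRESS	MAP2K4
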