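#oncointerp-kb v1
drug	target	pathway	evidence
vandetanib	RET	-	Strong
cabozantinib	RET	-	Strong
cabozantinib	FLT3	-	Weak
ponatinib	FLT3	-	Weak
quizartinib	FLT3	-	Weak
crizotinib	ALK	-	Moderate
erlotinib	EGFR	-	Moderate
cetuximab	EGFR	-	Moderate
lapatinib	ERBB2	-	Moderate
lucitanib	FGFR1	-	Weak
vemurafenib	BRAF	-	Moderate
dinaciclib	CDK1	-	Weak
everolimus	MTOR	PI3K_AKT_MTOR	Moderate
temsirolimus	MTOR	PI3K_AKT_MTOR	Weak
alpelisib	PIK3CA	PI3K_AKT_MTOR	Moderate
ipatasertib	AKT1	PI3K_AKT_MTOR	Weak
trametinib	MAP2K1	ERK	Moderate
selumetinib	MAP2K1	ERK	Weak
palbociclib	CDK4	CELL_CYCLE	Moderate
ribociclib	CDK6	CELL_CYCLE	Weak
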