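#oncointerp-kb v1
panel	gene
breast_risk	BRCA1
breast_risk	BRCA2
breast_risk	DCLRE1C
breast_risk	TP53
breast_risk	PALB2
breast_risk	ATM
breast_risk	CHEK2
breast_risk	PTEN
breast_risk	STK11
breast_risk	CDH1
breast_risk	BARD1
breast_risk	BRIP1
breast_risk	RAD51C
breast_risk	RAD51D
breast_risk	NBN
breast_risk	NF1
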