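#oncointerp-kb v1
gene	cancer_type
APC	colorectal
KRAS	colorectal
NRAS	colorectal
BRAF	colorectal
PIK3CA	colorectal
PTEN	colorectal
TP53	colorectal
SMAD4	colorectal
AXIN1	colorectal
EGFR	colorectal
TP53	breast
PIK3CA	breast
CCND1	breast
MAP3K1	breast
MAP2K4	breast
PTEN	breast
AKT1	breast
AKT3	breast
ERBB2	breast
FGFR1	breast
BRCA1	breast
BRCA2	breast
NF1	breast
ESR1	breast
RET	MTC
RET	thyroid
BRAF	thyroid
FLT3	leukemia
KIT	leukemia
VHL	renal
NF2	renal
TSC1	renal
EGFR	lung
ALK	lung
KRAS	lung
TP53	pan-cancer
KRAS	pan-cancer
NRAS	pan-cancer
BRAF	pan-cancer
PIK3CA	pan-cancer
PTEN	pan-cancer
CDKN2A	pan-cancer
RB1	pan-cancer
EGFR	pan-cancer
ERBB2	pan-cancer
CCND1	pan-cancer
ALK	pan-cancer
NF1	pan-cancer
NF2	pan-cancer
CTNNB1	pan-cancer
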