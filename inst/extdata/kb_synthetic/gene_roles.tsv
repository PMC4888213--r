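#oncointerp-kb v1
gene	role
APC	tumor_suppressor
KRAS	oncogene
NRAS	oncogene
BRAF	oncogene
PIK3CA	oncogene
PTEN	tumor_suppressor
EGFR	oncogene
TP53	tumor_suppressor
RET	oncogene
CDKN2A	tumor_suppressor
RASA1	tumor_suppressor
RB1	tumor_suppressor
CCND1	oncogene
MAP3K1	tumor_suppressor
MAP2K4	tumor_suppressor
CDK1	oncogene
CDK4	oncogene
CDK6	oncogene
NF1	tumor_suppressor
NF2	tumor_suppressor
FGFR1	oncogene
DKK1	other
DKK2	other
CSNK1A1	other
AXIN1	tumor_suppressor
BRCA1	tumor_suppressor
BRCA2	tumor_suppressor
DCLRE1C	other
EREG	other
AREG	other
AKT1	oncogene
AKT3	oncogene
ERBB2	oncogene
MTOR	oncogene
TSC1	tumor_suppressor
ALK	oncogene
FLT3	oncogene
MAP2K1	oncogene
ERCC1	other
ERCC2	other
ERCC5	other
XRCC1	other
KDR	oncogene
CXCR2	other
INPP5D	tumor_suppressor
INPPL1	tumor_suppressor
PIK3R1	tumor_suppressor
ESR1	oncogene
CTNNB1	oncogene
SMAD4	tumor_suppressor
VHL	tumor_suppressor
KIT	oncogene
DPYD	other
UGT1A1	other
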