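#oncointerp-kb v1
gene	protein_change
KRAS	p.G12V
KRAS	p.G12D
KRAS	p.G12C
KRAS	p.G12S
KRAS	p.G13D
KRAS	p.Q61H
KRAS	p.Q61L
NRAS	p.Q61R
NRAS	p.Q61P
NRAS	p.Q61K
NRAS	p.G12D
NRAS	p.G13R
NRAS	p.N116H
BRAF	p.V600E
PIK3CA	p.E542K
PIK3CA	p.E545K
PIK3CA	p.M1043I
PIK3CA	p.H1047R
RET	p.C634R
RET	p.C634Y
RET	p.M918T
EGFR	p.L858R
EGFR	p.D587H
ALK	p.A1200V
AKT1	p.E17K
TP53	p.R273H
TP53	p.R273C
TP53	p.R248Q
TP53	p.G245S
TP53	p.Y220C
TP53	p.R282W
TP53	p.F270I
TP53	p.P151S
TP53	p.C176F
TP53	p.S127F
TP53	p.S183*
TP53	p.L194R
TP53	p.R213fs
PTEN	p.Q61P
INPP5D	p.S19C
INPPL1	p.R346W
PIK3R1	p.E443K
CDKN2A	p.V82E
DKK1	p.S157F
CSNK1A1	p.D140N
DCLRE1C	p.S635_L636fs
CDK1	p.A100T
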