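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
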