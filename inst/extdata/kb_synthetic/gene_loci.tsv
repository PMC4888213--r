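#oncointerp-kb v1
gene	chrom	start	end	cds_start	protein_len
APC	chr5	112043695	112053224	112044195	2843
KRAS	chr12	25358680	25360247	25359180	189
NRAS	chr1	115247585	115249152	115248085	189
BRAF	chr7	140419627	140422925	140420127	766
PIK3CA	chr3	178866811	178871015	178867311	1068
PTEN	chr10	89623695	89625904	89624195	403
EGFR	chr7	55230751	55235381	55231251	1210
TP53	chr17	7572220	7574399	7572720	393
RET	chr10	43573017	43577359	43573517	1114
CDKN2A	chr9	21968251	21969719	21968751	156
RASA1	chr5	86564205	86568346	86564705	1047
RB1	chr13	48878387	48882171	48878887	928
CCND1	chr11	69456373	69458258	69456873	295
MAP3K1	chr5	56111901	56117437	56112401	1512
MAP2K4	chr17	11924641	11926838	11925141	399
CDK1	chr10	62538519	62540410	62539019	297
CDK4	chr12	58142010	58143919	58142510	303
CDK6	chr7	92234735	92236713	92235235	326
NF1	chr17	29422445	29431899	29422945	2818
NF2	chr22	30000045	30002830	30000545	595
FGFR1	chr8	38269156	38272622	38269656	822
DKK1	chr10	54074556	54076354	54075056	266
DKK2	chr4	107846137	107847914	107846637	259
CSNK1A1	chr5	148880620	148882631	148881120	337
AXIN1	chr16	337940	341526	338440	862
BRCA1	chr17	41196812	41203401	41197312	1863
BRCA2	chr13	32890117	32901371	32890617	3418
DCLRE1C	chr10	14949370	14952446	14949870	692
EREG	chr4	75231359	75232866	75231859	169
AREG	chr4	75311236	75312992	75311736	252
AKT1	chr14	105236186	105238626	105236686	480
AKT3	chr1	243652035	243654472	243652535	479
ERBB2	chr17	37844893	37849658	37845393	1255
MTOR	chr1	11167088	11175735	11167588	2549
TSC1	chr9	135767235	135771727	135767735	1164
ALK	chr2	29416140	29422000	29416640	1620
FLT3	chr13	28577911	28581890	28578411	993
MAP2K1	chr15	66679711	66681890	66680211	393
ERCC1	chr19	45911091	45912982	45911591	297
ERCC2	chr19	45855149	45858429	45855649	760
ERCC5	chr13	103498574	103503132	103499074	1186
XRCC1	chr19	44047964	44050863	44048464	633
KDR	chr4	55945144	55950212	55945644	1356
CXCR2	chr2	219028073	219030153	219028573	360
INPP5D	chr2	233925689	233930253	233926189	1188
INPPL1	chr11	71936556	71941330	71937056	1258
PIK3R1	chr5	67584751	67587923	67585251	724
ESR1	chr6	152012131	152014916	152012631	595
CTNNB1	chr3	41241442	41244785	41241942	781
SMAD4	chr18	48557083	48559739	48557583	552
VHL	chr3	10183819	10185458	10184319	213
KIT	chr4	55524585	55528513	55525085	976
DPYD	chr1	97544081	97548156	97544581	1025
UGT1A1	chr2	234669281	234671880	234669781	533
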