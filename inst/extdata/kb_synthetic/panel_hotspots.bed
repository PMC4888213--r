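chr12	25359212	25359218	chpv2_like_hotspot|KRAS
chr12	25359359	25359362	chpv2_like_hotspot|KRAS
chr1	115248117	115248123	chpv2_like_hotspot|NRAS
chr1	115248264	115248267	chpv2_like_hotspot|NRAS
chr7	140421923	140421926	chpv2_like_hotspot|BRAF
chr7	55233404	55233407	chpv2_like_hotspot|EGFR
chr7	55233485	55233500	chpv2_like_hotspot|EGFR
chr7	55233617	55233620	chpv2_like_hotspot|EGFR
chr7	55233821	55233833	chpv2_like_hotspot|EGFR
chr3	178868933	178868948	chpv2_like_hotspot|PIK3CA
chr3	178870436	178870451	chpv2_like_hotspot|PIK3CA
chr10	43575415	43575418	chpv2_like_hotspot|RET
chr10	43576267	43576270	chpv2_like_hotspot|RET
chr17	7572719	7573898	chpv2_like_hotspot|TP53
chr5	112047941	112048544	chpv2_like_hotspot|APC
chr14	105236733	105236736	chpv2_like_hotspot|AKT1
chr2	29420158	29420464	chpv2_like_hotspot|ALK
chr9	21968750	21969218	chpv2_like_hotspot|CDKN2A
chr17	37847654	37847735	chpv2_like_hotspot|ERBB2
chr13	28580912	28580915	chpv2_like_hotspot|FLT3
chr4	55527529	55527532	chpv2_like_hotspot|KIT
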