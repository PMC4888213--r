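#oncointerp-kb v1
rule_id	drug	drug_tier	cancer_type	predicate	effect	evidence
DR001	cetuximab	1	colorectal	KRAS somatic_activating	lack_of_benefit	Definitive
DR002	panitumumab	1	colorectal	KRAS somatic_activating	lack_of_benefit	Definitive
DR003	cetuximab	1	colorectal	NRAS somatic_activating	lack_of_benefit	Strong
DR004	panitumumab	1	colorectal	NRAS somatic_activating	lack_of_benefit	Strong
DR005	cetuximab	1	colorectal	BRAF somatic_activating	lack_of_benefit	Strong
DR006	panitumumab	1	colorectal	BRAF somatic_activating	lack_of_benefit	Strong
DR007	cetuximab	1	colorectal	EREG expression_high AND AREG expression_high	benefit	Moderate
DR008	panitumumab	1	colorectal	EREG expression_high AND AREG expression_high	benefit	Moderate
DR009	cetuximab	1	colorectal	PIK3CA somatic_activating	lack_of_benefit	Weak
DR010	cetuximab	1	colorectal	PTEN somatic_inactivating OR PTEN cna_loss	lack_of_benefit	Weak
DR011	cetuximab	1	colorectal	EGFR somatic_activating	benefit	Weak
DR012	vandetanib	1	MTC	RET somatic_activating OR RET germline_variant	benefit	Definitive
DR013	cabozantinib	1	MTC	RET somatic_activating OR RET germline_variant	benefit	Definitive
DR014	trastuzumab	1	breast	ERBB2 cna_gain OR ERBB2 expression_high	benefit	Definitive
DR015	tamoxifen	1	breast	ESR1 expression_high	benefit	Strong
DR016	oxaliplatin	1	any	ERCC1 germline_variant	lack_of_benefit	Weak
DR017	oxaliplatin	1	any	ERCC2 germline_variant	benefit	Weak
DR018	oxaliplatin	1	any	ERCC5 germline_variant	benefit	Weak
DR019	oxaliplatin	1	any	XRCC1 germline_variant	lack_of_benefit	Weak
DR020	bevacizumab	1	any	KDR germline_variant	benefit	Weak
DR021	bevacizumab	1	any	CXCR2 germline_variant	benefit	Weak
DR022	cisplatin	2	breast	BRCA1 germline_variant OR BRCA2 germline_variant	benefit	Strong
DR023	erlotinib	2	any	EGFR specific_protein_change p.L858R	sensitivity	Strong
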