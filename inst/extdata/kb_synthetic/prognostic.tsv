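#oncointerp-kb v1
marker_id	cancer_type	predicate	direction	note
PG001	colorectal	BRAF somatic_activating	unfavorable	BRAF-activated colorectal cancers show poorer survival
PG002	colorectal	TP53 somatic_inactivating	unfavorable	TP53 loss is associated with metastatic progression
PG003	breast	ESR1 expression_high	favorable	ER-positive tumors respond to endocrine therapy
PG004	breast	CCND1 cna_gain	unfavorable	CCND1 amplification is linked to endocrine resistance
PG005	MTC	RET specific_protein_change p.M918T	unfavorable	RET M918T defines aggressive medullary thyroid carcinoma
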