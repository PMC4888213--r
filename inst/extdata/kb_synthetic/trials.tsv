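#oncointerp-kb v1
trial_id	title	predicate	cancer_types	open	location
NCT-SYN-0001	CDK4/6 inhibitor in CCND1-amplified breast cancer	CCND1 cna_gain	breast	TRUE	New York NY
NCT-SYN-0002	AKT inhibitor basket for PI3K-pathway-activated tumors	PIK3CA somatic_activating OR PTEN somatic_inactivating OR PTEN cna_loss	any	TRUE	Boston MA
NCT-SYN-0003	FGFR inhibitor in FGFR1-amplified tumors	FGFR1 cna_gain	any	FALSE	Houston TX
NCT-SYN-0004	CDK1 inhibitor in CDK1-amplified tumors	CDK1 cna_gain	any	TRUE	Chicago IL
NCT-SYN-0005	MEK inhibitor in NRAS-altered tumors	NRAS somatic_activating OR NRAS cna_gain	any	TRUE	Baltimore MD
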