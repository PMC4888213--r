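#oncointerp-kb v1
rule_id	drug	predicate	outcome
TX001	fluorouracil	DPYD germline_variant	Severe Toxicity
TX002	irinotecan	UGT1A1 germline_variant	Elevated Toxicity
TX003	oxaliplatin	ERCC1 germline_variant	Elevated Toxicity
TX004	oxaliplatin	XRCC1 germline_variant	Less Toxicity
TX005	cisplatin	ERCC2 germline_variant	Elevated Toxicity
TX006	vandetanib	KDR germline_variant	Elevated Toxicity
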