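#oncointerp-kb v1
panel	mode	detects_germline	detects_expression
chpv2_like_hotspot	hotspot	FALSE	FALSE
ocp_like	full_gene_plus_cna	FALSE	FALSE
f1_like	full_gene_plus_cna	FALSE	FALSE
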