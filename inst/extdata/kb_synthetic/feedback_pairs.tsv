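#oncointerp-kb v1
pathway_a	pathway_b	drug_a	drug_b	note
PI3K_AKT_MTOR	ERK	everolimus	trametinib	PI3K and ERK cross-inhibition feedback loop
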