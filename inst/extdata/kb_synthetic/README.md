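# Synthetic mini knowledge base

All tables in this directory are SYNTHETIC stand-ins constructed for the
oncointerp package: the institutional curation they emulate (tier gene
lists, drug/toxicity/prognostic rules, trial records, panel contents,
risk-gene screens) is unpublished. Panel definitions are approximate
renderings based on publicly described panel designs, not the commercial
products. Gene loci are synthetic-but-stable coordinates used by the
fixture and generator code; they are not a genome annotation.

Format: TSV with a '#oncointerp-kb v1' first line; hotspot intervals in
BED (0-based half-open).
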