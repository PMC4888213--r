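# oncointerp

Integrative interpretation of tumor genomic profiles for personalized cancer
therapy. oncointerp takes what a molecular tumor board works from — a
patient's somatic and germline variant calls (VCF), copy-number segments
(log2 ratio + mirrored BAF), and gene-expression tables — and produces what
the board needs to decide: a tiered somatic mutation list, evidence-ranked
drug-response predictions, toxicity and prognosis calls, pathway perturbation
summaries, clinical-trial matches, an actionable-alteration tally, and a
structured per-patient findings document (JSON + markdown). It also
quantifies what a broad integrative assay adds over targeted panels via
in-silico panel restriction, and ships cohort statistics (mutation spectrum,
mutations/Mb, purity from allelic fractions, cross-platform CNA concordance)
plus a seeded synthetic-cohort generator so every stage is testable offline.

It is written for bioinformaticians building or evaluating clinical
interpretation pipelines; the packaged knowledge base is a **synthetic
miniature** (see `inst/extdata/kb_synthetic/README.md`) — swap in your own
curation for real use.

## The methods in brief

* **Mutation tiers.** Somatic mutations fall into five tiers by a
  first-match-wins cascade: tier 1 — gene curated for the patient's cancer
  type; tier 2 — pan-cancer gene; tier 3 — gene curated for other cancers;
  tier 4 — exact (gene, protein change) previously catalogued in tumors with
  no known cancer association for the gene; tier 5 — the rest. Tiers 1–4 are
  "cancer-relevant".
* **Drug response.** Per tier-1 drug, biomarker rules are walked in strict
  evidence order (Definitive > Strong > Moderate > Weak); the first level
  with a match fixes the call — e.g. an activating KRAS mutation in
  colorectal cancer yields *lack of benefit* for cetuximab/panitumumab at
  Definitive evidence. Tier-2 therapies come from drug-target and
  pathway-activation mapping (PTEN loss ⇒ AKT/mTOR-axis sensitivity).
* **Actionability.** An alteration is actionable if it supports any tier-1
  or tier-2 recommendation; counting unit is gene × source
  (somatic / CNA / germline / expression).
* **Statistics.** Six-class pyrimidine-convention substitution spectrum
  (C>A, C>G, C>T, T>A, T>C, T>G); mutations/Mb over the coding target;
  purity = min(1, 2 × median of the upper allelic-fraction cluster) under a
  diploid-heterozygous model; cross-platform CNA concordance as the
  partition-length-weighted Pearson correlation on the break-union genome
  partition, with Kolmogorov–Smirnov group comparisons.

The methods vignette (`vignettes/interpretation-methods.Rmd`) documents every
model, default and design decision.

## Worked example

The packaged fixtures encode the study cohorts. Interpreting one colorectal
patient:

```r
library(oncointerp)
kb <- load_kb(default_kb_dir())
fx <- table_fixtures()

p <- fx$colorectal[[1]]        # patient P0004
res <- interpret_patient(p, kb)
write_tiered_tsv(res$tiered, p$patient_id, kb)
#>   patient   gene protein_change tier                      gene_function
#> 1   P0004    APC        p.E763*    1 tumor_suppressor; cancer-type gene
#> 2   P0004   KRAS         p.G12V    1         oncogene; cancer-type gene
#> 3   P0004 PIK3CA        p.E545K    1         oncogene; cancer-type gene
#> 4   P0004 PIK3CA       p.M1043I    1         oncogene; cancer-type gene

res$tier1[res$tier1$effect != "no_prediction",
          c("drug", "effect", "evidence")]
#>          drug          effect   evidence
#> 2   cetuximab lack_of_benefit Definitive
#> 4 panitumumab lack_of_benefit Definitive

res$actionability
#> <actionability_report> P0004: 2 actionable (somatic 2, cna 0, germline 0,
#>   expression 0); tier1=TRUE tier2=TRUE
```

All four mutations are tier 1 (APC, KRAS, PIK3CA are curated colorectal
genes). The activating KRAS p.G12V fires the Definitive anti-EGFR
lack-of-benefit rule; the activating PIK3CA mutations activate the
PI3K–AKT–mTOR pathway, so tier-2 recommendations include alpelisib and
everolimus, and the KRAS lesion adds MEK-inhibitor options plus a
curated-feedback-loop combination (`everolimus + trametinib`). The findings
document renders the same content deterministically:

```r
doc <- generate_findings(p, res, kb, seed = 1)
cat(head(findings_to_markdown(doc), 8), sep = "\n")
#> # Genomic findings: P0004
#> Cancer type: colorectal
#>
#> ## Somatic mutations (tiers 1-4)
#> - tier 1: APC p.E763* (tumor_suppressor; WNT)
#> - tier 1: KRAS p.G12V (oncogene; ERK)
#> - tier 1: PIK3CA p.E545K (oncogene; PI3K_AKT_MTOR)
#> - tier 1: PIK3CA p.M1043I (oncogene; PI3K_AKT_MTOR)
```

A command-line wrapper ships at `inst/cli/oncointerp.R`
(`interpret`, `compare-panels`, `stats`, `concordance`, `simulate`), e.g.:

```sh
Rscript inst/cli/oncointerp.R simulate --seed 7 --out cohort/
Rscript inst/cli/oncointerp.R interpret --profile cohort/SYN0001 \
    --kb inst/extdata/kb_synthetic --out findings/ --seed 7
```

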