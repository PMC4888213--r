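---
title: "Methods: integrative interpretation of tumor genomic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative interpretation of tumor genomic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncointerp)
```

oncointerp turns a patient's somatic and germline variant calls, copy-number
segments and gene-expression measurements into a structured clinical findings
document: a tiered somatic mutation list, evidence-ranked drug-response
predictions, toxicity and prognosis calls, pathway perturbation summaries,
clinical-trial matches and an actionable-alteration tally. This vignette
describes the models and procedures, the parameters that matter, and the
design decisions taken where the underlying methodology left choices open.

## The mutation tier system

Somatic mutations are assigned to five tiers by a first-match-wins cascade
over the knowledge base's gene-cancer associations:

1. **Tier 1** — gene curated for the patient's own cancer type;
2. **Tier 2** — pan-cancer gene, not already tier 1;
3. **Tier 3** — gene curated for other cancer types, excluding tiers 1-2;
4. **Tier 4** — exact (gene, protein change) pair present in a catalog of
   previously observed tumor mutations, where the gene has no cancer
   association at all;
5. **Tier 5** — everything else.

Tiers 1-4 together define *cancer-relevant* mutations. Because each rule
excludes the previous ones, the tiers partition any input set, and adding a
gene to a cancer-type list can only lower (improve) tier numbers — both
properties are asserted in the test suite. Tier-4 matching requires an exact
protein-change string after stripping isoform qualifiers; a variant without a
protein change never matches the catalog (matching by genomic coordinate was
considered and rejected as overly permissive for a catalog keyed on protein
changes). A cancer type outside the controlled vocabulary triggers a warning
and the pan-cancer fallback, making tier 1 impossible rather than guessing.

## Drug response: the evidence-hierarchy decision tree

Therapies are split per cancer type into **tier 1** (approved for the tumor
type) and **tier 2** (everything else, including investigational agents).
Each tier-1 drug is evaluated by walking its biomarker rules strictly in
evidence order — Definitive > Strong > Moderate > Weak — and stopping at the
first level with at least one matching rule; that level fixes the predicted
effect and its evidence label, and lower levels are never consulted (the
"evidence short-circuit", property-tested by injecting conflicting Weak
rules). Two numerical conventions:

* **Conflicts within a level** (one rule predicting benefit, another
  lack-of-benefit) resolve to the negative call — a conservative clinical
  default, since the source methodology does not state a tie rule.
* **Supporting alterations** are every alteration matched at the deciding
  level, regardless of which side of a conflict they supported: all of them
  informed the prediction, and all of them count as actionable.

Biomarker predicates are a small declarative grammar stored as text in the
knowledge-base tables (`GENE class [arg]`, conjunction with `AND`,
alternatives with `OR`), so decision trees remain data, not code. Whether a
somatic change is *activating* is resolved from a curated per-gene list of
activating changes plus a fallback (oncogene with a catalogued change is
activating; tumor suppressor with a truncating — nonsense, frameshift,
splice — or catalogued change is inactivating).

Tier-2 recommendations come from three routes: explicit tier-2 rules
(evaluated through the same hierarchy), direct target mapping (an activating
lesion in a druggable target recommends drugs targeting it), and pathway
mapping (an activated signaling cascade recommends drugs targeting its
nodes). A pathway counts as activated when an oncogene member carries an
activating lesion or a tumor-suppressor member an inactivating one. Receptor
collections are deliberately excluded from the pathway route (their drugs are
direct-target only), so an EGFR mutation does not recommend an ALK inhibitor.
Combination recommendations arise only from a curated feedback-loop pair
table or from two independently activated pathways, each contributing its
alphabetically first drug — the source methodology gives no general
combination algorithm, so the rule is intentionally minimal and explicit.

**Actionability** counts gene x source units (somatic, CNA, germline,
expression): a gene contributes at most once per source, across all non-empty
tier-1 predictions and all tier-2 recommendations. Germline variants that
only modulate chemotherapy efficacy or toxicity (nucleotide-excision-repair
and angiogenesis polymorphisms) are encoded as Weak rules on broadly approved
tier-1 drugs and therefore enter the actionable tally.

## Toxicity and prognosis

Toxicity prediction evaluates all rules for a drug and reports the most
severe matching class (Severe Toxicity > Elevated Toxicity > Normal > Less
Toxicity); no match defaults to Normal with no supporting variants. The
most-severe-wins aggregation is a safety-biased choice made here — the four
classes are given by the methodology, the multi-match rule is not. One
consequence: a protective (Less Toxicity) marker is masked by any concurrent
Elevated/Severe marker, so mixed outputs cannot occur. Prognostic biomarkers
are matched per cancer type and all matches are reported without
aggregation, including contradictory directions.

## Cohort and tumor statistics

* **Mutation frequency per Mb** counts non-synonymous SNVs and canonical
  splice-site SNVs affecting canonical isoforms, divided by the coding
  territory of the capture design. The denominator is a configuration value
  (default 30 Mb) because capture designs differ; substitute the actual
  design territory when known.
* **Substitution spectrum** uses the six pyrimidine-convention classes (C>A,
  C>G, C>T, T>A, T>C, T>G); purine-reference pairs are reverse-complemented.
  Indels are excluded from the denominator.
* **Tumor purity** is estimated under a diploid-heterozygous model: a clonal
  variant has expected allelic fraction purity/2, so purity =
  min(1, 2 x median of the upper AF cluster), the clusters found by an exact
  1-D two-cluster split minimizing within-cluster sum of squares. Estimates
  below 5% raise a low-purity flag; fewer than 10 AFs flag the estimate
  unreliable. On unimodal AF distributions the forced split biases the
  estimate upward by roughly half a standard deviation of the AF noise
  (about +0.06 at purity 0.6 and depth 100), which is well inside the
  +/-0.1 recovery tolerance used in the tests; this estimator is a documented
  stand-in with the same decision outputs (notably the <5% flag) as the
  original unavailable procedure.
* **Cross-platform CNA concordance** partitions the genome on the break
  union of the two segmentations (via `IRanges::disjoin`), so each partition
  overlaps exactly one segment per platform, then computes the
  partition-length-weighted Pearson correlation (`boot::corr`) of the
  per-partition log2ratio values, and likewise for log2mBAF. Normal and
  undecided segments are included. Zero variance on either side is reported
  as NA with a warning rather than a fabricated value. Group comparisons
  (e.g. FFPE- vs frozen-derived correlation distributions) use the two-sided
  two-sample Kolmogorov-Smirnov test from `stats::ks.test`.
* **Expression levels** are quantile calls against a reference distribution
  (defaults 0.25/0.75); values exactly on a bound are intermediate. Fold
  changes are tumor/normal with an optional pseudocount (off by default;
  a zero or negative normal value without a pseudocount is an error).
* **Intrinsic subtype** is a nearest-centroid call by Spearman correlation
  over shared signature genes — the common practice for centroid-based
  expression classifiers; at least half the signature must be present, and
  ties break to the first declared label with a warning. The packaged
  centroid matrix is synthetic (fixed seed), standing in for published
  centroids.

## In-silico panel comparison

`panel_filter()` restricts a profile to what a targeted panel would see:
hotspot panels keep somatic SNV/indels inside hotspot intervals; full-gene
panels keep somatic variants in panel genes; full-gene-plus-CNA panels also
keep gain/loss segments overlapping panel genes. Germline variants survive
only germline-reporting panels and expression survives none (DNA panels).
`summarize_cohort()` reruns tiering and the full therapy engine on each
restricted profile with the *same* knowledge base — detection breadth is the
only variable being compared. Mutations, not genes, are counted in the
cancer-relevant tallies. The packaged panel definitions are approximate,
editable renderings of publicly described commercial designs and are labelled
synthetic; fold changes against them are structural statements (restriction
can only lose alterations, so every fold change is >= 1), not product
benchmarks.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of the study cohorts:

* cancer-type mixture 19/46 colorectal, 7/46 breast, 5/46 MTC, 15/46 other;
* per-gene driver frequencies equal to the published per-cohort alteration
  tables (e.g. APC 0.89 and TP53 0.84 in colorectal; RET in every MTC);
* germline pharmacogenomic polymorphism frequencies of 0.37 across six genes,
  so the expected actionable germline count is about 2.2 per patient;
* passenger SNVs as a Poisson process at the published per-type medians
  (2.7, 1.4, 0.7 mutations/Mb for colorectal, breast, MTC; 2.0 otherwise)
  over a 30 Mb target, with substitution classes drawn from configurable
  six-class spectrum weights (default dominated by C>T transitions, as in
  the real cohorts);
* a quarter of passengers fall in curated cancer genes, which puts the
  expected cancer-relevant mutation count per patient in the high teens;
* allelic fractions follow purity/2 with binomial noise at a
  negative-binomial depth (default mean 112x, the tumor WES median), purity
  drawn uniformly from 0.2-0.9;
* optional per-source actionable-event rates, translated into independent
  Bernoulli draws over per-type menus of individually actionable gene x
  source units.

All randomness flows from one mandatory seed; identical configurations
produce identical cohorts, and cohorts round-trip exactly through the
package's VCF/TSV writers and readers. Genomic coordinates are synthetic but
stable (codon c of a gene sits at `cds_start + 3*(c-1)`), with the EGFR
anchor chosen so the case-study codon lands on its printed coordinate, and
hotspot-panel intervals placed over the classic hotspot codons.

What the generator deliberately does **not** model: trinucleotide mutational
context (only the six-class spectrum), subclonal population structure (all
variants are clonal at purity/2), FFPE artifacts, read-level errors,
correlated co-occurrence or mutual exclusivity between drivers (all draws are
independent Bernoulli), fusions, and real genome annotation. Passing tests
therefore demonstrate the correctness of the interpretation machinery under
these idealized conditions, not calling performance on real sequencing data.

## Encoding of the published per-patient tables

The colorectal table's rendered text has ambiguous column boundaries for two
patients. The per-gene frequency row was taken as the authoritative
constraint, which admits exactly one consistent assignment: the double entry
splits into NRAS p.N116H and PTEN p.Q61P (column-order reading), one
patient's "Gain" is an EGFR copy gain, and another patient carries an APC
copy loss plus a PTEN splice-donor mutation — the latter consistent with the
narrative that PTEN loss predicted PI3K-pathway activation in that patient.
Fixture protein changes for alterations the tables name only generically
(e.g. "NF1 mutation") are invented truncating changes, marked as synthetic
choices.

## Assay selection and other conventions

The gDNA-mass rules run the targeted panel always, add WES when both normal
and tumor masses are >= 1.5 ug, and add the SNP array when both exceed
2.5 ug (the published brackets overlap at 2.5 ug; the closed upper bracket
went to the middle band). Tumor RNA-Seq requires frozen tumor; adjacent
normal RNA-Seq additionally requires frozen adjacent normal. Coordinates are
1-based inclusive everywhere internally (VCF convention); BED input is
converted on read. Gene symbols are upper-cased and matched exactly.
Variants whose FILTER is neither PASS nor "." are dropped on read by default
(they correspond to calls rejected in manual review), with `keep_filtered`
to retain them. Drugs with no matching rule are reported with
`no_prediction` and listed in the findings document rather than suppressed,
so the reader can distinguish "no biomarker-based prediction" from "not
evaluated". Vandetanib and cabozantinib are encoded as tier-1 drugs for MTC
(they are approved for that tumor type), so RET-driven recommendations for
MTC patients arrive through the tier-1 decision tree; in other cancer types
the same drugs surface through the tier-2 target route.

## Findings documents

`generate_findings()` assembles the per-patient document with deterministic
ordering (mutations by tier then gene; drugs tier 1 before tier 2, evidence
descending), a provenance block (KB version, input checksum, seed) and an
explicit "no clinically relevant results" banner when every section is
empty. JSON is the source of truth; the markdown rendering regenerates from
the JSON alone. The JSON is checked against a shipped structural schema
(required sections and types) by `validate_findings()` — a lightweight
structural check, not a full JSON-Schema validator. Section order is fixed;
a per-cancer-type section template was considered and deferred since the
document consumers here are programmatic.

## Problem sizes and tolerances used in the tests

Property tests use seeded cohorts of 3-12 patients (100 cohorts for the
panel-restriction invariant), 1900 patients for binomial recovery of the
colorectal frequency row, 500 SNVs for spectrum recovery at 3-sigma binomial
bounds, 200 mutations at depth 100 for purity recovery within +/-0.1, and
400 patients for actionable-rate recovery within 10%. Numerical identities
(weighted correlation against the direct formula, KS D against the maximal
ECDF gap, partitions against a brute-force boundary union) are asserted at
1e-12. These sizes keep the full suite within a couple of minutes on one
core while leaving comfortable statistical margins.

## Known limitations

The packaged knowledge base is a synthetic miniature: real clinical use
requires institution-grade curation, and absolute cohort-level numbers
(mean cancer-relevant or actionable alterations) depend on that curation
depth — only the structural properties (restriction inequalities, evidence
short-circuit, tier partition, parameter recovery) are portable claims.
Activating/inactivating resolution is list-driven with a coarse fallback and
has no pathogenicity scores. Trial matching is local-table lookup, not a
registry connection. The purity estimator assumes diploid heterozygosity and
will be biased in highly aneuploid tumors.
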