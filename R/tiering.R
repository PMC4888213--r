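# Five-tier cancer-relevance classification of somatic mutations.
# Tier 1: gene curated for the patient's cancer type. Tier 2: pan-cancer gene
# not in tier 1. Tier 3: gene curated for other cancers, excluding tiers 1-2.
# Tier 4: exact (gene, protein change) previously catalogued in tumors where
# the gene has no known cancer association. Tier 5: everything else.
# Tiers 1-4 are "cancer-relevant".

TIER_RATIONALES <- c("cancer-type gene", "pan-cancer gene", "other-cancer gene",
                     "catalog match", "none")

#' Assign cancer-relevance tiers to somatic mutations
#'
#' The first matching rule in tier order wins, so the five tiers partition any
#' input set. An unknown cancer type triggers a warning and the pan-cancer
#' fallback (tier 1 becomes impossible).
#'
#' @param variants a `somatic_variants` table
#' @param cancer_type the patient's cancer-type label
#' @param kb a `knowledge_base`
#' @return the input with `tier` (integer 1-5) and `rationale` columns added,
#'   class `tiered_mutations`
#' @export
tier_mutations <- function(variants, cancer_type, kb) {
  if (!is_known_cancer_type(cancer_type)) {
    warnf("cancer type '%s' not in controlled vocabulary; tier 1 impossible, evaluating pan-cancer lists only",
          cancer_type)
  }
  n <- nrow(variants)
  tier <- rep(5L, n)
  rationale <- rep("none", n)
  if (n > 0) {
    assoc <- kb$gene_cancer
    type_genes <- assoc$gene[assoc$cancer_type == cancer_type]
    pan_genes <- assoc$gene[assoc$cancer_type == "pan-cancer"]
    other_genes <- setdiff(assoc$gene, c(type_genes, pan_genes))
    any_assoc <- unique(assoc$gene)

    pc <- normalize_protein_change(variants$protein_change)
    in_catalog <- paste(variants$gene, pc) %in%
      paste(kb$catalog$gene, kb$catalog$protein_change) & nzchar(pc)

    t1 <- variants$gene %in% type_genes
    t2 <- !t1 & variants$gene %in% pan_genes
    t3 <- !t1 & !t2 & variants$gene %in% other_genes
    t4 <- !t1 & !t2 & !t3 & in_catalog & !(variants$gene %in% any_assoc)
    tier[t4] <- 4L; rationale[t4] <- "catalog match"
    tier[t3] <- 3L; rationale[t3] <- "other-cancer gene"
    tier[t2] <- 2L; rationale[t2] <- "pan-cancer gene"
    tier[t1] <- 1L; rationale[t1] <- "cancer-type gene"
  }
  out <- variants
  out$tier <- tier
  out$rationale <- rationale
  class(out) <- c("tiered_mutations", "data.frame")
  out
}

#' Assign a tier to a single somatic mutation
#' @param variant a one-row `somatic_variants` table
#' @inheritParams tier_mutations
#' @return a one-row `tiered_mutations` table
#' @export
assign_tier <- function(variant, cancer_type, kb) {
  stopifnot(nrow(variant) == 1)
  tier_mutations(variant, cancer_type, kb)
}

#' Filter tiered mutations to the cancer-relevant subset (tiers 1-4)
#' @param mutations a `tiered_mutations` table
#' @return list with `mutations` (order-preserving tier <= 4 subset) and `count`
#' @export
cancer_relevant <- function(mutations) {
  if (!"tier" %in% names(mutations)) stopf("mutations must be tiered first")
  keep <- mutations[mutations$tier <= 4L, , drop = FALSE]
  rownames(keep) <- NULL
  list(mutations = keep, count = nrow(keep))
}

#' Export tiered mutations as a findings-style TSV
#'
#' Layout: patient, gene, protein change, tier, gene function note (role and
#' firing rationale), sorted by tier then gene.
#'
#' @param mutations a `tiered_mutations` table
#' @param patient_id patient label for the first column
#' @param kb a `knowledge_base` (for gene roles)
#' @param path output TSV path, or NULL to return the data.frame
#' @export
write_tiered_tsv <- function(mutations, patient_id, kb, path = NULL) {
  df <- data.frame(
    patient = patient_id,
    gene = mutations$gene,
    protein_change = mutations$protein_change,
    tier = mutations$tier,
    gene_function = paste0(gene_role(kb, mutations$gene), "; ", mutations$rationale),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$tier, df$gene, df$protein_change), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
  } else df
}

#' Per-gene alteration frequency across a cohort
#'
#' Fraction of patients carrying any somatic mutation or gain/loss CNA in each
#' gene, the layout of a per-cohort alteration summary table.
#'
#' @param profiles list of `patient_profile`
#' @param genes genes to tabulate
#' @param kb a `knowledge_base` (gene loci, for CNA-to-gene mapping)
#' @return named numeric vector of frequencies in `[0,1]`
#' @export
gene_alteration_frequency <- function(profiles, genes, kb) {
  genes <- toupper(genes)
  hits <- vapply(genes, function(g) {
    sum(vapply(profiles, function(p) {
      som <- g %in% p$somatic$gene
      cna <- g %in% cna_gene_events(p$cna, kb)$gene
      som || cna
    }, logical(1)))
  }, numeric(1))
  hits / length(profiles)
}
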