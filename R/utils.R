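# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#: Ordered evidence hierarchy used by the drug-response decision trees.
EVIDENCE_LEVELS <- c("Definitive", "Strong", "Moderate", "Weak")

#: Toxicity outcomes, most severe first.
TOXICITY_LEVELS <- c("Severe Toxicity", "Elevated Toxicity", "Normal", "Less Toxicity")

#: Controlled vocabulary of cancer-type labels. Free-form types are accepted
#: with an "other:" prefix; anything else triggers the pan-cancer fallback.
CANCER_TYPES <- c(
  "colorectal", "breast", "MTC", "lung", "leukemia", "renal", "thyroid",
  "skin_scc", "ovarian", "pancreatic", "unknown_primary"
)

is_known_cancer_type <- function(x) {
  x %in% CANCER_TYPES | startsWith(x, "other:")
}

#' Rank of an evidence level (1 = Definitive)
#' @param level character vector of evidence levels
#' @return integer ranks; lower is stronger
#' @keywords internal
evidence_rank <- function(level) {
  r <- match(level, EVIDENCE_LEVELS)
  if (anyNA(r)) stop("unknown evidence level: ", paste(level[is.na(r)], collapse = ", "))
  r
}

toxicity_rank <- function(outcome) {
  r <- match(outcome, TOXICITY_LEVELS)
  if (anyNA(r)) stop("unknown toxicity outcome: ", paste(outcome[is.na(r)], collapse = ", "))
  r
}

# Truncating protein-change heuristics: frameshifts ("fs"), stop gains
# (trailing "*" or "*<n>"), and splice-site markers.
is_truncating_change <- function(protein_change, consequence = NULL) {
  pc <- ifelse(is.na(protein_change), "", protein_change)
  trunc_pc <- grepl("fs", pc, fixed = TRUE) |
    grepl("\\*[0-9]*$", pc) |
    grepl("splice", pc, ignore.case = TRUE)
  if (!is.null(consequence)) {
    trunc_pc <- trunc_pc | consequence %in% c("nonsense", "frameshift", "splice_site")
  }
  trunc_pc
}

# Infer a consequence label from an HGVS-like protein-change string.
consequence_from_protein_change <- function(protein_change) {
  pc <- ifelse(is.na(protein_change), "", protein_change)
  out <- rep("other", length(pc))
  out[grepl("^p\\.[A-Z][0-9]+[A-Z]$", pc)] <- "missense"
  out[grepl("fs", pc, fixed = TRUE)] <- "frameshift"
  out[grepl("\\*$", pc) & !grepl("fs", pc, fixed = TRUE)] <- "nonsense"
  out[grepl("\\*[0-9]+$", pc) & !grepl("fs", pc, fixed = TRUE)] <- "nonsense"
  out[grepl("splice", pc, ignore.case = TRUE)] <- "splice_site"
  out[grepl("del$|ins$|delins", pc)] <- "inframe_indel"
  out[pc == ""] <- "other"
  out
}

# Strip isoform qualifiers from HGVS p. strings so catalog matching is on the
# bare change (e.g. "p.G12V (iso2)" -> "p.G12V").
normalize_protein_change <- function(protein_change) {
  pc <- trimws(protein_change)
  pc <- sub("\\s*\\(.*\\)$", "", pc)
  pc
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# seed helper: derive a distinct, 32-bit-safe stream seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% .Machine$integer.max)
}
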