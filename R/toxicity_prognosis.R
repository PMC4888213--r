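# Four-class toxicity prediction for tier-1 drugs and prognostic biomarker
# matching.

#' Predict drug toxicity from germline and somatic markers
#'
#' All matching toxicity rules for the drug are evaluated against the profile;
#' the most severe matching outcome wins (Severe Toxicity > Elevated Toxicity >
#' Normal > Less Toxicity). With no matching rule the prediction defaults to
#' "Normal" with no supporting variants.
#'
#' @param profile a `patient_profile`
#' @param drug drug name (expected to be tier 1 for the profile's cancer type)
#' @param kb a `knowledge_base`
#' @return list of class `toxicity_prediction`: drug, outcome, support table
#' @export
predict_toxicity <- function(profile, drug, kb) {
  rules <- kb$toxicity_rules[kb$toxicity_rules$drug == drug, , drop = FALSE]
  hits <- lapply(seq_len(nrow(rules)), function(i) {
    m <- evaluate_predicate(rules$predicate[i], profile, kb)
    if (nrow(m) == 0) NULL else list(outcome = rules$outcome[i], support = m)
  })
  hits <- Filter(Negate(is.null), hits)
  if (length(hits) == 0) {
    return(structure(list(drug = drug, outcome = "Normal", support = empty_support()),
                     class = "toxicity_prediction"))
  }
  ranks <- vapply(hits, function(h) toxicity_rank(h$outcome), numeric(1))
  best <- min(ranks)
  outcome <- TOXICITY_LEVELS[best]
  support <- unique(do.call(rbind, lapply(hits[ranks == best], `[[`, "support")))
  if (outcome == "Normal") support <- empty_support()  # Normal <=> no supporting variants
  rownames(support) <- NULL
  structure(list(drug = drug, outcome = outcome, support = support),
            class = "toxicity_prediction")
}

#' @export
print.toxicity_prediction <- function(x, ...) {
  cat(sprintf("<toxicity_prediction> %s: %s (%d supporting variant(s))\n",
              x$drug, x$outcome, nrow(x$support)))
  invisible(x)
}

#' Match a patient's profile against curated prognostic biomarkers
#'
#' All markers curated for the patient's cancer type whose predicate matches
#' are reported, without aggregation -- two markers of opposite direction are
#' both returned.
#'
#' @inheritParams predict_toxicity
#' @return data.frame (marker_id, direction, note, matched alteration summary);
#'   zero rows when no marker matches or none is curated for the cancer type
#' @export
match_prognosis <- function(profile, kb) {
  rules <- kb$prognostic[kb$prognostic$cancer_type %in% c(profile$cancer_type, "any"), ,
                         drop = FALSE]
  hits <- lapply(seq_len(nrow(rules)), function(i) {
    m <- evaluate_predicate(rules$predicate[i], profile, kb)
    if (nrow(m) == 0) return(NULL)
    data.frame(
      marker_id = rules$marker_id[i], direction = rules$direction[i],
      note = rules$note[i],
      matched = paste(unique(paste0(m$gene, "(", m$detail, ")")), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(marker_id = character(), direction = character(),
                      note = character(), matched = character())
  }
  rownames(out) <- NULL
  out
}
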