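# In-silico restriction of patient profiles to targeted-panel content and the
# cohort-level comparison of panels versus the integrative approach.

#' Restrict a patient profile to what a targeted panel would detect
#'
#' Hotspot panels keep somatic SNV/indels whose genomic position lies inside a
#' hotspot interval; full-gene panels keep somatic SNV/indels in panel genes;
#' full-gene-plus-CNA panels additionally keep gain/loss segments overlapping a
#' panel gene. Germline variants survive only when the panel reports germline;
#' expression records only when it reports expression (never, for DNA panels).
#'
#' @param profile a `patient_profile`
#' @param panel a `panel_definition`
#' @param kb a `knowledge_base` (gene loci, for CNA-to-gene mapping)
#' @return the restricted `patient_profile`
#' @export
panel_filter <- function(profile, panel, kb) {
  stopifnot(inherits(panel, "panel_definition"))
  s <- profile$somatic
  if (panel$mode == "hotspot") {
    hs <- panel$hotspots
    keep <- vapply(seq_len(nrow(s)), function(i) {
      any(hs$chrom == s$chrom[i] & hs$start <= s$pos[i] & hs$end >= s$pos[i])
    }, logical(1))
    s <- s[keep, , drop = FALSE]
  } else {
    s <- s[s$gene %in% panel$genes, , drop = FALSE]
  }
  rownames(s) <- NULL

  cna <- profile$cna[0, , drop = FALSE]
  if (panel$mode == "full_gene_plus_cna" && nrow(profile$cna) > 0) {
    ev <- cna_gene_events(profile$cna, kb)
    seg_keep <- sort(unique(ev$seg[ev$gene %in% panel$genes]))
    cna <- profile$cna[seg_keep, , drop = FALSE]
    rownames(cna) <- NULL
  }

  germline <- if (panel$detects_germline) {
    profile$germline[profile$germline$gene %in% panel$genes, , drop = FALSE]
  } else profile$germline[0, , drop = FALSE]
  expression <- if (panel$detects_expression) profile$expression
                else profile$expression[0, , drop = FALSE]

  patient_profile(
    patient_id = profile$patient_id, cancer_type = profile$cancer_type,
    somatic = s, germline = germline, cna = cna, expression = expression,
    specimen_meta = c(profile$specimen_meta, list(panel = panel$name))
  )
}

interpret_counts <- function(profile, kb) {
  tiered <- tier_mutations(profile$somatic, profile$cancer_type, kb)
  relevant <- cancer_relevant(tiered)
  t1 <- predict_tier1_response(profile, kb)
  t2 <- recommend_tier2(profile, kb)
  act <- actionability(profile, t1, t2)
  list(relevant = relevant$count, actionable = act$total,
       has_tier1 = act$has_tier1, has_tier2 = act$has_tier2)
}

#' Cohort comparison of the integrative approach against targeted panels
#'
#' Runs tiering and the therapy engine per patient on the full profile
#' (integrative approach) and on each panel-restricted profile, then aggregates
#' cancer-relevant mutation counts, tier-1/tier-2 recommendation patient
#' counts, actionable-patient counts and actionable-alteration means, with
#' integrative/panel fold changes (NA when a panel mean is 0). Panel-restricted
#' evidence evaluation reuses the same knowledge base; only the visible
#' alterations change.
#'
#' @param profiles non-empty list of `patient_profile`
#' @param panels list of `panel_definition` (defaults to the KB's)
#' @param kb a `knowledge_base`
#' @return list of class `cohort_summary`: `table` (one row per approach, the
#'   integrative row last) and `fold_changes`
#' @export
summarize_cohort <- function(profiles, kb, panels = kb$panels) {
  if (length(profiles) == 0) stopf("empty cohort")
  approaches <- c(vapply(panels, `[[`, character(1), "name"), "integrative")
  per_patient <- lapply(profiles, function(p) {
    res <- list(integrative = interpret_counts(p, kb))
    for (pan in panels) {
      res[[pan$name]] <- interpret_counts(panel_filter(p, pan, kb), kb)
    }
    res
  })
  one_row <- function(appr) {
    rel <- vapply(per_patient, function(r) r[[appr]]$relevant, numeric(1))
    act <- vapply(per_patient, function(r) r[[appr]]$actionable, numeric(1))
    data.frame(
      approach = appr,
      mean_relevant = mean(rel), min_relevant = min(rel), max_relevant = max(rel),
      n_tier1 = sum(vapply(per_patient, function(r) r[[appr]]$has_tier1, logical(1))),
      n_tier2 = sum(vapply(per_patient, function(r) r[[appr]]$has_tier2, logical(1))),
      n_actionable = sum(act > 0),
      mean_actionable = mean(act), min_actionable = min(act), max_actionable = max(act),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, lapply(approaches, one_row))
  rownames(tab) <- NULL
  integ <- tab[tab$approach == "integrative", ]
  fc <- lapply(setdiff(approaches, "integrative"), function(a) {
    row <- tab[tab$approach == a, ]
    data.frame(
      panel = a,
      fold_relevant = if (row$mean_relevant > 0) integ$mean_relevant / row$mean_relevant else NA_real_,
      fold_actionable = if (row$mean_actionable > 0) integ$mean_actionable / row$mean_actionable else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  fc <- do.call(rbind, fc) %||% data.frame(panel = character(),
                                           fold_relevant = numeric(),
                                           fold_actionable = numeric())
  structure(list(table = tab, fold_changes = fc, n_patients = length(profiles)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d patients\n", x$n_patients))
  print(format_cohort_summary(x), row.names = FALSE)
  invisible(x)
}

#' Format a cohort summary as a comparison table
#'
#' Columns mirror the published comparison layout: mean cancer-relevant
#' mutations (range), patients with tier-1 / tier-2 recommendations, patients
#' with actionable alterations, mean actionable alterations (range).
#'
#' @param summary a `cohort_summary`
#' @param path optional TSV output path
#' @return data.frame (invisibly the path when `path` is given)
#' @export
format_cohort_summary <- function(summary, path = NULL) {
  tab <- summary$table
  n <- summary$n_patients
  df <- data.frame(
    approach = tab$approach,
    mean_relevant_range = sprintf("%.1f (%d-%d)", tab$mean_relevant,
                                  tab$min_relevant, tab$max_relevant),
    patients_tier1 = sprintf("%d (%.0f%%)", tab$n_tier1, 100 * tab$n_tier1 / n),
    patients_tier2 = sprintf("%d (%.0f%%)", tab$n_tier2, 100 * tab$n_tier2 / n),
    patients_actionable = sprintf("%d (%.0f%%)", tab$n_actionable, 100 * tab$n_actionable / n),
    mean_actionable_range = sprintf("%.2f (%d-%d)", tab$mean_actionable,
                                    tab$min_actionable, tab$max_actionable),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  df
}
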