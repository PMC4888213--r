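# Evidence-hierarchy decision-tree drug-response prediction (tier-1 drugs),
# tier-2 recommendations via drug-target/pathway mapping, pathway projection,
# germline risk screening, trial matching and actionability accounting.

new_predictions <- function(drug = character(), drug_tier = integer(),
                            effect = character(), evidence = character(),
                            is_combination = logical(), rule_ids = character(),
                            support = list()) {
  df <- data.frame(
    drug = drug, drug_tier = as.integer(drug_tier), effect = effect,
    evidence = evidence, is_combination = is_combination, rule_ids = rule_ids,
    stringsAsFactors = FALSE
  )
  df$support <- support
  class(df) <- c("therapy_predictions", "data.frame")
  df
}

empty_support <- function() {
  data.frame(gene = character(), source = character(), detail = character(),
             class = character(), stringsAsFactors = FALSE)
}

rules_for_type <- function(rules, cancer_type) {
  rules[rules$cancer_type %in% c(cancer_type, "any"), , drop = FALSE]
}

# Decision-tree evaluation for one drug: walk the evidence hierarchy
# Definitive -> Strong -> Moderate -> Weak; the first level with >= 1 matching
# rule determines effect and evidence (lower levels are never consulted).
# Conflicts at one level resolve to the negative effect (conservative default).
evaluate_drug_tree <- function(drug, rules, profile, kb, drug_tier) {
  rules <- rules[rules$drug == drug, , drop = FALSE]
  for (lvl in EVIDENCE_LEVELS) {
    lvl_rules <- rules[rules$evidence == lvl, , drop = FALSE]
    if (nrow(lvl_rules) == 0) next
    hits <- lapply(seq_len(nrow(lvl_rules)), function(i) {
      evaluate_predicate(lvl_rules$predicate[i], profile, kb)
    })
    matched <- vapply(hits, nrow, integer(1)) > 0
    if (!any(matched)) next
    effects <- lvl_rules$effect[matched]
    negative <- intersect(c("lack_of_benefit", "resistance"), effects)
    # conflicting effects at one level resolve to the negative call
    # (conservative clinical default); every alteration matched at the
    # deciding level remains in the supporting set
    effect <- if (length(unique(effects)) > 1 && length(negative) > 0) {
      negative[1]
    } else {
      effects[1]
    }
    support <- unique(do.call(rbind, hits[matched]))
    rownames(support) <- NULL
    return(new_predictions(
      drug = drug, drug_tier = drug_tier, effect = effect, evidence = lvl,
      is_combination = FALSE,
      rule_ids = paste(lvl_rules$rule_id[matched], collapse = ";"),
      support = list(support)
    ))
  }
  new_predictions(drug = drug, drug_tier = drug_tier, effect = "no_prediction",
                  evidence = "none", is_combination = FALSE, rule_ids = "",
                  support = list(empty_support()))
}

#' Predict tier-1 drug response via the evidence-hierarchy decision tree
#'
#' For every tier-1 drug curated for the patient's cancer type, rules are
#' evaluated strictly in evidence order (Definitive, then Strong, Moderate,
#' Weak); the first level with at least one matching rule determines the
#' predicted effect and its evidence level, and no lower level is consulted.
#' Drugs with no matching rule at any level are returned with effect
#' `no_prediction`.
#'
#' @param profile a `patient_profile`
#' @param kb a `knowledge_base`
#' @return a `therapy_predictions` table, one row per tier-1 drug
#' @export
predict_tier1_response <- function(profile, kb) {
  rules <- rules_for_type(kb$drug_rules[kb$drug_rules$drug_tier == 1L, , drop = FALSE],
                          profile$cancer_type)
  drugs <- sort(unique(rules$drug))
  out <- lapply(drugs, evaluate_drug_tree, rules = rules, profile = profile,
                kb = kb, drug_tier = 1L)
  if (length(out) == 0) return(new_predictions())
  res <- do.call(rbind, out)
  class(res) <- c("therapy_predictions", "data.frame")
  res
}

# activating lesions in a gene set: oncogene activated (activating mutation,
# copy gain, overexpression) or tumor suppressor inactivated (truncating
# mutation, copy loss, underexpression).
pathway_lesions <- function(profile, genes, kb) {
  out <- list()
  s <- profile$somatic
  if (nrow(s) > 0) {
    act <- s$gene %in% genes & is_activating(kb, s$gene, s$protein_change, s$consequence)
    inact <- s$gene %in% genes & is_inactivating(kb, s$gene, s$protein_change, s$consequence)
    sel <- act | inact
    if (any(sel)) {
      out$som <- data.frame(gene = s$gene[sel], source = "somatic",
                            detail = s$protein_change[sel],
                            class = ifelse(act[sel], "somatic_activating", "somatic_inactivating"),
                            stringsAsFactors = FALSE)
    }
  }
  ev <- cna_gene_events(profile$cna, kb)
  if (nrow(ev) > 0) {
    role <- gene_role(kb, ev$gene)
    sel <- ev$gene %in% genes &
      ((ev$call == "gain" & role == "oncogene") |
       (ev$call == "loss" & role == "tumor_suppressor"))
    if (any(sel)) {
      out$cna <- data.frame(gene = ev$gene[sel], source = "cna", detail = ev$call[sel],
                            class = paste0("cna_", ev$call[sel]), stringsAsFactors = FALSE)
    }
  }
  e <- profile$expression
  if (nrow(e) > 0) {
    role <- gene_role(kb, e$gene)
    sel <- e$gene %in% genes &
      ((e$level == "high" & role == "oncogene") |
       (e$level == "low" & role == "tumor_suppressor"))
    if (any(sel)) {
      out$expr <- data.frame(gene = e$gene[sel], source = "expression",
                             detail = e$level[sel],
                             class = paste0("expression_", e$level[sel]),
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty_support() else unique(res)
}

#' Recommend tier-2 therapies from drug-target and pathway mapping
#'
#' Three routes, all yielding `sensitivity` predictions with tier 2: (i)
#' explicit tier-2 drug rules evaluated through the same evidence hierarchy as
#' tier 1; (ii) direct target mapping -- an activating lesion in a druggable
#' target recommends the drugs targeting it; (iii) pathway mapping -- an
#' activated signaling pathway (an activating lesion in an oncogene member or
#' an inactivating lesion in a tumor-suppressor member) recommends drugs whose
#' target lies in that pathway. Combination recommendations are emitted when
#' two or more independent pathways carry actionable lesions, or when a curated
#' feedback-loop pathway pair is fully activated. Drugs that are tier 1 for the
#' patient's cancer type are excluded (tier 2 covers "all other therapies").
#'
#' @inheritParams predict_tier1_response
#' @return a `therapy_predictions` table with `drug_tier = 2`
#' @export
recommend_tier2 <- function(profile, kb) {
  tier1_drugs <- unique(rules_for_type(
    kb$drug_rules[kb$drug_rules$drug_tier == 1L, , drop = FALSE],
    profile$cancer_type
  )$drug)

  preds <- list()

  # (i) explicit tier-2 rules
  t2_rules <- rules_for_type(kb$drug_rules[kb$drug_rules$drug_tier == 2L, , drop = FALSE],
                             profile$cancer_type)
  t2_rules <- t2_rules[!t2_rules$drug %in% tier1_drugs, , drop = FALSE]
  for (d in sort(unique(t2_rules$drug))) {
    p <- evaluate_drug_tree(d, t2_rules, profile, kb, drug_tier = 2L)
    if (p$effect != "no_prediction") preds[[length(preds) + 1]] <- p
  }

  targets <- kb$drug_targets[!kb$drug_targets$drug %in% tier1_drugs, , drop = FALSE]

  # (ii) direct target activation
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    les <- pathway_lesions(profile, tg$target, kb)
    les <- les[les$class %in% c("somatic_activating", "cna_gain", "expression_high"), , drop = FALSE]
    if (nrow(les) > 0) {
      preds[[length(preds) + 1]] <- new_predictions(
        drug = tg$drug, drug_tier = 2L, effect = "sensitivity",
        evidence = tg$evidence, is_combination = FALSE,
        rule_ids = paste0("target:", tg$target), support = list(les)
      )
    }
  }

  # (iii) pathway activation
  pw_names <- intersect(unique(targets$pathway), unique(kb$pathways$pathway))
  activated <- list()
  for (pw in sort(pw_names)) {
    members <- kb$pathways$gene[kb$pathways$pathway == pw]
    les <- pathway_lesions(profile, members, kb)
    if (nrow(les) > 0) activated[[pw]] <- les
  }
  for (pw in names(activated)) {
    pw_targets <- targets[targets$pathway == pw, , drop = FALSE]
    for (i in seq_len(nrow(pw_targets))) {
      tg <- pw_targets[i, ]
      preds[[length(preds) + 1]] <- new_predictions(
        drug = tg$drug, drug_tier = 2L, effect = "sensitivity",
        evidence = tg$evidence, is_combination = FALSE,
        rule_ids = paste0("pathway:", pw), support = list(activated[[pw]])
      )
    }
  }

  if (length(preds) == 0) return(new_predictions())
  res <- do.call(rbind, preds)

  # deduplicate per drug: keep strongest evidence, merge support
  res <- res[order(res$drug, evidence_rank(res$evidence)), , drop = FALSE]
  merged <- lapply(split(seq_len(nrow(res)), res$drug), function(ix) {
    first <- res[ix[1], , drop = FALSE]
    sup <- unique(do.call(rbind, res$support[ix]))
    rownames(sup) <- NULL
    first$support <- list(sup)
    first$rule_ids <- paste(unique(unlist(strsplit(res$rule_ids[ix], ";"))), collapse = ";")
    first
  })
  res <- do.call(rbind, merged)

  # combinations: curated feedback-loop pairs, then the >=2-independent-lesions rule
  combos <- list()
  fb <- kb$feedback_pairs
  if (!is.null(fb)) {
    for (i in seq_len(nrow(fb))) {
      if (fb$pathway_a[i] %in% names(activated) && fb$pathway_b[i] %in% names(activated)) {
        sup <- unique(rbind(activated[[fb$pathway_a[i]]], activated[[fb$pathway_b[i]]]))
        combos[[length(combos) + 1]] <- new_predictions(
          drug = paste(fb$drug_a[i], "+", fb$drug_b[i]), drug_tier = 2L,
          effect = "sensitivity", evidence = "Weak", is_combination = TRUE,
          rule_ids = paste0("feedback:", fb$pathway_a[i], "+", fb$pathway_b[i]),
          support = list(sup)
        )
      }
    }
  }
  if (length(activated) >= 2) {
    pws <- sort(names(activated))[1:2]
    pick <- function(pw) sort(targets$drug[targets$pathway == pw])[1]
    da <- pick(pws[1]); db <- pick(pws[2])
    if (!is.na(da) && !is.na(db) && da != db) {
      sup <- unique(rbind(activated[[pws[1]]], activated[[pws[2]]]))
      combos[[length(combos) + 1]] <- new_predictions(
        drug = paste(da, "+", db), drug_tier = 2L, effect = "sensitivity",
        evidence = "Weak", is_combination = TRUE,
        rule_ids = paste0("multilesion:", paste(pws, collapse = "+")),
        support = list(sup)
      )
    }
  }
  if (length(combos) > 0) {
    cres <- do.call(rbind, combos)
    cres <- cres[!duplicated(cres$drug), , drop = FALSE]
    res <- rbind(res, cres)
  }
  rownames(res) <- NULL
  class(res) <- c("therapy_predictions", "data.frame")
  res
}

#' Project a patient's altered genes onto curated signaling pathways
#'
#' Altered genes (somatic, gain/loss CNA, high/low expression, germline) are
#' crossed against the curated pathway gene sets; one hit is reported per
#' pathway with at least one altered member, with `multi_hit` set when two or
#' more distinct member genes are altered.
#'
#' @inheritParams predict_tier1_response
#' @return data.frame (pathway, genes, n_genes, multi_hit)
#' @export
project_onto_pathways <- function(profile, kb) {
  altered <- unique(c(
    profile$somatic$gene,
    cna_gene_events(profile$cna, kb)$gene,
    profile$expression$gene[profile$expression$level %in% c("high", "low")],
    profile$germline$gene
  ))
  altered <- altered[nzchar(altered)]
  pws <- sort(unique(kb$pathways$pathway))
  hits <- lapply(pws, function(pw) {
    members <- kb$pathways$gene[kb$pathways$pathway == pw]
    hit <- sort(intersect(altered, members))
    if (length(hit) == 0) return(NULL)
    data.frame(pathway = pw, genes = paste(hit, collapse = ","),
               n_genes = length(hit), multi_hit = length(hit) >= 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(pathway = character(), genes = character(),
                      n_genes = integer(), multi_hit = logical())
  }
  rownames(out) <- NULL
  out
}

#' Screen germline variants against a risk-gene panel
#'
#' @param germline a `germline_variants` table
#' @param panel_genes character vector of risk genes (e.g. the breast-risk set)
#' @return matched variants with a `truncating` flag (protein-truncating
#'   changes are flagged prominent)
#' @export
germline_risk_screen <- function(germline, panel_genes) {
  if (length(panel_genes) == 0) stopf("risk panel is empty")
  hit <- germline[germline$gene %in% toupper(panel_genes), , drop = FALSE]
  hit$truncating <- is_truncating_change(hit$protein_change)
  rownames(hit) <- NULL
  hit
}

#' Match a patient against locally curated clinical-trial records
#'
#' Trials whose biomarker predicate matches the profile and whose cancer-type
#' list includes the profile's type (or is type-agnostic, "any") are returned,
#' open trials ranked before closed ones.
#'
#' @inheritParams predict_tier1_response
#' @param trials trial table (defaults to the KB's)
#' @return data.frame of matched trials with `n_matched_alterations`
#' @export
match_trials <- function(profile, kb, trials = kb$trials) {
  if (nrow(trials) == 0) {
    return(data.frame(trial_id = character(), title = character(), open = logical(),
                      location = character(), n_matched_alterations = integer()))
  }
  type_ok <- vapply(trials$cancer_types, function(ct) {
    types <- trimws(strsplit(ct, ",", fixed = TRUE)[[1]])
    "any" %in% types || profile$cancer_type %in% types
  }, logical(1))
  hits <- lapply(seq_len(nrow(trials)), function(i) {
    if (!type_ok[i]) return(NULL)
    m <- evaluate_predicate(trials$predicate[i], profile, kb)
    if (nrow(m) == 0) return(NULL)
    data.frame(trial_id = trials$trial_id[i], title = trials$title[i],
               open = as.logical(trials$open[i]), location = trials$location[i],
               n_matched_alterations = nrow(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(trial_id = character(), title = character(), open = logical(),
                      location = character(), n_matched_alterations = integer()))
  }
  out <- out[order(!out$open, out$trial_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count actionable alterations for one patient
#'
#' Actionable alterations are those supporting any tier-1 prediction (other
#' than `no_prediction`) or any tier-2 recommendation. The counting unit is
#' gene x source: a gene contributes at most once per source category
#' (somatic, cna, germline, expression).
#'
#' @param profile a `patient_profile`
#' @param tier1_predictions,tier2_predictions `therapy_predictions` tables
#' @return list of class `actionability_report`: per-source counts, total,
#'   `has_tier1`/`has_tier2` flags and the deduplicated alteration table
#' @export
actionability <- function(profile, tier1_predictions, tier2_predictions) {
  sup1 <- tier1_predictions$support[tier1_predictions$effect != "no_prediction"]
  sup2 <- tier2_predictions$support
  all_sup <- do.call(rbind, c(sup1, sup2, list(empty_support())))
  units <- unique(all_sup[, c("gene", "source")])
  rownames(units) <- NULL
  counts <- vapply(c("somatic", "cna", "germline", "expression"),
                   function(s) sum(units$source == s), integer(1))
  structure(list(
    patient_id = profile$patient_id,
    alterations = units,
    counts = counts,
    total = sum(counts),
    has_tier1 = any(tier1_predictions$effect != "no_prediction"),
    has_tier2 = nrow(tier2_predictions) > 0
  ), class = "actionability_report")
}

#' @export
print.actionability_report <- function(x, ...) {
  cat(sprintf(
    "<actionability_report> %s: %d actionable (somatic %d, cna %d, germline %d, expression %d); tier1=%s tier2=%s\n",
    x$patient_id, x$total, x$counts["somatic"], x$counts["cna"],
    x$counts["germline"], x$counts["expression"], x$has_tier1, x$has_tier2
  ))
  invisible(x)
}
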