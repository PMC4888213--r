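# Per-patient findings document assembly: run every engine, collect the
# sections of the summary genomic findings document, render deterministically
# to JSON (source of truth) and markdown.

#' Run the full interpretation pipeline for one patient
#'
#' Tiering, tier-1 decision trees, tier-2 recommendations, per-tier-1-drug
#' toxicity, prognosis matching, pathway projection, trial matching, germline
#' risk screening (against the risk panel named `<cancer_type>_risk` when the
#' KB carries one) and actionability accounting.
#'
#' @param profile a `patient_profile`
#' @param kb a `knowledge_base`
#' @return list of engine outputs consumed by [generate_findings()]
#' @export
interpret_patient <- function(profile, kb) {
  tiered <- tier_mutations(profile$somatic, profile$cancer_type, kb)
  tier1 <- predict_tier1_response(profile, kb)
  tier2 <- recommend_tier2(profile, kb)
  toxicity <- lapply(sort(unique(tier1$drug)), predict_toxicity,
                     profile = profile, kb = kb)
  prognosis <- match_prognosis(profile, kb)
  pathways <- project_onto_pathways(profile, kb)
  trials <- match_trials(profile, kb)
  risk_name <- paste0(profile$cancer_type, "_risk")
  risk_genes <- kb$risk_genes$gene[kb$risk_genes$panel == risk_name]
  germline_findings <- if (length(risk_genes) > 0) {
    germline_risk_screen(profile$germline, risk_genes)
  } else {
    cbind(profile$germline[0, , drop = FALSE], truncating = logical())
  }
  act <- actionability(profile, tier1, tier2)
  list(
    tiered = tiered, tier1 = tier1, tier2 = tier2, toxicity = toxicity,
    prognosis = prognosis, pathways = pathways, trials = trials,
    germline_findings = germline_findings, actionability = act
  )
}

predictions_section <- function(preds) {
  if (nrow(preds) == 0) return(list())
  # stable ordering: tier 1 before tier 2, evidence descending, drug name
  ev <- ifelse(preds$evidence == "none", length(EVIDENCE_LEVELS) + 1,
               match(preds$evidence, EVIDENCE_LEVELS))
  preds <- preds[order(preds$drug_tier, ev, preds$drug), , drop = FALSE]
  lapply(seq_len(nrow(preds)), function(i) {
    sup <- preds$support[[i]]
    list(
      drug = preds$drug[i], drug_tier = preds$drug_tier[i],
      effect = preds$effect[i], evidence = preds$evidence[i],
      is_combination = preds$is_combination[i],
      rule_ids = preds$rule_ids[i],
      supporting_alterations = if (nrow(sup) == 0) list() else
        lapply(seq_len(nrow(sup)), function(j) as.list(sup[j, ]))
    )
  })
}

#' Assemble the per-patient findings document
#'
#' Sections: somatic mutations (tiers 1-4 only, with gene function and pathway
#' notes), drug response (tier 1 then tier 2, evidence descending), toxicity,
#' prognosis, pathways, clinical trials, germline findings, plus a provenance
#' block (KB version, input checksum, seed). Rendering order is deterministic:
#' mutations sort by tier then gene; identical inputs produce byte-identical
#' JSON. Somatic mutations confirmed in RNA (`rna_validated` attribute on the
#' profile's somatic table) are flagged `"validated"`. An empty document
#' carries an explicit "no clinically relevant results" banner.
#'
#' @param profile a `patient_profile`
#' @param results output of [interpret_patient()]; any missing engine output is
#'   an assembly error naming the section
#' @param kb a `knowledge_base`
#' @param seed seed recorded in the provenance block (NA when none applies)
#' @return list of class `findings_document`
#' @export
generate_findings <- function(profile, results, kb, seed = NA) {
  required <- c("tiered", "tier1", "tier2", "toxicity", "prognosis",
                "pathways", "trials", "germline_findings", "actionability")
  missing <- setdiff(required, names(results))
  if (length(missing) > 0) {
    stopf("missing engine output for section(s): %s", paste(missing, collapse = ", "))
  }

  relevant <- cancer_relevant(results$tiered)$mutations
  validated <- attr(profile$somatic, "rna_validated") %||% character(0)
  somatic_section <- if (nrow(relevant) == 0) list() else {
    relevant <- relevant[order(relevant$tier, relevant$gene, relevant$protein_change), , drop = FALSE]
    lapply(seq_len(nrow(relevant)), function(i) {
      m <- relevant[i, ]
      pws <- kb$pathways$pathway[kb$pathways$gene == m$gene]
      list(
        gene = m$gene, protein_change = m$protein_change, tier = m$tier,
        tumor_id = m$tumor_id, af = m$af,
        gene_function = gene_role(kb, m$gene),
        pathways = as.list(sort(unique(pws))),
        rationale = m$rationale,
        validated = paste(m$gene, m$protein_change) %in% validated
      )
    })
  }

  tox_section <- lapply(results$toxicity, function(t) {
    list(drug = t$drug, outcome = t$outcome,
         supporting_variants = if (nrow(t$support) == 0) list() else
           lapply(seq_len(nrow(t$support)), function(j) as.list(t$support[j, ])))
  })

  df_section <- function(df) {
    if (nrow(df) == 0) list() else lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }

  has_content <- nrow(relevant) > 0 ||
    any(results$tier1$effect != "no_prediction") || nrow(results$tier2) > 0 ||
    nrow(results$prognosis) > 0 || nrow(results$trials) > 0 ||
    nrow(results$germline_findings) > 0

  prof_file <- tempfile(fileext = ".json")
  on.exit(unlink(prof_file), add = TRUE)
  jsonlite::write_json(list(
    somatic = profile$somatic, germline = profile$germline,
    cna = profile$cna, expression = profile$expression
  ), prof_file, digits = NA)

  doc <- structure(list(
    patient = list(patient_id = profile$patient_id,
                   cancer_type = profile$cancer_type),
    banner = if (has_content) NULL else "no clinically relevant results",
    somatic_mutations = somatic_section,
    drug_response = c(predictions_section(results$tier1),
                      predictions_section(results$tier2)),
    toxicity = tox_section,
    prognosis = df_section(results$prognosis),
    pathways = df_section(results$pathways),
    clinical_trials = df_section(results$trials),
    germline_findings = df_section(results$germline_findings),
    actionability = list(
      total = results$actionability$total,
      by_source = as.list(results$actionability$counts),
      has_tier1 = results$actionability$has_tier1,
      has_tier2 = results$actionability$has_tier2
    ),
    provenance = list(
      kb_version = kb$version,
      input_md5 = unname(tools::md5sum(prof_file)),
      seed = if (is.na(seed)) "none" else as.character(seed),
      generator = paste0("oncointerp ", as.character(utils::packageVersion("oncointerp")))
    )
  ), class = "findings_document")
  doc
}

#' Render a findings document to JSON (the document's source of truth)
#' @param doc a `findings_document`
#' @param path optional output path
#' @return JSON string (invisibly the path when `path` is given)
#' @export
findings_to_json <- function(doc, path = NULL) {
  body <- unclass(doc)
  body$banner <- body$banner %||% NA
  js <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  js
}

#' Render a findings document to human-readable markdown
#'
#' The markdown regenerates from the JSON alone: pass either a
#' `findings_document` or a JSON string/file produced by [findings_to_json()].
#'
#' @param doc a `findings_document`, JSON string, or path to a JSON file
#' @param path optional output path
#' @return character vector of markdown lines (invisibly the path if written)
#' @export
findings_to_markdown <- function(doc, path = NULL) {
  if (inherits(doc, "findings_document")) {
    doc <- jsonlite::fromJSON(findings_to_json(doc), simplifyVector = FALSE)
  } else if (is.character(doc) && length(doc) == 1 && file.exists(doc)) {
    doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  } else if (is.character(doc)) {
    doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  }
  l <- c(
    sprintf("# Genomic findings: %s", doc$patient$patient_id),
    sprintf("Cancer type: %s", doc$patient$cancer_type), ""
  )
  if (!is.null(doc$banner) && !is.na(doc$banner)) {
    l <- c(l, sprintf("**%s**", toupper(doc$banner)), "")
  }
  l <- c(l, "## Somatic mutations (tiers 1-4)")
  if (length(doc$somatic_mutations) == 0) l <- c(l, "_none_") else {
    for (m in doc$somatic_mutations) {
      l <- c(l, sprintf("- tier %d: %s %s (%s%s)%s", m$tier, m$gene,
                        m$protein_change, m$gene_function,
                        if (length(m$pathways) > 0)
                          paste0("; ", paste(unlist(m$pathways), collapse = ", "))
                        else "",
                        if (isTRUE(m$validated)) " [validated]" else ""))
    }
  }
  l <- c(l, "", "## Drug response")
  if (length(doc$drug_response) == 0) l <- c(l, "_none_") else {
    for (d in doc$drug_response) {
      genes <- unique(vapply(d$supporting_alterations, function(a) a$gene, character(1)))
      l <- c(l, sprintf("- [tier %d] %s: %s (%s)%s", d$drug_tier, d$drug,
                        d$effect, d$evidence,
                        if (length(genes) > 0)
                          paste0(" -- ", paste(genes, collapse = ", ")) else ""))
    }
  }
  l <- c(l, "", "## Toxicity")
  if (length(doc$toxicity) == 0) l <- c(l, "_none_") else {
    for (t in doc$toxicity) l <- c(l, sprintf("- %s: %s", t$drug, t$outcome))
  }
  l <- c(l, "", "## Prognosis")
  if (length(doc$prognosis) == 0) l <- c(l, "_none_") else {
    for (p in doc$prognosis) l <- c(l, sprintf("- %s (%s): %s", p$marker_id, p$direction, p$note))
  }
  l <- c(l, "", "## Pathway perturbations")
  if (length(doc$pathways) == 0) l <- c(l, "_none_") else {
    for (p in doc$pathways) {
      l <- c(l, sprintf("- %s: %s%s", p$pathway, p$genes,
                        if (isTRUE(p$multi_hit)) " [multi-hit]" else ""))
    }
  }
  l <- c(l, "", "## Clinical trials")
  if (length(doc$clinical_trials) == 0) l <- c(l, "_none_") else {
    for (t in doc$clinical_trials) {
      l <- c(l, sprintf("- %s (%s): %s", t$trial_id,
                        if (isTRUE(t$open)) "open" else "closed", t$title))
    }
  }
  l <- c(l, "", "## Germline findings")
  if (length(doc$germline_findings) == 0) l <- c(l, "_none_") else {
    for (g in doc$germline_findings) {
      l <- c(l, sprintf("- %s %s (%s)%s", g$gene, g$protein_change, g$zygosity,
                        if (isTRUE(g$truncating)) " [truncating]" else ""))
    }
  }
  l <- c(l, "", sprintf("_KB %s; seed %s; input md5 %s_",
                        doc$provenance$kb_version, doc$provenance$seed,
                        doc$provenance$input_md5))
  if (!is.null(path)) {
    writeLines(l, path)
    return(invisible(path))
  }
  l
}

#' Structural validation of a findings JSON document
#'
#' Checks the document against the shipped schema (required sections and their
#' types); a lightweight structural check, not a full JSON-Schema validator.
#'
#' @param doc a `findings_document`, JSON string, or JSON file path
#' @return TRUE invisibly; errors describe the first violated requirement
#' @export
validate_findings <- function(doc) {
  if (inherits(doc, "findings_document")) {
    doc <- jsonlite::fromJSON(findings_to_json(doc), simplifyVector = FALSE)
  } else if (is.character(doc)) {
    doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  }
  schema_path <- system.file("schema", "findings_schema.json", package = "oncointerp")
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  for (key in names(schema$required_sections)) {
    if (!key %in% names(doc)) stopf("findings document missing section '%s'", key)
    want <- schema$required_sections[[key]]
    if (want == "array" && !is.list(doc[[key]])) stopf("section '%s' must be an array", key)
  }
  for (key in unlist(schema$patient_required)) {
    if (is.null(doc$patient[[key]])) stopf("patient header missing '%s'", key)
  }
  for (m in doc$somatic_mutations) {
    if (!is.numeric(m$tier) || m$tier > 4) stopf("somatic section may only list tier <= 4 mutations")
  }
  for (d in doc$drug_response) {
    if (d$effect != "no_prediction" && !nzchar(d$rule_ids)) {
      stopf("prediction for '%s' is not traceable to a KB rule id", d$drug)
    }
  }
  invisible(TRUE)
}
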