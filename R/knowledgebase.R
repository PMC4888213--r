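# Loading and querying the curated knowledge base: gene-cancer tier lists, a
# COSMIC-like catalog, drug/toxicity/prognostic rules, pathways, panels, trials
# and risk-gene panels. All tables are TSV with a versioned first line
# ("#oncointerp-kb v1"); hotspot intervals additionally load from BED.

PREDICATE_CLASSES <- c(
  "somatic_activating", "somatic_inactivating", "specific_protein_change",
  "cna_gain", "cna_loss", "germline_variant", "expression_high", "expression_low"
)
DRUG_EFFECTS <- c("benefit", "lack_of_benefit", "resistance", "sensitivity")

read_kb_table <- function(dir, name, required, optional_file = FALSE) {
  path <- file.path(dir, paste0(name, ".tsv"))
  if (!file.exists(path)) {
    if (optional_file) return(NULL)
    stopf("knowledge base at %s is missing mandatory table '%s.tsv'", dir, name)
  }
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#oncointerp-kb")) {
    stopf("table %s lacks the versioned '#oncointerp-kb' header line", path)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) stopf("table %s missing column(s): %s", path, paste(miss, collapse = ", "))
  df
}

#' Parse a biomarker predicate string
#'
#' Predicates are a small declarative grammar serialized in KB tables:
#' alternatives separated by `" OR "` (disjunctive), clauses within an
#' alternative separated by `" AND "` (conjunctive). Each clause is
#' `GENE CLASS [ARG]` where CLASS is one of somatic_activating,
#' somatic_inactivating, specific_protein_change, cna_gain, cna_loss,
#' germline_variant, expression_high, expression_low; ARG is an exact protein
#' change (for specific_protein_change, optionally germline_variant) or a
#' minimum fold-change (expression classes).
#'
#' @param predicate predicate string
#' @return list of alternatives; each alternative a list of clauses
#'   `(gene, class, arg)`
#' @export
parse_predicate <- function(predicate) {
  if (is.na(predicate) || !nzchar(trimws(predicate))) stopf("empty predicate")
  alts <- strsplit(predicate, " OR ", fixed = TRUE)[[1]]
  lapply(alts, function(alt) {
    clauses <- strsplit(trimws(alt), " AND ", fixed = TRUE)[[1]]
    lapply(clauses, function(cl) {
      tok <- strsplit(trimws(cl), "\\s+")[[1]]
      if (length(tok) < 2) stopf("malformed predicate clause: '%s'", cl)
      if (!tok[2] %in% PREDICATE_CLASSES) {
        stopf("predicate names unsupported alteration class '%s'", tok[2])
      }
      list(gene = toupper(tok[1]), class = tok[2],
           arg = if (length(tok) >= 3) tok[3] else NA_character_)
    })
  })
}

#' Load a knowledge base directory
#'
#' Parses and cross-validates all curated tables. Every drug-rule gene is
#' checked against the gene-cancer associations and pathway sets (warning when
#' absent); unknown evidence levels, effects, predicate classes or toxicity
#' outcomes are load errors. Tables are sorted so loading is deterministic and
#' idempotent.
#'
#' @param directory path containing the KB tables (see the packaged synthetic
#'   mini-KB under `system.file("extdata", "kb_synthetic", package = "oncointerp")`)
#' @return object of class `knowledge_base`
#' @export
load_kb <- function(directory) {
  if (!dir.exists(directory)) stopf("knowledge base directory not found: %s", directory)

  meta_path <- file.path(directory, "kb_version")
  version <- if (file.exists(meta_path)) trimws(readLines(meta_path, n = 1)) else "unversioned"

  gene_roles <- read_kb_table(directory, "gene_roles", c("gene", "role"))
  if (!all(gene_roles$role %in% c("oncogene", "tumor_suppressor", "other"))) {
    stopf("gene_roles: role must be oncogene/tumor_suppressor/other")
  }
  gene_cancer <- read_kb_table(directory, "gene_cancer", c("gene", "cancer_type"))
  if (anyDuplicated(gene_cancer[c("gene", "cancer_type")])) {
    stopf("gene_cancer: (gene, cancer_type) pairs must be unique")
  }
  catalog <- read_kb_table(directory, "catalog", c("gene", "protein_change"))
  catalog$protein_change <- normalize_protein_change(catalog$protein_change)
  catalog <- unique(catalog)
  activating <- read_kb_table(directory, "activating", c("gene", "protein_change"))
  activating$protein_change <- normalize_protein_change(activating$protein_change)

  drug_rules <- read_kb_table(
    directory, "drug_rules",
    c("rule_id", "drug", "drug_tier", "cancer_type", "predicate", "effect", "evidence")
  )
  if (!all(drug_rules$evidence %in% EVIDENCE_LEVELS)) {
    bad <- unique(drug_rules$evidence[!drug_rules$evidence %in% EVIDENCE_LEVELS])
    stopf("drug_rules: unknown evidence level '%s'", paste(bad, collapse = ", "))
  }
  if (!all(drug_rules$effect %in% DRUG_EFFECTS)) {
    stopf("drug_rules: effect must be one of %s", paste(DRUG_EFFECTS, collapse = "/"))
  }
  if (!all(drug_rules$drug_tier %in% c(1L, 2L))) stopf("drug_rules: drug_tier must be 1 or 2")

  toxicity_rules <- read_kb_table(directory, "toxicity_rules",
                                  c("rule_id", "drug", "predicate", "outcome"))
  if (!all(toxicity_rules$outcome %in% TOXICITY_LEVELS)) {
    bad <- unique(toxicity_rules$outcome[!toxicity_rules$outcome %in% TOXICITY_LEVELS])
    stopf("toxicity_rules: unknown outcome '%s'", paste(bad, collapse = ", "))
  }
  prognostic <- read_kb_table(directory, "prognostic",
                              c("marker_id", "cancer_type", "predicate", "direction", "note"))
  if (!all(prognostic$direction %in% c("favorable", "unfavorable"))) {
    stopf("prognostic: direction must be favorable/unfavorable")
  }
  pathways_df <- read_kb_table(directory, "pathways", c("pathway", "gene"))
  if (anyDuplicated(pathways_df)) pathways_df <- unique(pathways_df)
  drug_targets <- read_kb_table(directory, "drug_targets",
                                c("drug", "target", "pathway", "evidence"))
  if (!all(drug_targets$evidence %in% EVIDENCE_LEVELS)) {
    stopf("drug_targets: unknown evidence level")
  }
  feedback_pairs <- read_kb_table(directory, "feedback_pairs",
                                  c("pathway_a", "pathway_b", "drug_a", "drug_b", "note"),
                                  optional_file = TRUE)
  panels_meta <- read_kb_table(directory, "panels",
                               c("panel", "mode", "detects_germline", "detects_expression"))
  panel_genes <- read_kb_table(directory, "panel_genes", c("panel", "gene"))
  trials <- read_kb_table(directory, "trials",
                          c("trial_id", "title", "predicate", "cancer_types", "open", "location"))
  risk_genes <- read_kb_table(directory, "risk_genes", c("panel", "gene"))
  gene_loci <- read_kb_table(directory, "gene_loci",
                             c("gene", "chrom", "start", "end", "cds_start"))

  hotspot_path <- file.path(directory, "panel_hotspots.bed")
  hotspots <- NULL
  if (file.exists(hotspot_path)) {
    hotspots <- utils::read.delim(
      hotspot_path, header = FALSE, stringsAsFactors = FALSE, comment.char = "#",
      col.names = c("chrom", "start", "end", "name")
    )
    # BED is 0-based half-open; convert to 1-based inclusive
    hotspots$start <- hotspots$start + 1L
    nm <- strsplit(hotspots$name, "|", fixed = TRUE)
    hotspots$panel <- vapply(nm, `[`, character(1), 1)
    hotspots$gene <- vapply(nm, function(x) if (length(x) > 1) x[2] else NA_character_, character(1))
  }

  # parse every predicate now so malformed rules fail at load with their id
  check_predicates <- function(df, id_col) {
    for (i in seq_len(nrow(df))) {
      tryCatch(parse_predicate(df$predicate[i]), error = function(e) {
        stopf("rule %s: %s", df[[id_col]][i], conditionMessage(e))
      })
    }
  }
  check_predicates(drug_rules, "rule_id")
  check_predicates(toxicity_rules, "rule_id")
  check_predicates(prognostic, "marker_id")
  check_predicates(trials, "trial_id")

  # cross-validation: drug-rule genes should be known somewhere
  rule_genes <- unique(unlist(lapply(drug_rules$predicate, function(p) {
    vapply(unlist(parse_predicate(p), recursive = FALSE), `[[`, character(1), "gene")
  })))
  known <- unique(c(gene_cancer$gene, pathways_df$gene, gene_roles$gene))
  orphan <- setdiff(rule_genes, known)
  if (length(orphan) > 0) {
    warnf("drug rules reference gene(s) absent from associations and pathways: %s",
          paste(sort(orphan), collapse = ", "))
  }

  # panel definitions
  if (!all(panels_meta$mode %in% c("hotspot", "full_gene", "full_gene_plus_cna"))) {
    stopf("panels: mode must be hotspot/full_gene/full_gene_plus_cna")
  }
  panels <- lapply(seq_len(nrow(panels_meta)), function(i) {
    p <- panels_meta[i, ]
    hs <- if (!is.null(hotspots)) hotspots[hotspots$panel == p$panel, , drop = FALSE] else NULL
    panel_definition(
      name = p$panel, mode = p$mode,
      genes = sort(panel_genes$gene[panel_genes$panel == p$panel]),
      hotspots = if (!is.null(hs) && nrow(hs) > 0) hs[c("chrom", "start", "end", "gene")] else NULL,
      detects_germline = as.logical(p$detects_germline),
      detects_expression = as.logical(p$detects_expression)
    )
  })
  names(panels) <- panels_meta$panel

  sort_by <- function(df, cols) df[do.call(order, df[cols]), , drop = FALSE]
  kb <- structure(list(
    version = version,
    gene_roles = sort_by(gene_roles, "gene"),
    gene_cancer = sort_by(gene_cancer, c("gene", "cancer_type")),
    catalog = sort_by(catalog, c("gene", "protein_change")),
    activating = sort_by(activating, c("gene", "protein_change")),
    drug_rules = sort_by(drug_rules, "rule_id"),
    toxicity_rules = sort_by(toxicity_rules, "rule_id"),
    prognostic = sort_by(prognostic, "marker_id"),
    pathways = sort_by(pathways_df, c("pathway", "gene")),
    drug_targets = sort_by(drug_targets, c("drug", "target")),
    feedback_pairs = feedback_pairs,
    panels = panels,
    trials = sort_by(trials, "trial_id"),
    risk_genes = sort_by(risk_genes, c("panel", "gene")),
    gene_loci = sort_by(gene_loci, "gene")
  ), class = "knowledge_base")
  rownames(kb$gene_roles) <- rownames(kb$gene_cancer) <- rownames(kb$catalog) <- NULL
  kb
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf(
    "<knowledge_base %s>: %d gene-cancer associations, %d drug rules, %d toxicity rules,\n  %d prognostic markers, %d pathways, %d panels, %d trials\n",
    x$version, nrow(x$gene_cancer), nrow(x$drug_rules), nrow(x$toxicity_rules),
    nrow(x$prognostic), length(unique(x$pathways$pathway)), length(x$panels),
    nrow(x$trials)
  ))
  invisible(x)
}

#' Definition of a targeted cancer panel
#'
#' @param name panel label
#' @param mode "hotspot" (covers recurrent-mutation intervals only),
#'   "full_gene" (all coding mutations in listed genes) or
#'   "full_gene_plus_cna" (additionally reports CNA on listed genes)
#' @param genes character vector of covered genes
#' @param hotspots data.frame (chrom, start, end, gene), 1-based inclusive;
#'   required for hotspot mode
#' @param detects_germline,detects_expression capability flags (DNA panels do
#'   not report expression)
#' @return object of class `panel_definition`
#' @export
panel_definition <- function(name, mode, genes, hotspots = NULL,
                             detects_germline = FALSE, detects_expression = FALSE) {
  mode <- match.arg(mode, c("hotspot", "full_gene", "full_gene_plus_cna"))
  if (mode == "hotspot" && (is.null(hotspots) || nrow(hotspots) == 0)) {
    stopf("hotspot panel '%s' requires hotspot intervals", name)
  }
  if (isTRUE(detects_expression)) {
    stopf("DNA panel '%s' cannot detect expression", name)
  }
  structure(list(
    name = name, mode = mode, genes = toupper(genes), hotspots = hotspots,
    detects_germline = isTRUE(detects_germline),
    detects_expression = isTRUE(detects_expression)
  ), class = "panel_definition")
}

## ---- alteration classification ---------------------------------------------

gene_role <- function(kb, gene) {
  r <- kb$gene_roles$role[match(gene, kb$gene_roles$gene)]
  ifelse(is.na(r), "other", r)
}

#' Is a somatic protein change activating / inactivating?
#'
#' Activating: listed in the curated per-gene activating table, or a recurrent
#' catalog change in an oncogene. Inactivating: a truncating change
#' (nonsense/frameshift/splice) in a tumor suppressor, or a catalog change in a
#' tumor suppressor.
#'
#' @param kb a `knowledge_base`
#' @param gene,protein_change,consequence vectors describing the changes
#' @return logical vector
#' @export
is_activating <- function(kb, gene, protein_change, consequence = NULL) {
  gene <- toupper(gene)
  pc <- normalize_protein_change(protein_change)
  listed <- paste(gene, pc) %in% paste(kb$activating$gene, kb$activating$protein_change)
  in_catalog <- paste(gene, pc) %in% paste(kb$catalog$gene, kb$catalog$protein_change)
  listed | (gene_role(kb, gene) == "oncogene" & in_catalog)
}

#' @rdname is_activating
#' @export
is_inactivating <- function(kb, gene, protein_change, consequence = NULL) {
  gene <- toupper(gene)
  pc <- normalize_protein_change(protein_change)
  ts <- gene_role(kb, gene) == "tumor_suppressor"
  in_catalog <- paste(gene, pc) %in% paste(kb$catalog$gene, kb$catalog$protein_change)
  ts & (is_truncating_change(pc, consequence) | in_catalog)
}

# Which genes does a CNA segment table hit (gain/loss calls only)?
cna_gene_events <- function(cna, kb, calls = c("gain", "loss")) {
  if (nrow(cna) == 0) return(data.frame(gene = character(), call = character()))
  loci <- kb$gene_loci
  hits <- lapply(seq_len(nrow(cna)), function(i) {
    s <- cna[i, ]
    if (!s$call %in% calls) return(NULL)
    sel <- loci$chrom == s$chrom & loci$start <= s$end & loci$end >= s$start
    if (!any(sel)) return(NULL)
    data.frame(gene = loci$gene[sel], call = s$call, seg = i, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(gene = character(), call = character(), seg = integer()) else out
}

## ---- predicate evaluation ---------------------------------------------------

match_clause <- function(clause, profile, kb) {
  g <- clause$gene; cls <- clause$class; arg <- clause$arg
  alt_row <- function(gene, source, detail) {
    data.frame(gene = gene, source = source, detail = detail, class = cls,
               stringsAsFactors = FALSE)
  }
  switch(cls,
    somatic_activating = {
      s <- profile$somatic
      sel <- s$gene == g & is_activating(kb, s$gene, s$protein_change, s$consequence)
      if (any(sel)) alt_row(g, "somatic", s$protein_change[sel]) else NULL
    },
    somatic_inactivating = {
      s <- profile$somatic
      sel <- s$gene == g & is_inactivating(kb, s$gene, s$protein_change, s$consequence)
      if (any(sel)) alt_row(g, "somatic", s$protein_change[sel]) else NULL
    },
    specific_protein_change = {
      s <- profile$somatic
      sel <- s$gene == g & normalize_protein_change(s$protein_change) == normalize_protein_change(arg)
      if (any(sel)) alt_row(g, "somatic", s$protein_change[sel]) else NULL
    },
    cna_gain = ,
    cna_loss = {
      want <- if (cls == "cna_gain") "gain" else "loss"
      ev <- cna_gene_events(profile$cna, kb, calls = want)
      ev <- ev[ev$gene == g, , drop = FALSE]
      if (nrow(ev) > 0) alt_row(g, "cna", ev$call) else NULL
    },
    germline_variant = {
      gl <- profile$germline
      sel <- gl$gene == g
      if (!is.na(arg)) sel <- sel & normalize_protein_change(gl$protein_change) == normalize_protein_change(arg)
      if (any(sel)) alt_row(g, "germline", gl$protein_change[sel]) else NULL
    },
    expression_high = ,
    expression_low = {
      want <- if (cls == "expression_high") "high" else "low"
      e <- profile$expression
      sel <- e$gene == g & e$level == want
      if (!is.na(arg)) {
        thr <- suppressWarnings(as.numeric(arg))
        if (!is.na(thr)) sel <- sel & !is.na(e$fold_change) & e$fold_change >= thr
      }
      if (any(sel)) alt_row(g, "expression", e$level[sel]) else NULL
    },
    stopf("predicate names unsupported alteration class '%s'", cls)
  )
}

#' Evaluate a biomarker predicate against a patient profile
#'
#' Matching is conjunctive within an alternative and disjunctive across the
#' `" OR "`-separated alternatives: an alternative matches only when every one
#' of its clauses matches, and the union of matched alterations over all
#' matching alternatives is returned.
#'
#' @param predicate predicate string or parsed predicate (see [parse_predicate()])
#' @param profile a `patient_profile`
#' @param kb a `knowledge_base`
#' @return data.frame of matched alterations (gene, source, detail, class);
#'   zero rows when the predicate does not match
#' @export
evaluate_predicate <- function(predicate, profile, kb) {
  parsed <- if (is.character(predicate)) parse_predicate(predicate) else predicate
  empty <- data.frame(gene = character(), source = character(),
                      detail = character(), class = character(),
                      stringsAsFactors = FALSE)
  matches <- list()
  for (alt in parsed) {
    clause_hits <- lapply(alt, match_clause, profile = profile, kb = kb)
    if (all(!vapply(clause_hits, is.null, logical(1)))) {
      matches <- c(matches, clause_hits)
    }
  }
  if (length(matches) == 0) return(empty)
  out <- unique(do.call(rbind, matches))
  rownames(out) <- NULL
  out
}
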