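# Seeded cohort generators and the in-code study cohorts, so every pipeline
# stage is testable offline. Genomic coordinates are synthetic but stable: each
# gene has a fixed locus and CDS anchor, and the position of codon c is
# cds_start + 3*(c-1). The EGFR anchor is chosen so that codon 587 falls at
# chr7:55233009, the printed coordinate of the case-study mutation.

#' Synthetic gene loci shipped with the package
#' @param kb_dir knowledge-base directory (defaults to the packaged mini-KB)
#' @return data.frame (gene, chrom, start, end, cds_start, protein_len)
#' @export
default_gene_loci <- function(kb_dir = default_kb_dir()) {
  read_kb_table(kb_dir, "gene_loci", c("gene", "chrom", "start", "end", "cds_start"))
}

#' Path of the packaged synthetic mini knowledge base
#' @export
default_kb_dir <- function() {
  system.file("extdata", "kb_synthetic", package = "oncointerp")
}

#' Genomic position of a codon under the synthetic gene model
#' @param gene gene symbol
#' @param codon codon number (1-based)
#' @param loci gene-locus table (see [default_gene_loci()])
#' @return list(chrom, pos) of the codon's first base
#' @export
codon_pos <- function(gene, codon, loci = default_gene_loci()) {
  i <- match(toupper(gene), loci$gene)
  if (is.na(i)) stopf("no locus for gene %s", gene)
  list(chrom = loci$chrom[i], pos = as.integer(loci$cds_start[i] + 3L * (codon - 1L)))
}

# parse the codon number out of an HGVS p. string ("p.G12V" -> 12,
# "p.E1309fs*4" -> 1309, "p.S635_L636fs" -> 635); splice markers -> NA
pc_codon <- function(protein_change) {
  m <- regmatches(protein_change, regexpr("[0-9]+", protein_change))
  if (length(m) == 0) NA_integer_ else as.integer(m)
}

# deterministic (ref, alt) pair for a substitution class
PAIR_FOR_CLASS <- list(
  "C>A" = list(c("C", "A"), c("G", "T")),
  "C>G" = list(c("C", "G"), c("G", "C")),
  "C>T" = list(c("C", "T"), c("G", "A")),
  "T>A" = list(c("T", "A"), c("A", "T")),
  "T>C" = list(c("T", "C"), c("A", "G")),
  "T>G" = list(c("T", "G"), c("A", "C"))
)

# build one somatic variant row for a gene + protein change at the synthetic
# locus; splice markers sit 10 bp upstream of the CDS anchor
fixture_somatic <- function(gene, protein_change, loci,
                            depth_alt = 30L, depth_total = 100L,
                            tumor_id = "T1", consequence = NA_character_) {
  if (grepl("splice", protein_change, ignore.case = TRUE)) {
    i <- match(toupper(gene), loci$gene)
    chrom <- loci$chrom[i]; pos <- as.integer(loci$cds_start[i] - 10L)
    ref <- "G"; alt <- "A"
    consequence <- "splice_site"
  } else {
    cp <- codon_pos(gene, pc_codon(protein_change), loci)
    chrom <- cp$chrom; pos <- cp$pos
    if (grepl("fs", protein_change, fixed = TRUE)) {
      ref <- "CT"; alt <- "C"
    } else {
      ref <- "G"; alt <- "A"
    }
  }
  somatic_variants(
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
    protein_change = protein_change, consequence = consequence,
    depth_alt = depth_alt, depth_total = depth_total, tumor_id = tumor_id
  )
}

fixture_cna <- function(gene, call, loci, platform = "wes") {
  i <- match(toupper(gene), loci$gene)
  if (is.na(i)) stopf("no locus for gene %s", gene)
  cna_segments(
    chrom = loci$chrom[i],
    start = max(1L, loci$start[i] - 100000L), end = loci$end[i] + 100000L,
    log2ratio = if (call == "gain") 0.9 else -1.0,
    log2mBAF = 0.3, call = call, platform = platform
  )
}

fixture_germline <- function(gene, protein_change, loci, classification = "pathogenic") {
  cd <- pc_codon(protein_change)
  cp <- codon_pos(gene, if (is.na(cd)) 1L else cd, loci)
  germline_variants(
    chrom = cp$chrom, pos = cp$pos, ref = "C", alt = "T", gene = gene,
    protein_change = protein_change, zygosity = "het",
    classification = classification
  )
}

rbind_or_empty <- function(lst, empty) {
  lst <- Filter(function(x) nrow(x) > 0, lst)
  if (length(lst) == 0) return(empty)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  class(out) <- class(empty)
  out
}

#' The three in-study cohorts plus the case-study patient, as fixtures
#'
#' Encodes the published per-patient alteration tables: five medullary thyroid
#' carcinomas (all RET-altered, somatically or in the germline), nineteen
#' colorectal cancers (per-gene frequencies APC 0.89, KRAS 0.53, NRAS 0.11,
#' BRAF 0.11, PIK3CA 0.11, PTEN 0.11, EGFR 0.05, TP53 0.84), seven breast
#' cancers, and the case-study patient P0015 carrying EGFR p.D587H at
#' chr7:55233009 with 387 of 1998 reads supporting the variant. Where the
#' rendered source table was ambiguous about column boundaries, the per-gene
#' frequency row was taken as authoritative (see the methods vignette).
#'
#' @param loci gene-locus table
#' @return list with elements `mtc` (5 profiles), `colorectal` (19), `breast`
#'   (7) and `p0015` (one profile)
#' @export
table_fixtures <- function(loci = default_gene_loci()) {
  som <- function(...) {
    specs <- list(...)
    rbind_or_empty(lapply(specs, function(s) {
      fixture_somatic(s[[1]], s[[2]], loci)
    }), somatic_variants())
  }
  cna <- function(...) {
    specs <- list(...)
    rbind_or_empty(lapply(specs, function(s) fixture_cna(s[[1]], s[[2]], loci)),
                   cna_segments())
  }
  germ <- function(...) {
    specs <- list(...)
    rbind_or_empty(lapply(specs, function(s) fixture_germline(s[[1]], s[[2]], loci)),
                   germline_variants())
  }
  expr_high <- function(gene, fold) {
    expression_records(gene = gene, tumor_value = fold, normal_value = 1, level = "high")
  }
  expr_level <- function(gene, level) {
    expression_records(gene = gene, tumor_value = if (level == "high") 10 else 0.5,
                       normal_value = NA_real_, level = level)
  }
  pp <- function(id, type, ...) patient_profile(id, type, ...)

  mtc <- list(
    pp("P0010", "MTC",
       germline = germ(list("RET", "p.C634R")),
       cna = cna(list("CDKN2A", "loss"), list("RASA1", "loss"), list("RB1", "loss"))),
    pp("P0029", "MTC", germline = germ(list("RET", "p.C634Y"))),
    pp("P0036", "MTC", somatic = som(list("RET", "p.M918T"))),
    pp("P0041", "MTC", somatic = som(list("RET", "p.M918T"))),
    pp("P0044", "MTC", somatic = som(list("RET", "p.M918T")))
  )

  crc <- list(
    pp("P0004", "colorectal", somatic = som(
      list("APC", "p.E763*"), list("KRAS", "p.G12V"),
      list("PIK3CA", "p.E545K"), list("PIK3CA", "p.M1043I"))),
    pp("P0005", "colorectal", somatic = som(
      list("APC", "p.R554*"), list("KRAS", "p.G12S"), list("TP53", "p.R273H"))),
    pp("P0008", "colorectal", somatic = som(list("BRAF", "p.V600E"))),
    pp("P0009", "colorectal",
       somatic = som(list("APC", "p.E1309fs*4"), list("TP53", "p.P151S")),
       cna = cna(list("EGFR", "gain")),
       expression = rbind_or_empty(list(expr_high("EREG", 113), expr_high("AREG", 29)),
                                   expression_records())),
    pp("P0016", "colorectal", somatic = som(
      list("KRAS", "p.G12V"), list("PIK3CA", "p.E545K"), list("TP53", "p.R248Q"))),
    pp("P0018", "colorectal", somatic = som(
      list("APC", "p.E1309*"), list("APC", "p.V1377fs"), list("KRAS", "p.G13D"),
      list("TP53", "p.G245S"))),
    pp("P0019", "colorectal", somatic = som(
      list("APC", "p.R232*"), list("APC", "p.R1114*"), list("TP53", "p.R333fs*12"))),
    pp("P0020", "colorectal", somatic = som(
      list("APC", "p.T683P"), list("APC", "p.R876*"), list("APC", "p.E1577*"),
      list("KRAS", "p.G13D"), list("TP53", "p.F270I"))),
    pp("P0022", "colorectal", somatic = som(
      list("APC", "p.T1493fs*14"), list("TP53", "p.R248Q"))),
    pp("P0024", "colorectal", somatic = som(
      list("APC", "p.E955*"), list("NRAS", "p.N116H"), list("PTEN", "p.Q61P"),
      list("TP53", "p.S183*"))),
    pp("P0025", "colorectal", somatic = som(
      list("APC", "p.I606fs"), list("APC", "p.R1450*"), list("NRAS", "p.Q61R"),
      list("TP53", "p.R273C"))),
    pp("P0027", "colorectal",
       somatic = som(list("PTEN", "splice_donor"), list("DKK1", "p.S157F"),
                     list("DKK2", "p.R135W"), list("CSNK1A1", "p.D140N"),
                     list("AXIN1", "p.R395*")),
       cna = cna(list("APC", "loss"))),
    pp("P0028", "colorectal", somatic = som(
      list("APC", "splice_donor"), list("APC", "p.Q1067*"), list("TP53", "p.R282W"))),
    pp("P0031", "colorectal", somatic = som(
      list("APC", "p.E1097*"), list("APC", "p.E1397*"), list("KRAS", "p.G12D"),
      list("TP53", "p.G245S"))),
    pp("P0033", "colorectal", somatic = som(
      list("APC", "p.E1306*"), list("KRAS", "p.G13D"), list("TP53", "p.R273C"))),
    pp("P0034", "colorectal", somatic = som(
      list("APC", "p.E1322*"), list("KRAS", "p.G12C"), list("TP53", "p.Y220C"))),
    pp("P0037", "colorectal", somatic = som(
      list("APC", "p.R232*"), list("BRAF", "p.V600E"), list("TP53", "splice_acceptor"))),
    pp("P0043", "colorectal", somatic = som(
      list("APC", "p.F1354fs"), list("APC", "p.S1400*"), list("KRAS", "p.G13D"),
      list("TP53", "p.C176F"))),
    pp("P0046", "colorectal", somatic = som(
      list("APC", "p.R876*"), list("KRAS", "p.G12D"), list("TP53", "p.S127F")))
  )

  breast <- list(
    pp("P0002", "breast",
       somatic = som(list("PIK3CA", "p.E545K"), list("MAP3K1", "p.F1462V")),
       cna = cna(list("CCND1", "gain"), list("FGFR1", "gain")),
       expression = rbind_or_empty(list(expr_level("ESR1", "high"),
                                        expr_level("ERBB2", "low")),
                                   expression_records())),
    pp("P0006", "breast",
       somatic = som(list("PIK3CA", "p.E542K")),
       expression = rbind_or_empty(list(expr_level("ESR1", "high"),
                                        expr_level("ERBB2", "low")),
                                   expression_records())),
    pp("P0007", "breast",
       somatic = som(list("TP53", "p.R213fs")),
       cna = cna(list("CDK1", "gain"), list("RASA1", "loss"))),
    pp("P0013", "breast",
       somatic = som(list("MAP2K4", "p.R110P")),
       germline = germ(list("BRCA1", "p.W1712fs")),
       expression = rbind_or_empty(list(expr_level("ESR1", "low"),
                                        expr_level("ERBB2", "low")),
                                   expression_records())),
    pp("P0030", "breast",
       somatic = som(list("TP53", "p.Y220C")),
       cna = cna(list("NRAS", "gain"))),
    pp("P0040", "breast",
       somatic = som(list("TP53", "p.W95*")),
       cna = cna(list("CCND1", "gain")),
       germline = germ(list("DCLRE1C", "p.S635_L636fs")),
       expression = rbind_or_empty(list(expr_level("ESR1", "high"),
                                        expr_level("ERBB2", "low")),
                                   expression_records())),
    pp("P0042", "breast",
       somatic = som(list("TP53", "p.L194R"), list("NF1", "p.Q1174*")))
  )

  p0015 <- patient_profile(
    "P0015", "unknown_primary",
    somatic = fixture_somatic("EGFR", "p.D587H", loci,
                              depth_alt = 387L, depth_total = 1998L)
  )
  # printed coordinate check: chr7:55233009 G > C
  p0015$somatic$ref <- "G"; p0015$somatic$alt <- "C"

  list(mtc = mtc, colorectal = crc, breast = breast, p0015 = p0015)
}

## ---- seeded cohort generation ----------------------------------------------

#' Configuration for the seeded cohort generator
#'
#' @param n_patients cohort size
#' @param cancer_mix named probability vector over cancer types (sums to 1)
#' @param gene_freqs data.frame (cancer_type, gene, source, freq
#'   `[0,1]`) of per-gene per-type alteration frequencies; source is one of
#'   somatic, cna_gain, cna_loss, germline, expression_high, expression_low;
#'   cancer_type "any" applies to all patients
#' @param actionable_rates optional named vector (somatic, cna, germline,
#'   expression) of mean actionable-event counts per patient; translated into
#'   independent Bernoulli draws over the per-type actionable gene menus
#' @param background_rate_mb named per-type rate of qualifying passenger SNVs
#'   per Mb of coding target
#' @param coding_mb coding target territory in Mb
#' @param passenger_known_gene_frac fraction of passenger SNVs placed in
#'   curated cancer genes (hence tiered 1-3) rather than anonymous background
#'   genes; drives the cancer-relevant mutation count
#' @param spectrum_weights probabilities over the six substitution classes
#'   (C>A, C>G, C>T, T>A, T>C, T>G); must sum to 1
#' @param purity_range min/max of the per-patient uniform purity draw
#' @param depth_mean,depth_size negative-binomial sequencing-depth model
#' @param seed mandatory RNG seed
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(n_patients,
                          cancer_mix = c(colorectal = 1),
                          gene_freqs = NULL,
                          actionable_rates = NULL,
                          background_rate_mb = c(default = 2),
                          coding_mb = 30,
                          passenger_known_gene_frac = 0,
                          spectrum_weights = c(0.10, 0.08, 0.45, 0.07, 0.22, 0.08),
                          purity_range = c(0.2, 0.9),
                          depth_mean = 112, depth_size = 8,
                          seed) {
  if (missing(seed) || is.null(seed)) stopf("cohort_config: seed is mandatory")
  errs <- character()
  if (n_patients < 1) errs <- c(errs, "n_patients must be >= 1")
  if (abs(sum(cancer_mix) - 1) > 1e-8) errs <- c(errs, "cancer_mix must sum to 1")
  if (length(spectrum_weights) != 6 || abs(sum(spectrum_weights) - 1) > 1e-8) {
    errs <- c(errs, "spectrum_weights must be 6 probabilities summing to 1")
  }
  if (!is.null(gene_freqs)) {
    need <- c("cancer_type", "gene", "source", "freq")
    if (!all(need %in% names(gene_freqs))) errs <- c(errs, "gene_freqs needs cancer_type/gene/source/freq")
    else if (any(gene_freqs$freq < 0 | gene_freqs$freq > 1)) errs <- c(errs, "gene_freqs$freq must be in [0,1]")
  }
  if (!is.null(actionable_rates) &&
      !all(names(actionable_rates) %in% c("somatic", "cna", "germline", "expression"))) {
    errs <- c(errs, "actionable_rates names must be somatic/cna/germline/expression")
  }
  if (passenger_known_gene_frac < 0 || passenger_known_gene_frac > 1) {
    errs <- c(errs, "passenger_known_gene_frac must be in [0,1]")
  }
  if (length(errs) > 0) stopf("invalid cohort config: %s", paste(errs, collapse = "; "))
  structure(list(
    n_patients = as.integer(n_patients), cancer_mix = cancer_mix,
    gene_freqs = gene_freqs, actionable_rates = actionable_rates,
    background_rate_mb = background_rate_mb, coding_mb = coding_mb,
    passenger_known_gene_frac = passenger_known_gene_frac,
    spectrum_weights = setNames(spectrum_weights, SUBSTITUTION_CLASSES),
    purity_range = purity_range, depth_mean = depth_mean,
    depth_size = depth_size, seed = as.integer(seed)
  ), class = "cohort_config")
}

# per-gene activating changes the generator draws from (aligned with the
# mini-KB activating table); tumor suppressors get random truncating stops
GENERATOR_CHANGES <- list(
  KRAS = c("p.G12V", "p.G12D", "p.G12C", "p.G12S", "p.G13D"),
  NRAS = c("p.Q61R", "p.Q61P", "p.Q61K", "p.G12D"),
  BRAF = "p.V600E",
  PIK3CA = c("p.E542K", "p.E545K", "p.H1047R", "p.M1043I"),
  RET = c("p.C634R", "p.C634Y", "p.M918T"),
  EGFR = c("p.L858R"),
  ALK = "p.A1200V",
  AKT1 = "p.E17K",
  TP53 = c("p.R273H", "p.R273C", "p.R248Q", "p.G245S", "p.Y220C", "p.R282W")
)

GERMLINE_CHANGES <- c(
  ERCC1 = "p.N118S", ERCC2 = "p.K751Q", ERCC5 = "p.D1104H", XRCC1 = "p.R399Q",
  KDR = "p.Q472H", CXCR2 = "p.R289C", DPYD = "p.D949V", UGT1A1 = "p.G71R",
  BRCA1 = "p.W1712fs", BRCA2 = "p.S1982fs", DCLRE1C = "p.S635_L636fs"
)

# per-cancer-type menus of individually actionable gene x source units under
# the packaged mini-KB; used when actionable_rates is configured
actionable_menus <- function(cancer_type) {
  base <- list(
    somatic = c("PIK3CA", "BRAF"),
    cna = c("FGFR1", "CDK1"),
    germline = c("ERCC1", "ERCC2", "ERCC5", "XRCC1", "KDR", "CXCR2"),
    expression = c("ERBB2", "FLT3", "FGFR1")
  )
  if (cancer_type == "colorectal") {
    base$somatic <- c("KRAS", "NRAS", "BRAF", "PIK3CA", "PTEN")
    base$cna <- c("EGFR", "FGFR1", "CDK1")
  } else if (cancer_type == "breast") {
    base$somatic <- c("PIK3CA", "NF1", "AKT1")
    base$cna <- c("CCND1", "FGFR1", "CDK1", "RASA1")
  } else if (cancer_type == "MTC") {
    base$somatic <- c("RET", "ALK")
    base$cna <- c("CDKN2A", "RB1")
  }
  base
}

#' Default generator configuration: the study conditions
#'
#' Cancer-type mixture 19/46 colorectal, 7/46 breast, 5/46 MTC, 15/46 other;
#' per-gene driver frequencies taken from the published per-cohort alteration
#' tables; germline pharmacogenomic variant frequencies set so the expected
#' actionable germline count is about 2.2 per patient; background passenger
#' SNV rates per Mb set to the published per-type medians (breast 1.4,
#' colorectal 2.7, MTC 0.7; 2.0 for the mixed remainder) over a 30 Mb coding
#' target; depth model centered on 112x (the tumor WES median).
#'
#' @param n_patients cohort size (46, the analyzed study cohort, by default)
#' @param seed RNG seed
#' @return a `cohort_config`
#' @export
default_cohort_config <- function(n_patients = 46, seed) {
  gf <- function(type, gene, source, freq) {
    data.frame(cancer_type = type, gene = gene, source = source, freq = freq,
               stringsAsFactors = FALSE)
  }
  gene_freqs <- rbind(
    gf("colorectal", "APC", "somatic", 0.84),
    gf("colorectal", "APC", "cna_loss", 0.05),
    gf("colorectal", "KRAS", "somatic", 0.53),
    gf("colorectal", "NRAS", "somatic", 0.11),
    gf("colorectal", "BRAF", "somatic", 0.11),
    gf("colorectal", "PIK3CA", "somatic", 0.11),
    gf("colorectal", "PTEN", "somatic", 0.11),
    gf("colorectal", "TP53", "somatic", 0.84),
    gf("colorectal", "EGFR", "cna_gain", 0.05),
    gf("colorectal", "EREG", "expression_high", 0.05),
    gf("colorectal", "AREG", "expression_high", 0.05),
    gf("MTC", "RET", "somatic", 0.6),
    gf("MTC", "RET", "germline", 0.4),
    gf("MTC", "CDKN2A", "cna_loss", 0.2),
    gf("MTC", "RASA1", "cna_loss", 0.2),
    gf("MTC", "RB1", "cna_loss", 0.2),
    gf("breast", "TP53", "somatic", 0.57),
    gf("breast", "PIK3CA", "somatic", 0.29),
    gf("breast", "CCND1", "cna_gain", 0.29),
    gf("breast", "MAP3K1", "somatic", 0.14),
    gf("breast", "NF1", "somatic", 0.14),
    gf("breast", "NRAS", "cna_gain", 0.14),
    gf("breast", "CDK1", "cna_gain", 0.14),
    gf("breast", "RASA1", "cna_loss", 0.14),
    gf("breast", "FGFR1", "cna_gain", 0.14),
    gf("breast", "BRCA1", "germline", 0.14),
    gf("breast", "DCLRE1C", "germline", 0.14),
    gf("breast", "ESR1", "expression_high", 0.43),
    gf("breast", "ERBB2", "expression_low", 0.57),
    gf("other:mixed", "TP53", "somatic", 0.40),
    gf("other:mixed", "KRAS", "somatic", 0.15),
    gf("other:mixed", "PIK3CA", "somatic", 0.15),
    gf("other:mixed", "BRAF", "somatic", 0.10),
    gf("other:mixed", "NF2", "somatic", 0.10),
    gf("other:mixed", "TSC1", "cna_loss", 0.05),
    gf("other:mixed", "ALK", "somatic", 0.05),
    gf("other:mixed", "FLT3", "cna_gain", 0.05),
    gf("other:mixed", "EGFR", "somatic", 0.05),
    # germline pharmacogenomic polymorphisms, all types: 6 x 0.37 ~ 2.2
    gf("any", c("ERCC1", "ERCC2", "ERCC5", "XRCC1", "KDR", "CXCR2"),
       "germline", 0.37)
  )
  cohort_config(
    n_patients = n_patients,
    cancer_mix = c(colorectal = 19 / 46, breast = 7 / 46, MTC = 5 / 46,
                   `other:mixed` = 15 / 46),
    gene_freqs = gene_freqs,
    background_rate_mb = c(colorectal = 2.7, breast = 1.4, MTC = 0.7,
                           `other:mixed` = 2.0, default = 2.0),
    coding_mb = 30,
    # a quarter of passengers fall in curated cancer genes, putting the
    # expected cancer-relevant count per patient in the high teens
    passenger_known_gene_frac = 0.25,
    seed = seed
  )
}

draw_af <- function(n, purity, depth_mean, depth_size) {
  depth <- stats::rnbinom(n, mu = depth_mean, size = depth_size) + 1L
  alt <- stats::rbinom(n, depth, purity / 2)
  alt <- pmax(alt, 1L)  # called variants have at least one supporting read
  list(depth_alt = as.integer(alt), depth_total = as.integer(depth))
}

generate_driver <- function(gene, source, loci, purity, config, role_lookup) {
  if (source == "somatic") {
    if (gene %in% names(GENERATOR_CHANGES)) {
      pc <- sample(GENERATOR_CHANGES[[gene]], 1)
    } else {
      plen <- loci$protein_len[match(gene, loci$gene)]
      plen <- if (is.na(plen)) 400L else plen
      pc <- sprintf("p.R%d*", sample.int(max(plen - 10L, 2L), 1))
    }
    v <- fixture_somatic(gene, pc, loci)
    d <- draw_af(1, purity, config$depth_mean, config$depth_size)
    v$depth_alt <- d$depth_alt; v$depth_total <- d$depth_total
    v$af <- v$depth_alt / v$depth_total
    list(somatic = v)
  } else if (source %in% c("cna_gain", "cna_loss")) {
    list(cna = fixture_cna(gene, sub("cna_", "", source), loci))
  } else if (source == "germline") {
    pc <- GERMLINE_CHANGES[gene]
    if (is.na(pc)) pc <- "p.R100Q"
    list(germline = fixture_germline(gene, unname(pc), loci, classification = "VUS"))
  } else if (source %in% c("expression_high", "expression_low")) {
    lvl <- sub("expression_", "", source)
    fold <- if (lvl == "high") stats::rlnorm(1, log(20), 0.5) else stats::rlnorm(1, log(0.2), 0.3)
    list(expression = expression_records(gene = gene, tumor_value = fold,
                                         normal_value = 1, level = lvl))
  } else stopf("unknown alteration source '%s'", source)
}

# curated genes a passenger can land in (subset of the mini-KB associations;
# random codons, so virtually never a hotspot/catalog change)
PASSENGER_GENE_POOL <- c(
  "APC", "KRAS", "NRAS", "BRAF", "PIK3CA", "PTEN", "TP53", "SMAD4", "AXIN1",
  "EGFR", "CCND1", "MAP3K1", "MAP2K4", "AKT1", "AKT3", "ERBB2", "FGFR1",
  "BRCA1", "BRCA2", "NF1", "ESR1", "RET", "FLT3", "KIT", "VHL", "NF2",
  "TSC1", "ALK", "CDKN2A", "RB1", "CTNNB1"
)

generate_background <- function(n, config, loci, purity) {
  if (n == 0) return(somatic_variants())
  cls <- sample(SUBSTITUTION_CLASSES, n, replace = TRUE,
                prob = config$spectrum_weights)
  pick <- sample.int(2, n, replace = TRUE)
  ra <- t(vapply(seq_len(n), function(i) PAIR_FOR_CLASS[[cls[i]]][[pick[i]]],
                 character(2)))
  d <- draw_af(n, purity, config$depth_mean, config$depth_size)
  known <- stats::runif(n) < config$passenger_known_gene_frac
  gene <- sprintf("BKG%05d", sample.int(99999L, n))
  chrom <- sample(paste0("chr", 1:22), n, replace = TRUE)
  pos <- sample.int(100000000L, n)
  pc <- rep("p.A100V", n)
  if (any(known)) {
    kg <- sample(PASSENGER_GENE_POOL, sum(known), replace = TRUE)
    li <- match(kg, loci$gene)
    codon <- vapply(loci$protein_len[li], function(pl) sample.int(max(pl - 5L, 2L), 1),
                    integer(1))
    gene[known] <- kg
    chrom[known] <- loci$chrom[li]
    pos[known] <- as.integer(loci$cds_start[li] + 3L * (codon - 1L))
    pc[known] <- sprintf("p.A%dV", codon)
  }
  somatic_variants(
    chrom = chrom, pos = pos,
    ref = ra[, 1], alt = ra[, 2],
    gene = gene, protein_change = pc,
    consequence = "missense",
    depth_alt = d$depth_alt, depth_total = d$depth_total
  )
}

#' Generate a seeded synthetic cohort
#'
#' Per patient: a cancer type from the configured mixture; a uniform purity
#' draw; driver alterations by independent Bernoulli draws at the configured
#' per-gene frequencies (oncogenes receive curated hotspot changes, tumor
#' suppressors random truncating stops); passenger SNVs at the configured
#' per-Mb rate with substitution classes drawn from the spectrum weights; every
#' somatic SNV's allelic fraction follows purity/2 with binomial read-depth
#' noise on a negative-binomial depth; optional per-source actionable events
#' over the per-type menus. Fully deterministic given `config$seed`.
#'
#' @param config a `cohort_config`
#' @param loci gene-locus table
#' @return list of `patient_profile` with a `purity` entry in `specimen_meta`
#' @export
generate_cohort <- function(config, loci = default_gene_loci()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  types <- sample(names(config$cancer_mix), config$n_patients, replace = TRUE,
                  prob = config$cancer_mix)
  lapply(seq_len(config$n_patients), function(i) {
    type <- types[i]
    purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
    parts <- list(somatic = list(), germline = list(), cna = list(),
                  expression = list())
    add <- function(ev) {
      for (nm in names(ev)) parts[[nm]][[length(parts[[nm]]) + 1]] <<- ev[[nm]]
    }
    if (!is.null(config$gene_freqs)) {
      rows <- config$gene_freqs[config$gene_freqs$cancer_type %in% c(type, "any"), ,
                                drop = FALSE]
      hit <- stats::runif(nrow(rows)) < rows$freq
      for (j in which(hit)) {
        add(generate_driver(rows$gene[j], rows$source[j], loci, purity, config))
      }
    }
    if (!is.null(config$actionable_rates)) {
      menus <- actionable_menus(type)
      src_map <- c(somatic = "somatic", cna = NA, germline = "germline",
                   expression = "expression_high")
      for (src in names(config$actionable_rates)) {
        menu <- menus[[src]]
        p <- min(1, config$actionable_rates[[src]] / length(menu))
        hit <- stats::runif(length(menu)) < p
        for (g in menu[hit]) {
          source <- if (src == "cna") {
            # menu CNAs: losses for tumor suppressors, gains otherwise
            if (g %in% c("RASA1", "CDKN2A", "RB1", "PTEN")) "cna_loss" else "cna_gain"
          } else src_map[[src]]
          add(generate_driver(g, source, loci, purity, config))
        }
      }
    }
    rate <- unname(config$background_rate_mb[type])
    if (is.na(rate)) rate <- unname(config$background_rate_mb["default"])
    if (is.na(rate)) rate <- unname(config$background_rate_mb[1])
    nbkg <- stats::rpois(1, rate * config$coding_mb)
    bkg <- generate_background(nbkg, config, loci, purity)

    somatic <- rbind_or_empty(c(parts$somatic, list(bkg)), somatic_variants())
    # one event per gene x source unit: drop duplicate driver draws
    somatic <- somatic[!duplicated(paste(somatic$gene, somatic$protein_change,
                                         somatic$tumor_id)), , drop = FALSE]
    patient_profile(
      patient_id = sprintf("SYN%04d", i), cancer_type = type,
      somatic = somatic,
      germline = rbind_or_empty(parts$germline, germline_variants()),
      cna = rbind_or_empty(parts$cna, cna_segments()),
      expression = rbind_or_empty(parts$expression, expression_records()),
      specimen_meta = list(purity = purity, seed = config$seed)
    )
  })
}

## ---- cohort file I/O --------------------------------------------------------

#' Write a cohort to per-patient directories
#'
#' Each patient gets a directory with somatic.vcf, germline.tsv, segments.tsv,
#' expression.tsv and meta.tsv, in the same formats the package readers
#' consume.
#'
#' @param cohort list of `patient_profile`
#' @param dir output directory (created)
#' @return invisibly, `dir`
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort) {
    pd <- file.path(dir, p$patient_id)
    dir.create(pd, showWarnings = FALSE)
    write_somatic_vcf(p$somatic, file.path(pd, "somatic.vcf"))
    utils::write.table(p$germline, file.path(pd, "germline.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_segments_tsv(p$cna, file.path(pd, "segments.tsv"))
    write_expression_tsv(p$expression, file.path(pd, "expression.tsv"))
    meta <- data.frame(key = c("patient_id", "cancer_type"),
                       value = c(p$patient_id, p$cancer_type))
    utils::write.table(meta, file.path(pd, "meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read one patient directory written by [write_cohort()]
#' @param dir patient directory
#' @return a `patient_profile`
#' @export
read_patient_dir <- function(dir) {
  meta_path <- file.path(dir, "meta.tsv")
  if (!file.exists(meta_path)) stopf("no meta.tsv in %s", dir)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  kv <- setNames(meta$value, meta$key)
  gl_path <- file.path(dir, "germline.tsv")
  germline <- if (file.exists(gl_path)) {
    g <- utils::read.delim(gl_path, stringsAsFactors = FALSE,
                           colClasses = c(protein_change = "character"))
    if (nrow(g) == 0) germline_variants() else
      germline_variants(g$chrom, g$pos, g$ref, g$alt, g$gene, g$protein_change,
                        g$zygosity, g$classification)
  } else germline_variants()
  seg_path <- file.path(dir, "segments.tsv")
  expr_path <- file.path(dir, "expression.tsv")
  vcf_path <- file.path(dir, "somatic.vcf")
  patient_profile(
    patient_id = unname(kv["patient_id"]),
    cancer_type = unname(kv["cancer_type"]),
    somatic = if (file.exists(vcf_path)) read_somatic_vcf(vcf_path) else somatic_variants(),
    germline = germline,
    cna = if (file.exists(seg_path)) read_segments_tsv(seg_path) else cna_segments(),
    expression = if (file.exists(expr_path)) read_expression_tsv(expr_path)
                 else expression_records()
  )
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir cohort directory
#' @return list of `patient_profile`
#' @export
read_cohort <- function(dir) {
  subdirs <- sort(list.dirs(dir, recursive = FALSE))
  if (length(subdirs) == 0) stopf("no patient directories under %s", dir)
  lapply(subdirs, read_patient_dir)
}

#' Synthetic expression centroids for nearest-centroid subtype calls
#'
#' A 50-gene, 5-subtype centroid matrix with a fixed seed, standing in for a
#' published intrinsic-subtype centroid set; labels follow the conventional
#' five intrinsic breast cancer subtypes.
#'
#' @param n_genes signature size
#' @param seed RNG seed for the fixed synthetic centroids
#' @return numeric matrix, rows = genes ("SIG001"...), columns = subtypes
#' @export
synthetic_centroids <- function(n_genes = 50, seed = 20260101) {
  labels <- c("luminal A", "luminal B", "HER2 enriched", "basal-like", "normal-like")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * length(labels)), nrow = n_genes,
              dimnames = list(sprintf("SIG%03d", seq_len(n_genes)), labels))
  m
}

# save/restore the global RNG state so fixture helpers do not perturb
# caller-controlled seeding
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
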