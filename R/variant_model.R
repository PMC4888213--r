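# Domain types and readers/writers for somatic/germline variants, copy-number
# segments and expression tables, plus substitution classification and the
# gDNA-mass assay-selection rules.

SOMATIC_COLS <- c(
  "chrom", "pos", "ref", "alt", "gene", "protein_change", "consequence",
  "canonical_isoform", "af", "depth_alt", "depth_total", "tumor_id", "recurrent"
)
CONSEQUENCES <- c(
  "missense", "nonsense", "frameshift", "inframe_indel", "splice_site",
  "synonymous", "other"
)
CNA_CALLS <- c("gain", "loss", "normal", "undecided")

#' Construct a table of somatic variants
#'
#' One row per variant per tumor specimen. Coordinates are 1-based (VCF
#' convention). When read depths are supplied the allelic fraction is
#' `depth_alt / depth_total`.
#'
#' @param chrom,pos,ref,alt core variant description (1-based position)
#' @param gene HGNC-style symbol (upper-cased on construction), "" if unknown
#' @param protein_change HGVS p. notation or "" (splice markers allowed)
#' @param consequence one of missense, nonsense, frameshift, inframe_indel,
#'   splice_site, synonymous, other; inferred from `protein_change` when NA
#' @param canonical_isoform logical, does the change affect the canonical isoform
#' @param af allelic fraction in `[0,1]`; computed from depths when NA
#' @param depth_alt,depth_total supporting / total read counts
#' @param tumor_id specimen label
#' @param recurrent logical, variant seen in >=2 tumor specimens of one patient
#' @return data.frame of class `somatic_variants`
#' @export
somatic_variants <- function(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             gene = "", protein_change = "",
                             consequence = NA_character_,
                             canonical_isoform = TRUE,
                             af = NA_real_, depth_alt = NA_integer_,
                             depth_total = NA_integer_,
                             tumor_id = "T1", recurrent = FALSE) {
  n <- length(pos)
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    gene = toupper(rep_len(as.character(gene), n)),
    protein_change = rep_len(as.character(protein_change), n),
    consequence = rep_len(as.character(consequence), n),
    canonical_isoform = rep_len(as.logical(canonical_isoform), n),
    af = rep_len(as.numeric(af), n),
    depth_alt = rep_len(as.integer(depth_alt), n),
    depth_total = rep_len(as.integer(depth_total), n),
    tumor_id = rep_len(as.character(tumor_id), n),
    recurrent = rep_len(as.logical(recurrent), n),
    stringsAsFactors = FALSE
  )
  miss <- is.na(df$consequence)
  df$consequence[miss] <- consequence_from_protein_change(df$protein_change[miss])
  calc <- is.na(df$af) & !is.na(df$depth_total) & df$depth_total > 0
  df$af[calc] <- df$depth_alt[calc] / df$depth_total[calc]
  validate_somatic(df)
  class(df) <- c("somatic_variants", "data.frame")
  df
}

validate_somatic <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$pos < 1)) stopf("somatic variant positions must be >= 1")
  if (any(df$ref == df$alt)) stopf("somatic variant with alt == ref")
  bad <- !df$consequence %in% CONSEQUENCES
  if (any(bad)) stopf("unknown consequence: %s", paste(unique(df$consequence[bad]), collapse = ", "))
  has_depth <- !is.na(df$depth_total) & df$depth_total > 0 & !is.na(df$af)
  if (any(has_depth)) {
    dev <- abs(df$af[has_depth] - df$depth_alt[has_depth] / df$depth_total[has_depth])
    if (any(dev > 1e-6)) stopf("af inconsistent with depth_alt/depth_total")
  }
  ok_af <- is.na(df$af) | (df$af >= 0 & df$af <= 1)
  if (!all(ok_af)) stopf("allelic fraction outside [0,1]")
  invisible(df)
}

#' Construct a table of germline variants
#' @param chrom,pos,ref,alt,gene,protein_change as in [somatic_variants()]
#' @param zygosity "het" or "hom"
#' @param classification free-text pathogenicity label
#' @return data.frame of class `germline_variants`
#' @export
germline_variants <- function(chrom = character(), pos = integer(),
                              ref = character(), alt = character(),
                              gene = "", protein_change = "",
                              zygosity = "het", classification = "VUS") {
  n <- length(pos)
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    gene = toupper(rep_len(as.character(gene), n)),
    protein_change = rep_len(as.character(protein_change), n),
    zygosity = rep_len(as.character(zygosity), n),
    classification = rep_len(as.character(classification), n),
    stringsAsFactors = FALSE
  )
  if (nrow(df) > 0) {
    if (any(df$pos < 1)) stopf("germline variant positions must be >= 1")
    if (any(df$ref == df$alt)) stopf("germline variant with alt == ref")
    if (!all(df$zygosity %in% c("het", "hom"))) stopf("zygosity must be het or hom")
  }
  class(df) <- c("germline_variants", "data.frame")
  df
}

#' Construct a table of copy-number segments
#'
#' Segments carry the median log2 tumor/normal copy ratio (`log2ratio`) and the
#' median mirrored-B-allele-frequency statistic (`log2mBAF`) plus a four-state
#' call: gain, loss, normal (no CNA), undecided (unclear change).
#'
#' @param chrom,start,end 1-based inclusive segment coordinates
#' @param log2ratio,log2mBAF per-segment summary statistics
#' @param call one of gain, loss, normal, undecided
#' @param platform "wes" or "array"
#' @param tissue_source "ffpe", "frozen" or "unknown"
#' @return data.frame of class `cna_segments`
#' @export
cna_segments <- function(chrom = character(), start = integer(), end = integer(),
                         log2ratio = NA_real_, log2mBAF = NA_real_,
                         call = "undecided", platform = "wes",
                         tissue_source = "unknown") {
  n <- length(start)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    log2ratio = rep_len(as.numeric(log2ratio), n),
    log2mBAF = rep_len(as.numeric(log2mBAF), n),
    call = rep_len(as.character(call), n),
    platform = rep_len(as.character(platform), n),
    tissue_source = rep_len(as.character(tissue_source), n),
    stringsAsFactors = FALSE
  )
  if (nrow(df) > 0) {
    if (any(df$start > df$end)) stopf("CNA segment with start > end")
    if (!all(df$call %in% CNA_CALLS)) stopf("CNA call must be one of %s", paste(CNA_CALLS, collapse = "/"))
    if (!all(df$platform %in% c("wes", "array"))) stopf("platform must be wes or array")
  }
  class(df) <- c("cna_segments", "data.frame")
  df
}

#' Construct a table of gene-expression records
#' @param gene gene symbols
#' @param tumor_value normalized tumor expression (arbitrary units)
#' @param normal_value matched-normal/reference expression, optional (NA)
#' @param level "high", "low" or "unknown" relative to a reference distribution
#' @return data.frame of class `expression_records`; `fold_change` is
#'   tumor/normal where the normal value is present and positive
#' @export
expression_records <- function(gene = character(), tumor_value = numeric(),
                               normal_value = NA_real_, level = "unknown") {
  n <- length(gene)
  df <- data.frame(
    gene = toupper(as.character(gene)),
    tumor_value = as.numeric(tumor_value),
    normal_value = rep_len(as.numeric(normal_value), n),
    level = rep_len(as.character(level), n),
    stringsAsFactors = FALSE
  )
  df$fold_change <- ifelse(
    !is.na(df$normal_value) & df$normal_value > 0,
    df$tumor_value / df$normal_value, NA_real_
  )
  if (nrow(df) > 0) {
    if (!all(df$level %in% c("high", "low", "intermediate", "unknown"))) {
      stopf("expression level must be high/low/intermediate/unknown")
    }
    fc <- df$fold_change[!is.na(df$fold_change)]
    if (any(fc <= 0)) stopf("fold_change must be > 0 when defined")
  }
  df <- df[, c("gene", "tumor_value", "normal_value", "fold_change", "level")]
  class(df) <- c("expression_records", "data.frame")
  df
}

#' Assemble a patient profile
#'
#' The unit of analysis: one patient's somatic and germline variants,
#' copy-number segments and expression records under a cancer-type label.
#'
#' @param patient_id unique patient label
#' @param cancer_type controlled-vocabulary label (e.g. "colorectal",
#'   "breast", "MTC", "unknown_primary", or "other:<name>")
#' @param somatic,germline,cna,expression component tables (see constructors)
#' @param specimen_meta free-form list of tissue/source annotations
#' @return object of class `patient_profile`
#' @export
patient_profile <- function(patient_id, cancer_type,
                            somatic = somatic_variants(),
                            germline = germline_variants(),
                            cna = cna_segments(),
                            expression = expression_records(),
                            specimen_meta = list()) {
  stopifnot(is.character(patient_id), nchar(patient_id) > 0)
  if (!nzchar(cancer_type)) stopf("cancer_type must be non-empty")
  structure(
    list(
      patient_id = patient_id, cancer_type = cancer_type,
      somatic = somatic, germline = germline, cna = cna,
      expression = expression, specimen_meta = specimen_meta
    ),
    class = "patient_profile"
  )
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf(
    "<patient_profile> %s (%s): %d somatic, %d germline, %d CNA segments, %d expression records\n",
    x$patient_id, x$cancer_type, nrow(x$somatic), nrow(x$germline),
    nrow(x$cna), nrow(x$expression)
  ))
  invisible(x)
}

## ---- substitution classification -------------------------------------------

#' Classify a single-base substitution into the six pyrimidine-convention classes
#'
#' SNVs are summarized by the change of the pyrimidine member of the base pair:
#' C>A, C>G, C>T, T>A, T>C, T>G. Purine-reference pairs are reverse-complemented
#' onto this convention, so G>A is reported as C>T (a C:G > T:A transition).
#'
#' @param ref,alt single reference/alternate bases (vectors recycled together)
#' @return character vector of substitution classes
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (length(ref) != length(alt)) stopf("ref and alt must have equal length")
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases)) {
    stopf("classify_substitution requires single A/C/G/T bases (no indels or ambiguity codes)")
  }
  if (any(ref == alt)) stopf("ref and alt must differ")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, comp[ref], ref)
  a <- ifelse(flip, comp[alt], alt)
  paste0(r, ">", a)
}

#: the six classes in conventional display order
SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

## ---- assay selection -------------------------------------------------------

#' Select genomic assays from gDNA mass and frozen-tissue availability
#'
#' Encodes the study's assay-selection rules: the targeted panel always runs;
#' WES additionally runs when both normal and tumor gDNA masses are at least
#' 1.5 ug; the SNP array additionally runs when both exceed 2.5 ug. Tumor
#' RNA-Seq requires frozen tumor tissue; adjacent-normal RNA-Seq additionally
#' requires frozen adjacent normal tissue.
#'
#' @param gdna_mass_normal,gdna_mass_tumor double-stranded gDNA mass in ug
#' @param frozen_tumor_available,frozen_adjacent_normal_available logical flags
#' @return character vector, subset of
#'   `c("panel","wes","array","rnaseq_tumor","rnaseq_normal")`
#' @export
select_assays <- function(gdna_mass_normal, gdna_mass_tumor,
                          frozen_tumor_available = FALSE,
                          frozen_adjacent_normal_available = FALSE) {
  if (gdna_mass_normal < 0 || gdna_mass_tumor < 0) stopf("gDNA mass must be >= 0")
  assays <- "panel"
  if (gdna_mass_normal >= 1.5 && gdna_mass_tumor >= 1.5) assays <- c(assays, "wes")
  if (gdna_mass_normal > 2.5 && gdna_mass_tumor > 2.5) assays <- c(assays, "array")
  if (isTRUE(frozen_tumor_available)) assays <- c(assays, "rnaseq_tumor")
  if (isTRUE(frozen_tumor_available) && isTRUE(frozen_adjacent_normal_available)) {
    assays <- c(assays, "rnaseq_normal")
  }
  assays
}

## ---- VCF I/O ---------------------------------------------------------------

#' Write somatic variants to a VCF 4.2 file
#'
#' Emits one record per site with per-tumor genotype columns (multi-sample when
#' the variant table carries several tumor specimens). Annotations travel in
#' INFO keys `GENE`, `PCHANGE`, `CSQ` and `CANON`; depths in FORMAT `AD`/`DP`.
#'
#' @param variants a `somatic_variants` table
#' @param path output file path (plain text)
#' @param sample_ids optional explicit sample column order
#' @return invisibly, the path
#' @export
write_somatic_vcf <- function(variants, path, sample_ids = NULL) {
  samples <- sample_ids %||% unique(variants$tumor_id)
  if (nrow(variants) > 0 && !all(variants$tumor_id %in% samples)) {
    stopf("variants carry tumor_id values missing from sample_ids")
  }
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = "\r")
  sites <- variants[!duplicated(key), c("chrom", "pos", "ref", "alt", "gene",
                                        "protein_change", "consequence",
                                        "canonical_isoform"), drop = FALSE]
  ukey <- key[!duplicated(key)]
  ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt, method = "radix")
  sites <- sites[ord, , drop = FALSE]; ukey <- ukey[ord]

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=oncointerp",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"HGVS p. change\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=CANON,Number=1,Type=Integer,Description=\"Canonical isoform flag\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )

  body <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    info <- sprintf(
      "GENE=%s;PCHANGE=%s;CSQ=%s;CANON=%d",
      ifelse(nzchar(s$gene), s$gene, "."),
      ifelse(nzchar(s$protein_change), gsub("[; ]", "_", s$protein_change), "."),
      s$consequence, as.integer(s$canonical_isoform)
    )
    cells <- vapply(samples, function(sm) {
      j <- which(key == ukey[i] & variants$tumor_id == sm)
      if (length(j) == 0) return("./.:.:.")
      v <- variants[j[1], ]
      da <- v$depth_alt; dt <- v$depth_total
      if (is.na(da) || is.na(dt)) {
        sprintf("0/1:.:.")
      } else {
        sprintf("0/1:%d,%d:%d", dt - da, da, dt)
      }
    }, character(1))
    paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", info, "GT:AD:DP",
            cells), collapse = "\t")
  }, character(1))

  writeLines(c(header, body), path)
  invisible(path)
}

#' Read somatic variants from a VCF 4.x file
#'
#' Returns one record per variant per tumor sample in which it is called. In
#' multi-sample (multi-tumor) files the `recurrent` flag is set for variants
#' called in two or more tumor specimens of the file. Gene and protein-change
#' annotations are taken from INFO keys `GENE`/`PCHANGE` (with `CSQ`/`CANON`)
#' when present and left empty otherwise. Records whose FILTER is neither PASS
#' nor "." (e.g. rejected during manual review) are dropped unless
#' `keep_filtered = TRUE`.
#'
#' @param path VCF file (plain or gzipped)
#' @param sample_map optional named character vector renaming VCF sample
#'   columns to tumor labels; names must exist among the file's samples
#' @param keep_filtered keep non-PASS records?
#' @return a `somatic_variants` table
#' @export
read_somatic_vcf <- function(path, sample_map = NULL, keep_filtered = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)  # single-record files come back as a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(somatic_variants())
  keep <- keep_filtered | is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  samples <- colnames(gt)
  if (!is.null(sample_map)) {
    unknown <- setdiff(names(sample_map), samples)
    if (length(unknown) > 0) {
      stopf("sample_map names unknown sample label(s): %s", paste(unknown, collapse = ", "))
    }
  }
  info_get <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  gene <- info_get("GENE"); pchg <- info_get("PCHANGE")
  csq <- info_get("CSQ"); canon <- info_get("CANON")

  called <- !is.na(gt) & !gt %in% c("./.", ".", "0/0", "0|0")
  n_called <- rowSums(called)

  out <- list()
  for (sm in samples) {
    idx <- which(keep & called[, sm])
    if (length(idx) == 0) next
    da <- dt <- rep(NA_integer_, length(idx))
    if (!is.null(ad)) {
      parts <- strsplit(ifelse(is.na(ad[idx, sm]), ".", ad[idx, sm]), ",", fixed = TRUE)
      da <- vapply(parts, function(p) {
        if (length(p) >= 2) suppressWarnings(as.integer(p[2])) else NA_integer_
      }, integer(1))
      dref <- vapply(parts, function(p) {
        if (length(p) >= 1) suppressWarnings(as.integer(p[1])) else NA_integer_
      }, integer(1))
      dt <- ifelse(is.na(da) | is.na(dref), NA_integer_, da + dref)
    }
    label <- if (!is.null(sample_map) && sm %in% names(sample_map)) sample_map[[sm]] else sm
    g <- gene[idx]; p <- pchg[idx]
    out[[sm]] <- somatic_variants(
      chrom = fix$CHROM[idx], pos = as.integer(fix$POS[idx]),
      ref = fix$REF[idx], alt = fix$ALT[idx],
      gene = ifelse(is.na(g) | g == ".", "", g),
      protein_change = ifelse(is.na(p) | p == ".", "", p),
      consequence = ifelse(is.na(csq[idx]) | csq[idx] == ".", NA_character_, csq[idx]),
      canonical_isoform = ifelse(is.na(canon[idx]), TRUE, canon[idx] == "1"),
      depth_alt = da, depth_total = dt,
      tumor_id = label,
      recurrent = length(samples) > 1 & n_called[idx] >= 2
    )
  }
  if (length(out) == 0) return(somatic_variants())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("somatic_variants", "data.frame")
  res
}

## ---- segment and expression TSV I/O ----------------------------------------

#' Read copy-number segments from a tab-separated file
#'
#' Expects columns chrom, start, end, log2ratio, log2mBAF, call (and optional
#' platform, tissue_source). Coordinates are taken as 1-based inclusive; pass
#' `bed_coords = TRUE` for BED-style half-open 0-based input.
#'
#' @param path TSV file
#' @param platform,tissue_source defaults used when the file lacks the columns
#' @param bed_coords input uses BED coordinate convention?
#' @return a `cna_segments` table
#' @export
read_segments_tsv <- function(path, platform = "wes", tissue_source = "unknown",
                              bed_coords = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("chrom", "start", "end", "log2ratio", "log2mBAF", "call")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stopf("segment table %s missing column(s): %s", path, paste(miss, collapse = ", "))
  start <- df$start; if (bed_coords) start <- start + 1L
  cna_segments(
    chrom = df$chrom, start = start, end = df$end,
    log2ratio = df$log2ratio, log2mBAF = df$log2mBAF, call = df$call,
    platform = if ("platform" %in% names(df)) df$platform else platform,
    tissue_source = if ("tissue_source" %in% names(df)) df$tissue_source else tissue_source
  )
}

#' Write copy-number segments to TSV
#' @param segments a `cna_segments` table
#' @param path output path
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-level expression table (gene, tumor_value, normal_value)
#' @param path TSV file; `normal_value` optional
#' @param level optional precomputed level column name in the file
#' @return an `expression_records` table
#' @export
read_expression_tsv <- function(path, level = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene", "tumor_value") %in% names(df))) {
    stopf("expression table %s needs columns gene, tumor_value", path)
  }
  expression_records(
    gene = df$gene, tumor_value = df$tumor_value,
    normal_value = if ("normal_value" %in% names(df)) df$normal_value else NA_real_,
    level = if (!is.null(level) && level %in% names(df)) df[[level]]
            else if ("level" %in% names(df)) df$level else "unknown"
  )
}

#' Write an expression table to TSV
#' @param expression an `expression_records` table
#' @param path output path
#' @export
write_expression_tsv <- function(expression, path) {
  utils::write.table(expression, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
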