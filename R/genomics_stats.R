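# Per-tumor and cohort statistics: mutation frequency per megabase, six-class
# substitution spectrum, purity from the somatic allelic-fraction distribution,
# CNA-expression support, cross-platform CNA concordance on a break-union
# genome partition with length-weighted Pearson correlation, KS comparison,
# expression level calls, fold changes and nearest-centroid subtyping.

is_snv <- function(variants) {
  nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref %in% c("A", "C", "G", "T") & variants$alt %in% c("A", "C", "G", "T")
}

#' Somatic mutation frequency per megabase
#'
#' Counts non-synonymous SNVs and SNVs altering canonical splice sites
#' (consequence missense, nonsense or splice_site) whose functional impact is
#' in the canonical protein isoform, divided by the coding target territory in
#' megabases.
#'
#' @param variants a `somatic_variants` table
#' @param coding_target_mb coding exon territory of the capture design, in Mb.
#'   The default of 30 Mb is a configuration value; substitute the actual
#'   design's territory when known.
#' @return mutations per Mb
#' @export
mutation_frequency <- function(variants, coding_target_mb = 30) {
  if (coding_target_mb <= 0) stopf("coding_target_mb must be > 0")
  qual <- is_snv(variants) &
    variants$consequence %in% c("missense", "nonsense", "splice_site") &
    variants$canonical_isoform
  sum(qual) / coding_target_mb
}

#' Six-class substitution spectrum of a tumor
#'
#' Single-nucleotide variants only (indels are excluded from the total); each
#' SNV is assigned to one of the six pyrimidine-convention classes via
#' [classify_substitution()].
#'
#' @param variants a `somatic_variants` table
#' @return list of class `spectrum_profile` with `counts`, `fractions` (sum to
#'   1 when `total > 0`) and `total`
#' @export
spectrum <- function(variants) {
  snv <- variants[is_snv(variants), , drop = FALSE]
  counts <- setNames(integer(6), SUBSTITUTION_CLASSES)
  if (nrow(snv) > 0) {
    cls <- classify_substitution(snv$ref, snv$alt)
    tab <- table(factor(cls, levels = SUBSTITUTION_CLASSES))
    counts[] <- as.integer(tab)
  }
  total <- sum(counts)
  structure(list(
    counts = counts,
    fractions = if (total > 0) counts / total else setNames(rep(NA_real_, 6), SUBSTITUTION_CLASSES),
    total = total
  ), class = "spectrum_profile")
}

#' @export
print.spectrum_profile <- function(x, ...) {
  cat("<spectrum_profile>", x$total, "SNVs\n")
  print(round(x$fractions, 3))
  invisible(x)
}

# exact 1-D two-cluster split: minimize total within-cluster sum of squares
# over all n-1 split points of the sorted sample; returns indices of the upper
# cluster (all points when the sample is constant).
split_1d_two_clusters <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 2 || stats::var(x) == 0) return(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  k <- seq_len(n - 1)
  ss_lo <- cs2[k] - cs[k]^2 / k
  ss_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  kbest <- which.min(ss_lo + ss_hi)
  x[(kbest + 1):n]
}

#' Estimate tumor purity from the somatic allelic-fraction distribution
#'
#' Under a diploid-heterozygous model a clonal somatic variant has expected
#' allelic fraction purity/2, so purity is estimated as `min(1, 2 * median)` of
#' the upper (clonal) AF cluster found by an exact 1-D two-cluster split of the
#' AF distribution. Tumors estimated below 5% purity are flagged `low_purity`;
#' estimates from fewer than 10 AFs are flagged unreliable.
#'
#' @param afs numeric vector of somatic allelic fractions in `[0,1]`
#' @return list of class `purity_estimate`: `purity`, `low_purity`, `reliable`, `n`
#' @export
estimate_purity <- function(afs) {
  afs <- afs[!is.na(afs)]
  if (length(afs) == 0) stopf("estimate_purity requires at least one allelic fraction")
  if (any(afs < 0 | afs > 1)) stopf("allelic fractions must lie in [0,1]")
  upper <- split_1d_two_clusters(afs)
  purity <- min(1, 2 * stats::median(upper))
  structure(list(
    purity = purity,
    low_purity = purity < 0.05,
    reliable = length(afs) >= 10,
    n = length(afs)
  ), class = "purity_estimate")
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat(sprintf("<purity_estimate> %.3f (n=%d%s%s)\n", x$purity, x$n,
              if (x$low_purity) ", LOW PURITY" else "",
              if (!x$reliable) ", unreliable" else ""))
  invisible(x)
}

#' Is a copy-number call supported by gene expression?
#'
#' A gain supported by high expression, or a loss supported by low expression,
#' is `"supported"`; an available-but-contradicting expression level is
#' `"unsupported"`; missing expression, an unknown level, or a normal/undecided
#' call is `"untestable"`. When the segment carries no call, one is derived
#' from `log2ratio` at `+/- gain_log2_min`.
#'
#' @param segment one-row `cna_segments` table
#' @param expr one-row `expression_records` table for the gene, or NULL
#' @param gain_log2_min |log2ratio| threshold used only when the call is absent
#' @param gene_locus optional c(chrom, start, end); when given, a
#'   non-overlapping segment is a domain error
#' @return one of "supported", "unsupported", "untestable"
#' @export
cna_expression_support <- function(segment, expr, gain_log2_min = 0.3,
                                   gene_locus = NULL) {
  stopifnot(nrow(segment) == 1)
  if (!is.null(gene_locus)) {
    if (segment$chrom != gene_locus[[1]] ||
        segment$end < as.numeric(gene_locus[[2]]) ||
        segment$start > as.numeric(gene_locus[[3]])) {
      stopf("segment does not overlap the gene locus")
    }
  }
  call <- segment$call
  if (is.na(call) || call == "") {
    call <- if (segment$log2ratio >= gain_log2_min) "gain"
            else if (segment$log2ratio <= -gain_log2_min) "loss"
            else "normal"
  }
  if (is.null(expr) || nrow(expr) == 0) return("untestable")
  level <- expr$level[1]
  if (!call %in% c("gain", "loss") || level %in% c("unknown", "intermediate")) {
    return("untestable")
  }
  if ((call == "gain" && level == "high") || (call == "loss" && level == "low")) {
    "supported"
  } else "unsupported"
}

#' Partition the genome on the break-union of two segmentations
#'
#' Each partition begins and ends on a segment break from either input and
#' contains no break inside, so it overlaps exactly one segment from each
#' platform; only territory covered by both inputs is emitted. Both inputs must
#' be internally non-overlapping per chromosome.
#'
#' @param segs_a,segs_b `cna_segments` tables (e.g. WES-derived and
#'   array-derived)
#' @return data.frame with partition coordinates, `length`, and the
#'   `log2ratio`/`log2mBAF` of the one overlapping segment from each input
#'   (suffixes `_a`, `_b`)
#' @export
partition_genome <- function(segs_a, segs_b) {
  check_disjoint <- function(s, label) {
    for (ch in unique(s$chrom)) {
      x <- s[s$chrom == ch, , drop = FALSE]
      x <- x[order(x$start), , drop = FALSE]
      if (nrow(x) > 1 && any(x$start[-1] <= x$end[-nrow(x)])) {
        stopf("overlapping segments within input %s on %s", label, ch)
      }
    }
  }
  check_disjoint(segs_a, "A"); check_disjoint(segs_b, "B")

  out <- list()
  for (ch in intersect(unique(segs_a$chrom), unique(segs_b$chrom))) {
    a <- segs_a[segs_a$chrom == ch, , drop = FALSE]
    b <- segs_b[segs_b$chrom == ch, , drop = FALSE]
    ir_a <- IRanges::IRanges(start = a$start, end = a$end)
    ir_b <- IRanges::IRanges(start = b$start, end = b$end)
    pieces <- IRanges::disjoin(c(ir_a, ir_b))
    ov_a <- IRanges::findOverlaps(pieces, ir_a)
    ov_b <- IRanges::findOverlaps(pieces, ir_b)
    ia <- rep(NA_integer_, length(pieces)); ib <- rep(NA_integer_, length(pieces))
    ia[S4Vectors::queryHits(ov_a)] <- S4Vectors::subjectHits(ov_a)
    ib[S4Vectors::queryHits(ov_b)] <- S4Vectors::subjectHits(ov_b)
    keep <- !is.na(ia) & !is.na(ib)
    if (!any(keep)) next
    out[[ch]] <- data.frame(
      chrom = ch,
      start = IRanges::start(pieces)[keep], end = IRanges::end(pieces)[keep],
      length = IRanges::width(pieces)[keep],
      log2ratio_a = a$log2ratio[ia[keep]], log2ratio_b = b$log2ratio[ib[keep]],
      log2mBAF_a = a$log2mBAF[ia[keep]], log2mBAF_b = b$log2mBAF[ib[keep]],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), start = integer(), end = integer(),
                      length = integer(), log2ratio_a = numeric(),
                      log2ratio_b = numeric(), log2mBAF_a = numeric(),
                      log2mBAF_b = numeric())
  }
  rownames(res) <- NULL
  res
}

#' Length-weighted Pearson concordance of two segmentations
#'
#' Computes the partition-length-weighted Pearson correlation (via
#' `boot::corr`) between the two platforms' per-partition `log2ratio` values,
#' and likewise for `log2mBAF`. Zero variance on either side yields NA with a
#' warning.
#'
#' @param partitions output of [partition_genome()]
#' @return list of class `concordance_result`: `r_log2ratio`, `r_log2mBAF`,
#'   `n_partitions`, `partitions`
#' @export
weighted_concordance <- function(partitions) {
  if (nrow(partitions) < 2) stopf("need at least 2 partitions with finite statistics")
  w <- partitions$length
  wcor <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 2) return(NA_real_)
    wm <- function(v) sum(w[ok] * v) / sum(w[ok])
    if (wm((x[ok] - wm(x[ok]))^2) == 0 || wm((y[ok] - wm(y[ok]))^2) == 0) {
      warnf("zero variance on one side; weighted correlation undefined")
      return(NA_real_)
    }
    boot::corr(cbind(x[ok], y[ok]), w = w[ok])
  }
  structure(list(
    r_log2ratio = wcor(partitions$log2ratio_a, partitions$log2ratio_b),
    r_log2mBAF = wcor(partitions$log2mBAF_a, partitions$log2mBAF_b),
    n_partitions = nrow(partitions),
    partitions = partitions
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> %d partitions; r(log2ratio)=%.4f r(log2mBAF)=%.4f\n",
              x$n_partitions, x$r_log2ratio, x$r_log2mBAF))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper around `stats::ks.test` (two-sided), returning the D statistic
#' and the exact/asymptotic p value; used e.g. to compare per-tumor
#' concordance-correlation distributions between FFPE- and frozen-derived
#' specimens.
#'
#' @param group_a,group_b numeric vectors (both non-empty)
#' @return list with `D` and `p`
#' @export
ks_compare <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) stopf("both groups must be non-empty")
  kt <- suppressWarnings(stats::ks.test(group_a, group_b))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Call an expression level against a reference distribution
#'
#' @param value observed expression value
#' @param reference_values non-empty reference distribution (same units)
#' @param high_quantile,low_quantile quantile bounds, `0 <= low < high <= 1`
#' @return "high", "low" or "intermediate"
#' @export
expression_level <- function(value, reference_values, high_quantile = 0.75,
                             low_quantile = 0.25) {
  if (length(reference_values) == 0) stopf("reference distribution is empty")
  if (!(low_quantile >= 0 && low_quantile < high_quantile && high_quantile <= 1)) {
    stopf("quantile bounds must satisfy 0 <= low < high <= 1")
  }
  q <- stats::quantile(reference_values, c(low_quantile, high_quantile), names = FALSE)
  if (value > q[2]) "high" else if (value < q[1]) "low" else "intermediate"
}

#' Tumor/normal expression fold change
#'
#' @param tumor_value,normal_value expression values (same units)
#' @param pseudocount added to both values before division; 0 (off) by default
#' @return `(tumor_value + pseudocount) / (normal_value + pseudocount)`
#' @export
fold_change <- function(tumor_value, normal_value, pseudocount = 0) {
  if (normal_value + pseudocount <= 0) {
    stopf("normal value must be positive (or supply a pseudocount)")
  }
  (tumor_value + pseudocount) / (normal_value + pseudocount)
}

#' Nearest-centroid expression subtype call
#'
#' Assigns the label of the nearest centroid by Spearman correlation over the
#' genes shared between the expression vector and the centroid matrix (as in
#' centroid-based intrinsic breast cancer subtyping). At least 50% of the
#' signature genes must be present. Ties break to the first label in column
#' order, with a warning.
#'
#' @param expression_vector named numeric vector (names = signature genes)
#' @param centroids numeric matrix, rows = signature genes, columns = subtypes
#' @return the winning subtype label
#' @export
subtype_by_centroid <- function(expression_vector, centroids) {
  genes <- intersect(names(expression_vector), rownames(centroids))
  if (length(genes) < 0.5 * nrow(centroids)) {
    stopf("insufficient gene overlap: %d of %d signature genes present",
          length(genes), nrow(centroids))
  }
  cors <- apply(centroids[genes, , drop = FALSE], 2, function(cent) {
    stats::cor(expression_vector[genes], cent, method = "spearman")
  })
  best <- max(cors)
  winners <- names(cors)[cors == best]
  if (length(winners) > 1) {
    warnf("centroid tie between %s; using first in declared order", paste(winners, collapse = ", "))
  }
  winners[1]
}
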