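# Shared fixtures: the packaged synthetic mini-KB, gene loci and the encoded
# study cohorts are loaded once per test session.

test_kb <- load_kb(default_kb_dir())
test_loci <- default_gene_loci()
test_fixtures <- table_fixtures(test_loci)

# minimal profile builders used across test files
mk_somatic_profile <- function(gene, protein_change, cancer_type = "colorectal",
                               id = "TEST", loci = test_loci) {
  specs <- Map(list, gene, protein_change)
  som <- do.call(rbind, lapply(specs, function(s) {
    oncointerp:::fixture_somatic(s[[1]], s[[2]], loci)
  }))
  class(som) <- c("somatic_variants", "data.frame")
  patient_profile(id, cancer_type, somatic = som)
}

mk_cna_profile <- function(gene, call, cancer_type = "breast", id = "TESTC",
                           loci = test_loci) {
  cna <- do.call(rbind, Map(function(g, cl) {
    oncointerp:::fixture_cna(g, cl, loci)
  }, gene, call))
  class(cna) <- c("cna_segments", "data.frame")
  patient_profile(id, cancer_type, cna = cna)
}

mk_expression_profile <- function(gene, level, cancer_type = "colorectal",
                                  id = "TESTE") {
  patient_profile(id, cancer_type,
                  expression = expression_records(gene = gene, tumor_value = 10,
                                                  normal_value = 1, level = level))
}

# independent brute-force oracle for the break-union genome partition
oracle_partition <- function(a, b) {
  out <- list()
  covered <- function(s, chrom, lo, hi) {
    any(s$chrom == chrom & s$start <= lo & s$end >= hi)
  }
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    sa <- a[a$chrom == ch, ]; sb <- b[b$chrom == ch, ]
    cuts <- sort(unique(c(sa$start, sa$end + 1L, sb$start, sb$end + 1L)))
    for (i in seq_len(length(cuts) - 1)) {
      lo <- cuts[i]; hi <- cuts[i + 1] - 1L
      if (covered(sa, ch, lo, hi) && covered(sb, ch, lo, hi)) {
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = lo, end = hi)
      }
    }
  }
  do.call(rbind, out)
}

# independent weighted-Pearson oracle (direct weighted-covariance formula)
oracle_weighted_pearson <- function(x, y, w) {
  xm <- sum(w * x) / sum(w); ym <- sum(w * y) / sum(w)
  sum(w * (x - xm) * (y - ym)) /
    sqrt(sum(w * (x - xm)^2) * sum(w * (y - ym)^2))
}

# independent two-sample KS-D oracle (max ECDF gap)
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}
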