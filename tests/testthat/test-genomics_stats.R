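test_that("mutation frequency counts qualifying SNVs per megabase", {
  v <- somatic_variants(chrom = "chr1", pos = seq_len(70) * 10L, ref = "C", alt = "T",
                        consequence = "missense")
  expect_equal(mutation_frequency(v, 35), 2.0)
  expect_equal(mutation_frequency(somatic_variants(), 30), 0.0)
  # synonymous / non-canonical / indel calls do not count
  v$consequence[1:10] <- "synonymous"
  v$canonical_isoform[11:20] <- FALSE
  v$ref[21] <- "CT"
  expect_equal(mutation_frequency(v, 35), 49 / 35)
  expect_error(mutation_frequency(v, 0), "> 0")
})

test_that("a cohort simulated at the configured median rate recovers it", {
  cfg <- cohort_config(n_patients = 19, cancer_mix = c(colorectal = 1),
                       gene_freqs = NULL,
                       background_rate_mb = c(colorectal = 2.7),
                       coding_mb = 30, seed = 314)
  coh <- generate_cohort(cfg)
  med <- median(vapply(coh, function(p) mutation_frequency(p$somatic, 30), numeric(1)))
  expect_lt(abs(med - 2.7) / 2.7, 0.10)
})

test_that("the spectrum handles pure and uniform inputs", {
  v <- somatic_variants(chrom = "chr1", pos = seq_len(10), ref = "G", alt = "A")
  sp <- spectrum(v)
  expect_equal(unname(sp$fractions["C>T"]), 1.0)
  expect_equal(sp$total, 10)

  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  v2 <- somatic_variants(chrom = "chr1", pos = seq_len(12), ref = pairs$ref,
                         alt = pairs$alt)
  expect_true(all(abs(spectrum(v2)$fractions - 1 / 6) < 1e-12))
})

test_that("spectrum fractions sum to one and ignore input order", {
  set.seed(5)
  v <- generate_cohort(cohort_config(
    n_patients = 1, gene_freqs = NULL, background_rate_mb = c(default = 10),
    coding_mb = 30, seed = 6
  ))[[1]]$somatic
  sp <- spectrum(v)
  expect_equal(sum(sp$fractions), 1, tolerance = 1e-9)
  shuf <- v[sample(nrow(v)), ]
  expect_equal(spectrum(shuf)$fractions, sp$fractions)
})

test_that("a generated tumor recovers the configured spectrum weights", {
  w <- c(.05, .05, .7, .05, .1, .05)
  cfg <- cohort_config(n_patients = 1, gene_freqs = NULL,
                       background_rate_mb = c(default = 500 / 30), coding_mb = 30,
                       spectrum_weights = w, seed = 271)
  v <- generate_cohort(cfg)[[1]]$somatic
  sp <- spectrum(v)
  n <- sp$total
  for (k in seq_along(w)) {
    sigma <- sqrt(w[k] * (1 - w[k]) / n)
    expect_lt(abs(sp$fractions[k] - w[k]), 3 * sigma + 1e-9)
  }
})

test_that("purity estimation follows the diploid-heterozygous 2xAF model", {
  expect_equal(estimate_purity(rep(0.5, 20))$purity, 1.0)
  expect_equal(estimate_purity(rep(0.125, 20))$purity, 0.25)
  low <- estimate_purity(rep(0.02, 20))
  expect_true(low$low_purity)
  unrel <- estimate_purity(rep(0.3, 5))
  expect_false(unrel$reliable)
  expect_error(estimate_purity(numeric(0)), "at least one")
})

test_that("purity is recovered within 0.1 from generated tumors", {
  cfg <- cohort_config(n_patients = 1, gene_freqs = NULL,
                       background_rate_mb = c(default = 200 / 30), coding_mb = 30,
                       purity_range = c(0.6, 0.6), depth_mean = 100,
                       depth_size = 1e6, seed = 99)
  p <- generate_cohort(cfg)[[1]]
  est <- estimate_purity(p$somatic$af)
  expect_lt(abs(est$purity - 0.6), 0.1)
})

test_that("purity estimation is scale-consistent in depth", {
  afs <- c(rep(0.31, 30), rep(0.08, 10))
  base <- estimate_purity(afs)$purity
  # multiplying all depths by a constant leaves the AFs, hence the estimate
  deeper <- estimate_purity((afs * 1000 * 7) / (1000 * 7))$purity
  expect_equal(deeper, base)
})

test_that("CNA-expression support follows the call x level contingency", {
  seg <- cna_segments(chrom = "chr11", start = 1L, end = 1000L, log2ratio = 0.9,
                      log2mBAF = 0.3, call = "gain")
  high <- expression_records(gene = "CCND1", tumor_value = 50, normal_value = 1,
                             level = "high")
  low <- expression_records(gene = "CCND1", tumor_value = 0.5, normal_value = 1,
                            level = "low")
  expect_equal(cna_expression_support(seg, high), "supported")
  expect_equal(cna_expression_support(seg, low), "unsupported")
  expect_equal(cna_expression_support(seg, NULL), "untestable")
  expect_error(
    cna_expression_support(seg, high, gene_locus = list("chr5", 10, 20)),
    "does not overlap"
  )
})

test_that("genome partitioning handles the degenerate and split cases", {
  a <- cna_segments(chrom = "chr1", start = 1L, end = 100L, log2ratio = 0.5,
                    log2mBAF = 0.2, call = "gain")
  same <- partition_genome(a, a)
  expect_equal(nrow(same), 1)
  expect_equal(c(same$start, same$end), c(1L, 100L))

  b <- cna_segments(chrom = c("chr1", "chr1"), start = c(1L, 51L),
                    end = c(50L, 100L), log2ratio = c(0.4, 0.6),
                    log2mBAF = c(0.1, 0.3), call = "gain")
  parts <- partition_genome(a, b)
  expect_equal(parts$start, c(1L, 51L))
  expect_equal(parts$end, c(50L, 100L))
  expect_equal(parts$log2ratio_a, c(0.5, 0.5))
  expect_equal(parts$log2ratio_b, c(0.4, 0.6))
})

test_that("overlapping segments within one input are rejected", {
  bad <- cna_segments(chrom = c("chr1", "chr1"), start = c(1L, 50L),
                      end = c(60L, 100L), log2ratio = 0, log2mBAF = 0,
                      call = "normal")
  ok <- cna_segments(chrom = "chr1", start = 1L, end = 100L, log2ratio = 0,
                     log2mBAF = 0, call = "normal")
  expect_error(partition_genome(bad, ok), "overlapping segments")
})

random_segmentation <- function(n, chrom = "chr1") {
  bounds <- sort(sample.int(10000L, 2 * n))
  starts <- bounds[seq(1, 2 * n, 2)]
  ends <- bounds[seq(2, 2 * n, 2)]
  cna_segments(chrom = chrom, start = starts, end = ends,
               log2ratio = rnorm(n), log2mBAF = runif(n), call = "undecided")
}

test_that("partitioning matches the brute-force boundary-union oracle", {
  set.seed(20)
  for (i in 1:10) {
    a <- random_segmentation(sample(2:6, 1))
    b <- random_segmentation(sample(2:6, 1))
    got <- partition_genome(a, b)
    want <- oracle_partition(a, b)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[c("chrom", "start", "end")],
                   want[c("chrom", "start", "end")],
                   ignore_attr = TRUE)
      # conservation: partition lengths tile the covered intersection exactly
      expect_equal(sum(got$length), sum(want$end - want$start + 1))
    }
  }
})

test_that("weighted concordance is 1 on identical inputs and -1 on negation", {
  a <- cna_segments(chrom = "chr1", start = c(1L, 101L, 301L),
                    end = c(100L, 300L, 400L), log2ratio = c(0.5, -0.3, 0.1),
                    log2mBAF = c(0.2, 0.05, 0.4), call = "undecided")
  parts <- partition_genome(a, a)
  cr <- weighted_concordance(parts)
  expect_equal(cr$r_log2ratio, 1.0, tolerance = 1e-12)
  expect_equal(cr$r_log2mBAF, 1.0, tolerance = 1e-12)
  neg <- a; neg$log2ratio <- -neg$log2ratio
  expect_equal(weighted_concordance(partition_genome(a, neg))$r_log2ratio, -1.0,
               tolerance = 1e-12)
})

test_that("weighted concordance equals the direct weighted-covariance formula", {
  set.seed(31)
  for (i in 1:5) {
    a <- random_segmentation(5)
    b <- random_segmentation(5)
    parts <- partition_genome(a, b)
    if (nrow(parts) < 2) next
    cr <- weighted_concordance(parts)
    expect_equal(cr$r_log2ratio,
                 oracle_weighted_pearson(parts$log2ratio_a, parts$log2ratio_b,
                                         parts$length),
                 tolerance = 1e-12)
  }
})

test_that("weighted concordance reduces to plain Pearson for equal lengths", {
  parts <- data.frame(chrom = "chr1", start = c(1, 11, 21, 31),
                      end = c(10, 20, 30, 40), length = 10,
                      log2ratio_a = c(0.1, -0.5, 0.7, 0.2),
                      log2ratio_b = c(0.2, -0.4, 0.5, 0.1),
                      log2mBAF_a = 1:4 / 10, log2mBAF_b = c(2, 1, 4, 3) / 10)
  cr <- weighted_concordance(parts)
  expect_equal(cr$r_log2ratio, cor(parts$log2ratio_a, parts$log2ratio_b),
               tolerance = 1e-12)
})

test_that("zero variance yields NA with a warning", {
  parts <- data.frame(chrom = "chr1", start = c(1, 11), end = c(10, 20),
                      length = 10, log2ratio_a = c(0.3, 0.3),
                      log2ratio_b = c(0.1, 0.9),
                      log2mBAF_a = c(0.1, 0.2), log2mBAF_b = c(0.1, 0.2))
  expect_warning(cr <- weighted_concordance(parts), "zero variance")
  expect_true(is.na(cr$r_log2ratio))
})

test_that("KS comparison matches the ECDF-gap oracle", {
  expect_equal(ks_compare(1:5, 1:5)$D, 0)
  expect_equal(ks_compare(1:5, 6:10)$D, 1)
  set.seed(17)
  a <- rnorm(8); b <- rnorm(11, mean = 0.5)
  ks <- ks_compare(a, b)
  expect_equal(ks$D, oracle_ks_d(a, b), tolerance = 1e-12)
  expect_true(ks$p >= 0 && ks$p <= 1)
  expect_error(ks_compare(numeric(0), 1:3), "non-empty")
})

test_that("expression levels are quantile calls against the reference", {
  ref <- 1:100
  expect_equal(expression_level(99, ref, 0.75, 0.25), "high")
  expect_equal(expression_level(2, ref, 0.75, 0.25), "low")
  expect_equal(expression_level(50, ref, 0.75, 0.25), "intermediate")
  expect_error(expression_level(1, numeric(0)), "empty")
  expect_error(expression_level(1, ref, 0.2, 0.8), "bounds")
})

test_that("fold change divides tumor by normal with optional pseudocount", {
  expect_equal(fold_change(113, 1), 113)
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(0, 1, pseudocount = 0.5), 0.5 / 1.5)
  expect_error(fold_change(1, 0), "positive")
})

test_that("nearest-centroid subtyping recovers planted labels", {
  centroids <- synthetic_centroids()
  # a vector equal to a centroid maps to that label
  for (lab in colnames(centroids)) {
    expect_equal(subtype_by_centroid(centroids[, lab], centroids), lab)
  }
  # negation of a centroid never maps to it
  expect_false(subtype_by_centroid(-centroids[, "basal-like"], centroids) == "basal-like")
  expect_error(
    subtype_by_centroid(setNames(rnorm(10), rownames(centroids)[1:10]), centroids),
    "insufficient gene overlap"
  )
})

test_that("noisy draws around each centroid are recovered at >= 95%", {
  centroids <- synthetic_centroids()
  set.seed(2024)
  n_per <- 10
  correct <- 0
  for (lab in colnames(centroids)) {
    for (i in seq_len(n_per)) {
      v <- centroids[, lab] + rnorm(nrow(centroids), sd = 0.3)
      names(v) <- rownames(centroids)
      if (subtype_by_centroid(v, centroids) == lab) correct <- correct + 1
    }
  }
  expect_gte(correct / (n_per * ncol(centroids)), 0.95)
})
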