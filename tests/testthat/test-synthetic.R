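test_that("a frequency of 1 means every profile carries the alteration", {
  cfg <- cohort_config(
    n_patients = 10, cancer_mix = c(colorectal = 1),
    gene_freqs = data.frame(cancer_type = "colorectal", gene = "KRAS",
                            source = "somatic", freq = 1),
    background_rate_mb = c(default = 0), seed = 1
  )
  coh <- generate_cohort(cfg)
  expect_true(all(vapply(coh, function(p) "KRAS" %in% p$somatic$gene, logical(1))))
})

test_that("the generator is deterministic given the seed", {
  cfg <- default_cohort_config(n_patients = 6, seed = 123)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- generate_cohort(default_cohort_config(n_patients = 6, seed = 124))
  expect_false(identical(c1, c3))
})

test_that("empirical per-gene frequencies recover the configured table row", {
  genes <- c("APC", "KRAS", "NRAS", "BRAF", "PIK3CA", "PTEN", "TP53")
  freqs <- c(0.89, 0.53, 0.11, 0.11, 0.11, 0.11, 0.84)
  cfg <- cohort_config(
    n_patients = 1900, cancer_mix = c(colorectal = 1),
    gene_freqs = data.frame(cancer_type = "colorectal", gene = genes,
                            source = "somatic", freq = freqs),
    background_rate_mb = c(default = 0), seed = 1900
  )
  coh <- generate_cohort(cfg)
  for (k in seq_along(genes)) {
    hits <- sum(vapply(coh, function(p) genes[k] %in% p$somatic$gene, logical(1)))
    sigma <- sqrt(1900 * freqs[k] * (1 - freqs[k]))
    expect_lt(abs(hits - 1900 * freqs[k]), 3 * sigma)
  }
})

test_that("invalid configurations are rejected with the offending fields", {
  expect_error(cohort_config(n_patients = 5, cancer_mix = c(a = 0.5), seed = 1),
               "sum to 1")
  expect_error(cohort_config(n_patients = 5, spectrum_weights = rep(1, 6), seed = 1),
               "summing to 1")
  expect_error(cohort_config(n_patients = 5), "seed")
  expect_error(
    cohort_config(n_patients = 5,
                  gene_freqs = data.frame(cancer_type = "x", gene = "KRAS",
                                          source = "somatic", freq = 2),
                  seed = 1),
    "freq"
  )
})

test_that("generated cohorts round-trip through the on-disk formats", {
  cfg <- default_cohort_config(n_patients = 4, seed = 55)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_length(back, 4)
  for (i in seq_along(coh)) {
    orig <- coh[[i]]; rt <- back[[i]]
    expect_equal(rt$patient_id, orig$patient_id)
    expect_equal(rt$cancer_type, orig$cancer_type)
    key <- function(s) sort(paste(s$chrom, s$pos, s$ref, s$alt, s$tumor_id))
    expect_identical(key(rt$somatic), key(orig$somatic))
    # annotations and depths survive the VCF round trip
    ko <- order(orig$somatic$chrom, orig$somatic$pos, orig$somatic$ref, orig$somatic$alt)
    kr <- order(rt$somatic$chrom, rt$somatic$pos, rt$somatic$ref, rt$somatic$alt)
    expect_equal(rt$somatic$gene[kr], orig$somatic$gene[ko])
    expect_equal(rt$somatic$depth_alt[kr], orig$somatic$depth_alt[ko])
    expect_equal(rt$cna$start, orig$cna$start)
    expect_equal(rt$cna$log2ratio, orig$cna$log2ratio)
    expect_equal(rt$expression$gene, orig$expression$gene)
    expect_equal(rt$germline$gene, orig$germline$gene)
  }
})

test_that("the encoded study cohorts match the narrated alteration structure", {
  fx <- test_fixtures
  expect_length(fx$mtc, 5)
  expect_true(all(vapply(fx$mtc, function(p) {
    "RET" %in% c(p$somatic$gene, p$germline$gene)
  }, logical(1))))
  expect_length(fx$colorectal, 19)
  expect_length(fx$breast, 7)
  tp53_breast <- vapply(fx$breast, function(p) "TP53" %in% p$somatic$gene, logical(1))
  expect_equal(sum(tp53_breast), 4)
  expect_setequal(
    vapply(fx$breast[tp53_breast], `[[`, character(1), "patient_id"),
    c("P0007", "P0030", "P0040", "P0042")
  )
  # fixture variants sit at the synthetic codon positions
  kras <- fx$colorectal[[1]]$somatic
  g12 <- codon_pos("KRAS", 12, test_loci)
  expect_equal(kras$pos[kras$gene == "KRAS"], g12$pos)
})

test_that("the case-study fixture reproduces the printed coordinates and depths", {
  p15 <- test_fixtures$p0015
  s <- p15$somatic
  expect_equal(s$gene, "EGFR")
  expect_equal(s$protein_change, "p.D587H")
  expect_equal(s$chrom, "chr7")
  expect_equal(s$pos, 55233009L)
  expect_equal(s$ref, "G")
  expect_equal(s$alt, "C")
  expect_equal(s$depth_alt, 387L)
  expect_equal(s$depth_total, 1998L)
})
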