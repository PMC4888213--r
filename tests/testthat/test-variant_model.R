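test_that("substitution classification follows the pyrimidine convention", {
  # a C:G > T:A transition is written C>T regardless of strand of report
  expect_equal(classify_substitution("G", "A"), "C>T")
  expect_equal(classify_substitution("C", "G"), "C>G")
  expect_equal(classify_substitution("A", "C"), "T>G")
  expect_equal(classify_substitution("C", "T"), "C>T")
})

test_that("classification is a total surjective 2-to-1 map onto the 6 classes", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_substitution(pairs$ref, pairs$alt)
  expect_equal(length(cls), 12)
  tab <- table(cls)
  expect_setequal(names(tab), c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  expect_true(all(tab == 2))
})

test_that("indels and ambiguity codes are rejected", {
  expect_error(classify_substitution("CT", "C"), "single")
  expect_error(classify_substitution("N", "A"), "single")
  expect_error(classify_substitution("C", "C"), "differ")
})

test_that("assay selection implements the gDNA-mass decision rules", {
  expect_setequal(select_assays(1.0, 3.0, FALSE, FALSE), "panel")
  expect_setequal(select_assays(2.0, 2.0, FALSE, FALSE), c("panel", "wes"))
  expect_setequal(select_assays(3.0, 3.0, TRUE, TRUE),
                  c("panel", "wes", "array", "rnaseq_tumor", "rnaseq_normal"))
  # RNA assays depend on frozen tissue, not mass
  expect_setequal(select_assays(1.0, 1.0, TRUE, FALSE), c("panel", "rnaseq_tumor"))
  expect_error(select_assays(-1, 2), ">= 0")
})

test_that("assay selection is monotone in gDNA mass", {
  masses <- c(0, 1, 1.5, 2, 2.5, 2.6, 5)
  for (m1 in masses) for (m2 in masses) {
    a <- select_assays(m1, m2)
    for (d in c(0.5, 1, 2)) {
      expect_true(all(a %in% select_assays(m1 + d, m2)))
      expect_true(all(a %in% select_assays(m1, m2 + d)))
    }
  }
})

test_that("somatic variant invariants are enforced", {
  expect_error(
    somatic_variants(chrom = "chr1", pos = 0, ref = "A", alt = "T"),
    ">= 1"
  )
  expect_error(
    somatic_variants(chrom = "chr1", pos = 5, ref = "A", alt = "A"),
    "alt == ref"
  )
  expect_error(
    somatic_variants(chrom = "chr1", pos = 5, ref = "A", alt = "T",
                     af = 0.9, depth_alt = 10, depth_total = 100),
    "inconsistent"
  )
  v <- somatic_variants(chrom = "chr1", pos = 5, ref = "A", alt = "T",
                        depth_alt = 25, depth_total = 100)
  expect_equal(v$af, 0.25)
})

test_that("single-sample VCFs round-trip and cannot be recurrent", {
  v <- somatic_variants(
    chrom = c("chr1", "chr2", "chr7"), pos = c(100L, 200L, 300L),
    ref = c("C", "G", "A"), alt = c("T", "A", "G"),
    gene = c("GENE1", "GENE2", "GENE3"),
    protein_change = c("p.A10V", "p.R20*", "p.G30E"),
    depth_alt = c(20L, 30L, 40L), depth_total = c(100L, 100L, 100L)
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_somatic_vcf(v, path)
  back <- read_somatic_vcf(path)
  expect_equal(nrow(back), 3)
  expect_false(any(back$recurrent))
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, x$gene, x$protein_change,
                           x$depth_alt, x$depth_total)
  expect_setequal(key(back), key(v))
})

test_that("multi-sample VCFs set the recurrent flag for shared variants", {
  shared <- somatic_variants(chrom = "chr7", pos = 1000L, ref = "G", alt = "C",
                             gene = "EGFR", protein_change = "p.D587H",
                             depth_alt = 10L, depth_total = 50L, tumor_id = "T1")
  shared2 <- shared; shared2$tumor_id <- "T2"
  t2only <- somatic_variants(chrom = "chr1", pos = 50L, ref = "C", alt = "T",
                             gene = "TP53", protein_change = "p.R273H",
                             depth_alt = 12L, depth_total = 60L, tumor_id = "T2")
  v <- rbind(shared, shared2, t2only)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_somatic_vcf(v, path)
  back <- read_somatic_vcf(path)
  expect_equal(nrow(back), 3)
  shared_back <- back[back$gene == "EGFR", ]
  expect_equal(nrow(shared_back), 2)
  expect_true(all(shared_back$recurrent))
  expect_false(back$recurrent[back$gene == "TP53"])
})

test_that("sample_map renames tumors and rejects unknown labels", {
  v <- somatic_variants(chrom = "chr1", pos = 10L, ref = "C", alt = "T",
                        tumor_id = "S1")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_somatic_vcf(v, path)
  back <- read_somatic_vcf(path, sample_map = c(S1 = "tumor_frozen"))
  expect_equal(back$tumor_id, "tumor_frozen")
  expect_error(read_somatic_vcf(path, sample_map = c(NOPE = "x")), "unknown sample")
})

test_that("non-PASS records are dropped unless kept explicitly", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", "T1", sep = "\t"),
    paste("chr1", "100", ".", "C", "T", ".", "PASS", ".", "GT", "0/1", sep = "\t"),
    paste("chr1", "200", ".", "G", "A", ".", "manual_review", ".", "GT", "0/1", sep = "\t")
  ), path)
  expect_equal(nrow(read_somatic_vcf(path)), 1)
  expect_equal(nrow(read_somatic_vcf(path, keep_filtered = TRUE)), 2)
})

test_that("segment and expression tables round-trip through TSV", {
  segs <- cna_segments(chrom = c("chr1", "chr1"), start = c(1L, 501L),
                       end = c(500L, 900L), log2ratio = c(0.8, -0.2),
                       log2mBAF = c(0.3, 0.1), call = c("gain", "normal"))
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_segments_tsv(segs, sp)
  back <- read_segments_tsv(sp)
  expect_equal(back$start, segs$start)
  expect_equal(back$log2ratio, segs$log2ratio)
  expect_equal(back$call, segs$call)

  # BED-style input converts to 1-based inclusive on read
  bed <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tlog2ratio\tlog2mBAF\tcall",
               "chr1\t0\t500\t0.8\t0.3\tgain"), bed)
  expect_equal(read_segments_tsv(bed, bed_coords = TRUE)$start, 1L)

  ex <- expression_records(gene = c("EREG", "AREG"), tumor_value = c(113, 29),
                           normal_value = 1, level = "high")
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(ex, ep)
  back <- read_expression_tsv(ep)
  expect_equal(back$fold_change, c(113, 29))
  expect_equal(back$level, c("high", "high"))
})
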