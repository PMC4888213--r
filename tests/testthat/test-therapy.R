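test_that("anti-EGFR decision tree: RAS-activated colorectal gets lack-of-benefit", {
  p <- mk_somatic_profile("KRAS", "p.G13D")
  t1 <- predict_tier1_response(p, test_kb)
  for (drug in c("cetuximab", "panitumumab")) {
    row <- t1[t1$drug == drug, ]
    expect_equal(row$effect, "lack_of_benefit")
    expect_equal(row$evidence, "Definitive")
    expect_equal(row$support[[1]]$gene, "KRAS")
  }
})

test_that("quadruple-negative colorectal with high EGFR ligands gets benefit", {
  p <- test_fixtures$colorectal[[4]]  # APC/TP53 mutant, EREG+AREG high, RAS/RAF wild-type
  t1 <- predict_tier1_response(p, test_kb)
  row <- t1[t1$drug == "cetuximab", ]
  expect_equal(row$effect, "benefit")
  expect_equal(row$evidence, "Moderate")
  expect_setequal(row$support[[1]]$gene, c("EREG", "AREG"))
})

test_that("profiles matching no rule get no_prediction for every drug", {
  p <- patient_profile("EMPTY", "colorectal")
  t1 <- predict_tier1_response(p, test_kb)
  expect_true(all(t1$effect == "no_prediction"))
  expect_true(all(t1$evidence == "none"))
  expect_true(all(vapply(t1$support, nrow, integer(1)) == 0))
})

test_that("evidence short-circuit: Definitive match blinds all lower levels", {
  kb2 <- test_kb
  # inject a conflicting Weak benefit rule for cetuximab on the same biomarker
  kb2$drug_rules <- rbind(kb2$drug_rules, data.frame(
    rule_id = "DRX1", drug = "cetuximab", drug_tier = 1L,
    cancer_type = "colorectal", predicate = "KRAS somatic_activating",
    effect = "benefit", evidence = "Weak"
  ))
  p <- mk_somatic_profile("KRAS", "p.G12D")
  base <- predict_tier1_response(p, test_kb)
  injected <- predict_tier1_response(p, kb2)
  row_b <- base[base$drug == "cetuximab", ]
  row_i <- injected[injected$drug == "cetuximab", ]
  expect_equal(row_i$effect, row_b$effect)
  expect_equal(row_i$evidence, "Definitive")
})

test_that("same-level conflicts resolve to the negative call", {
  kb2 <- test_kb
  kb2$drug_rules <- rbind(kb2$drug_rules, data.frame(
    rule_id = "DRX2", drug = "cetuximab", drug_tier = 1L,
    cancer_type = "colorectal", predicate = "TP53 somatic_inactivating",
    effect = "benefit", evidence = "Definitive"
  ))
  p <- mk_somatic_profile(c("KRAS", "TP53"), c("p.G12D", "p.R273H"))
  row <- predict_tier1_response(p, kb2)
  row <- row[row$drug == "cetuximab", ]
  expect_equal(row$effect, "lack_of_benefit")
  # both matched alterations remain in the supporting set
  expect_setequal(row$support[[1]]$gene, c("KRAS", "TP53"))
})

test_that("RET activation recommends RET kinase inhibitors", {
  # tier-1 route for MTC (the drugs are approved for that tumor type)
  for (p in test_fixtures$mtc) {
    t1 <- predict_tier1_response(p, test_kb)
    for (drug in c("vandetanib", "cabozantinib")) {
      expect_equal(t1$effect[t1$drug == drug], "benefit")
    }
  }
  # tier-2 target route elsewhere
  p <- mk_somatic_profile("RET", "p.M918T", cancer_type = "other:mixed")
  t2 <- recommend_tier2(p, test_kb)
  expect_true(all(c("vandetanib", "cabozantinib") %in% t2$drug))
  expect_true(all(t2$effect == "sensitivity"))
})

test_that("CCND1 amplification recommends CDK4/6-targeting drugs and trials", {
  p <- mk_cna_profile("CCND1", "gain", cancer_type = "breast")
  t2 <- recommend_tier2(p, test_kb)
  expect_true(any(t2$drug %in% c("palbociclib", "ribociclib")))
  trials <- match_trials(p, test_kb)
  expect_true("NCT-SYN-0001" %in% trials$trial_id)
})

test_that("PTEN loss without an ERK lesion recommends the AKT/mTOR axis only", {
  p <- mk_cna_profile("PTEN", "loss", cancer_type = "colorectal")
  t2 <- recommend_tier2(p, test_kb)
  expect_true(any(t2$drug %in% c("everolimus", "temsirolimus")))
  expect_false(any(t2$drug %in% c("trametinib", "selumetinib")))
  expect_false(any(t2$is_combination))
})

test_that("two independently activated pathways trigger a combination", {
  p <- mk_somatic_profile(c("KRAS", "PTEN"), c("p.G12D", "p.R130*"),
                          cancer_type = "other:mixed")
  t2 <- recommend_tier2(p, test_kb)
  expect_true(any(t2$is_combination))
  combo <- t2[t2$is_combination, ][1, ]
  expect_match(combo$drug, "\\+")
})

test_that("pathway projection flags multi-hit pathways", {
  p <- mk_somatic_profile(c("DKK1", "CSNK1A1", "AXIN1"),
                          c("p.S157F", "p.D140N", "p.R395*"))
  hits <- project_onto_pathways(p, test_kb)
  wnt <- hits[hits$pathway == "WNT", ]
  expect_equal(nrow(wnt), 1)
  expect_true(wnt$multi_hit)
  expect_equal(wnt$n_genes, 3)

  p2 <- mk_somatic_profile(c("PIK3R1", "INPP5D", "INPPL1"),
                           c("p.E443K", "p.S19C", "p.R346W"),
                           cancer_type = "skin_scc")
  pi3k <- project_onto_pathways(p2, test_kb)
  expect_true(pi3k$multi_hit[pi3k$pathway == "PI3K_AKT_MTOR"])

  expect_equal(nrow(project_onto_pathways(patient_profile("E", "breast"), test_kb)), 0)
})

test_that("germline risk screening flags truncating variants in panel genes", {
  panel <- test_kb$risk_genes$gene[test_kb$risk_genes$panel == "breast_risk"]
  g <- germline_variants(chrom = c("chr17", "chr10", "chr3"),
                         pos = c(100L, 200L, 300L), ref = "C", alt = "T",
                         gene = c("BRCA1", "DCLRE1C", "OFFPANEL"),
                         protein_change = c("p.W1712fs", "p.S635_L636fs", "p.A1V"))
  hit <- germline_risk_screen(g, panel)
  expect_setequal(hit$gene, c("BRCA1", "DCLRE1C"))
  expect_true(all(hit$truncating))
  off <- germline_risk_screen(g[3, , drop = FALSE], panel)
  expect_equal(nrow(off), 0)
})

test_that("trial matching filters by biomarker and type, open trials first", {
  p <- mk_cna_profile(c("CCND1", "FGFR1"), c("gain", "gain"), cancer_type = "breast")
  tr <- match_trials(p, test_kb)
  expect_true(all(c("NCT-SYN-0001", "NCT-SYN-0003") %in% tr$trial_id))
  # the closed FGFR trial ranks after open matches
  expect_true(which(tr$trial_id == "NCT-SYN-0003") > which(tr$trial_id == "NCT-SYN-0001"))
  none <- match_trials(patient_profile("X", "breast"), test_kb)
  expect_equal(nrow(none), 0)
})

test_that("actionability counts gene x source units across tiers", {
  p <- patient_profile(
    "ACT", "colorectal",
    somatic = mk_somatic_profile("KRAS", "p.G12V")$somatic,
    cna = mk_cna_profile("CCND1", "gain")$cna
  )
  t1 <- predict_tier1_response(p, test_kb)
  t2 <- recommend_tier2(p, test_kb)
  act <- actionability(p, t1, t2)
  expect_equal(unname(act$counts["somatic"]), 1L)
  expect_equal(unname(act$counts["cna"]), 1L)
  expect_equal(act$total, 2L)
  expect_true(act$has_tier1)
  expect_true(act$has_tier2)
})

test_that("actionability is idempotent under prediction duplication", {
  p <- mk_somatic_profile("KRAS", "p.G12V")
  t1 <- predict_tier1_response(p, test_kb)
  t2 <- recommend_tier2(p, test_kb)
  once <- actionability(p, t1, t2)
  twice <- actionability(p, rbind(t1, t1), rbind(t2, t2))
  expect_equal(twice$total, once$total)
  expect_equal(twice$counts, once$counts)
})

test_that("no predictions means zero actionable and unset flags", {
  p <- patient_profile("NONE", "colorectal")
  t1 <- predict_tier1_response(p, test_kb)
  t2 <- recommend_tier2(p, test_kb)
  act <- actionability(p, t1, t2)
  expect_equal(act$total, 0L)
  expect_false(act$has_tier1)
  expect_false(act$has_tier2)
})

test_that("the same gene hit by two sources counts once per source", {
  p <- patient_profile(
    "DUAL", "breast",
    cna = mk_cna_profile("ERBB2", "gain")$cna,
    expression = expression_records(gene = "ERBB2", tumor_value = 50,
                                    normal_value = 1, level = "high")
  )
  t1 <- predict_tier1_response(p, test_kb)
  t2 <- recommend_tier2(p, test_kb)
  act <- actionability(p, t1, t2)
  expect_equal(act$total, 2L)
  expect_equal(unname(act$counts["cna"]), 1L)
  expect_equal(unname(act$counts["expression"]), 1L)
})

test_that("removing a KB rule never increases an actionable count", {
  cohort <- generate_cohort(default_cohort_config(n_patients = 8, seed = 99))
  kb2 <- test_kb
  kb2$drug_rules <- kb2$drug_rules[kb2$drug_rules$rule_id != "DR001", ]
  for (p in cohort) {
    full <- actionability(p, predict_tier1_response(p, test_kb),
                          recommend_tier2(p, test_kb))
    reduced <- actionability(p, predict_tier1_response(p, kb2),
                             recommend_tier2(p, kb2))
    expect_lte(reduced$total, full$total)
  }
})
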