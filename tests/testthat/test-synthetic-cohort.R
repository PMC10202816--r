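small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 40, n_genes = 60, clone_richness = 100,
         total_templates = 5000),
    list(...)
  )
  do.call(cohort_config, args)
}

test_that("config validation enforces the documented invariants", {
  expect_s3_class(small_cfg(), "cohort_config")
  expect_error(cohort_config(n_samples = 0), "positive")
  expect_error(cohort_config(icr_group_proportions = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(cohort_config(clone_richness = 1), "undefined")
  expect_error(cohort_config(editing_strength = 0), "0, 1")
  expect_error(cohort_config(censoring_rate = 1.2), "censoring_rate")
  expect_error(cohort_config(n_risk_taxa = 80, n_protective_taxa = 30),
               "exceed")
})

test_that("expression generator plants the signature shift and only that", {
  cfg <- cohort_config(n_samples = 120, n_genes = 80, icr_effect = 2,
                       noise_sd = 1, seed = 5)
  out <- generate_expression(cfg)
  expect_equal(dim(out$expression), c(80, 120))
  expect_true(all(is.finite(out$expression)))
  sig <- icr_signature()$genes
  sc <- icr_score(out$expression)
  grp <- out$truth$true_icr_level
  means <- tapply(sc, grp, mean)
  expect_equal(unname(means["Medium"] - means["Low"]), 2, tolerance = 0.2)
  expect_equal(unname(means["High"] - means["Low"]), 4, tolerance = 0.2)
  # non-signature genes carry no group structure
  filler <- setdiff(rownames(out$expression), sig)
  fm <- colMeans(out$expression[filler, ])
  p <- anova(lm(fm ~ grp))$`Pr(>F)`[1]
  expect_gt(p, 0.01)
  # zero effect: signature genes statistically indistinguishable across groups
  out0 <- generate_expression(cohort_config(n_samples = 120, n_genes = 80,
                                            icr_effect = 0, seed = 6))
  p0 <- anova(lm(icr_score(out0$expression) ~ out0$truth$true_icr_level))$`Pr(>F)`[1]
  expect_gt(p0, 0.001)
  # determinism
  expect_identical(generate_expression(cfg)$expression, out$expression)
})

test_that("planted three-group cohorts are recovered by the clustering pipeline", {
  cfg <- cohort_config(n_samples = 150, icr_effect = 3, noise_sd = 1, seed = 17)
  out <- generate_expression(cfg)
  res <- consensus_cluster(out$expression, sig = icr_signature(),
                           k_range = 2:5, n_reps = 150, seed = 2)
  expect_equal(res$chosen_k, 3)
  ari <- rand_index_adj(res$final_labels, out$truth$true_icr_level)
  expect_gte(ari, 0.9)
  lab <- assign_icr_labels(res, out$expression)
  agree <- mean(as.character(lab$icr_cluster) ==
                  as.character(out$truth$true_icr_level))
  expect_gte(agree, 0.9)
})

test_that("repertoire pairs hit clonality targets and plant exactly the spiked clones", {
  cfg <- small_cfg(clone_richness = 500, total_templates = 20000)
  for (target in c(0, 0.1, 0.3)) {
    pr <- generate_repertoire_pair(cfg, target, seed = 31)
    real <- summarize_repertoire(pr$tumor)$clonality
    expect_lt(abs(real - target), 0.05)
  }
  # even limit: target 0 is near-uniform
  pr0 <- generate_repertoire_pair(cfg, 0, seed = 3)
  expect_lt(summarize_repertoire(pr0$tumor)$clonality, 0.05)
  # spiked clones are exactly the enriched set at the rule defaults
  pr5 <- generate_repertoire_pair(cfg, 0.2, n_spiked = 5, seed = 8)
  ov <- detect_tumor_enriched(pr5$tumor, pr5$normal)
  expect_setequal(ov$tumor_enriched, pr5$spiked_ids)
  # no spikes, disjoint background: enriched fraction equals the
  # brute-force template share of floor-passing clones
  prd <- generate_repertoire_pair(cfg, 0.2, shared_fraction = 0, seed = 9)
  ovd <- detect_tumor_enriched(prd$tumor, prd$normal)
  prod <- prd$tumor$clones[prd$tumor$clones$productive, ]
  freq <- prod$templates / sum(prod$templates)
  manual <- sum(prod$templates[freq > 0.001]) / sum(prod$templates)
  expect_equal(ovd$fraction_enriched, manual)
  # richness below 2 is rejected at the config level (entropy undefined)
  expect_error(small_cfg(clone_richness = 1), "undefined")
})

test_that("mutation generator respects the zero crossing and editing recovery works", {
  cfg <- cohort_config(n_samples = 400, editing_strength = 0.5, seed = 21)
  truth <- data.frame(sample = sprintf("S%04d", 1:400))
  mut <- generate_mutation_neoantigen(cfg, truth)
  # all draws stay above the expected-model zero crossing
  expect_true(all(mut$x > 26))
  expect_true(all(mut$observed_neoantigens >= 0))
  # hypermutated samples all exceed the 12/Mb class boundary
  expect_true(all(tmb_and_class(mut$x)$hypermutated == mut$hypermutated_true))
  # GIE recovery at the midpoint cutoff between the null and edited ratios
  g <- gie_evaluate(mut$observed_neoantigens, mut$x, edited_cutoff = 0.75)
  acc <- mean(g$edited == mut$edited_true, na.rm = TRUE)
  expect_gte(acc, 0.9)
  # null editing: ratios center on 1
  cfg1 <- cohort_config(n_samples = 300, editing_fraction = 0, seed = 22)
  mut1 <- generate_mutation_neoantigen(cfg1, data.frame(sample = sprintf("S%03d", 1:300)))
  g1 <- gie_evaluate(mut1$observed_neoantigens, mut1$x)
  expect_lt(abs(mean(g1$gie_value) - 1), 0.05)
})

test_that("microbiome tables close to 1 and survival reflects the planted hazards", {
  cfg <- small_cfg(seed = 41)
  truth <- generate_expression(cfg)$truth
  truth$edited_true <- rep(c(TRUE, FALSE), length.out = nrow(truth))
  micro <- generate_microbiome_survival(cfg, truth)
  expect_true(all(abs(rowSums(micro$abundance) - 1) < 1e-9))
  expect_true(all(micro$abundance >= 0))
  expect_equal(sum(micro$taxon_truth$true_risk_sign == "+"), cfg$n_risk_taxa)
  expect_equal(sum(micro$taxon_truth$true_risk_sign == "-"), cfg$n_protective_taxa)
  expect_true(all(micro$survival$time > 0))
  # higher true linear predictor means earlier events (rank association)
  c_lp <- harrell_c(micro$linear_predictor, micro$survival$time,
                    micro$survival$event)
  expect_gt(c_lp, 0.6)
  # null hazards: log-rank of an arbitrary split is calibrated
  cfg0 <- small_cfg(
    seed = 43,
    hazard_coefficients = list(icr_level = 0, edited = 0,
                               risk_taxon = 0, protective_taxon = 0)
  )
  micro0 <- generate_microbiome_survival(cfg0, truth)
  lr <- logrank_test(micro0$survival$time, micro0$survival$event,
                     truth$true_icr_level)
  expect_gt(lr$p, 0.001)
  # censoring calibration is close to the requested rate
  big <- cohort_config(n_samples = 2000, seed = 44)
  tbig <- data.frame(sample = sprintf("S%04d", 1:2000),
                     true_icr_level = factor(rep(c("Low", "Medium", "High"),
                                                 length.out = 2000),
                                             c("Low", "Medium", "High")),
                     edited_true = rep(c(TRUE, FALSE), 1000))
  mbig <- generate_microbiome_survival(big, tbig)
  expect_lt(abs(mean(mbig$survival$event == 0) - big$censoring_rate), 0.05)
})

test_that("linked cohorts share sample ids, honor missing-assay masks, and reproduce", {
  cfg <- cohort_config(n_samples = 50, n_genes = 60, clone_richness = 60,
                       total_templates = 3000, tcr_missing_fraction = 0.5,
                       seed = 61)
  co <- generate_cohort(cfg)
  ids <- co$truth$samples$sample
  expect_equal(colnames(co$expression), ids)
  expect_equal(rownames(co$abundance), ids)
  expect_equal(co$survival$sample, ids)
  expect_equal(co$clinical$sample, ids)
  expect_equal(co$mutation$sample, ids)
  # exactly ceiling(50 * 0.5) samples lack repertoires
  expect_equal(length(co$repertoires), 50 - ceiling(50 * 0.5))
  expect_true(all(names(co$repertoires) %in% ids))
  # fixed seed reproduces the bundle exactly
  co2 <- generate_cohort(cfg)
  expect_identical(co, co2)
})
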