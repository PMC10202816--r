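test_that("clonality matches hand Shannon evaluation and limits", {
  # counts (8,4,2,2): p = (.5,.25,.125,.125), H = 1.75 bits, J = .875
  expect_equal(clonality_from_counts(c(8, 4, 2, 2)), 0.125)
  # uniform distributions of any richness are exactly polyclonal
  for (s in c(2, 3, 7, 50)) {
    expect_equal(clonality_from_counts(rep(3, s)), 0)
  }
  # extreme skew approaches but never reaches 1
  v <- clonality_from_counts(c(999999, 1))
  expect_gt(v, 0.99)
  expect_lt(v, 1)
  # scale invariance
  expect_equal(clonality_from_counts(c(8, 4, 2, 2) * 10),
               clonality_from_counts(c(8, 4, 2, 2)))
  expect_error(clonality_from_counts(c(5, -1)), "non-negative")
  expect_error(clonality_from_counts(c(7)), "at least 2")
})

test_that("repertoire summary reports entropy, evenness, clonality over productive clones", {
  rep <- toy_repertoire(c(8, 4, 2, 2, 100),
                        productive = c(rep(TRUE, 4), FALSE))
  s <- summarize_repertoire(rep)
  expect_equal(s$entropy_bits, 1.75)
  expect_equal(s$normalized_entropy, 0.875)
  expect_equal(s$clonality, 0.125)
  expect_equal(s$total_templates, 116)
  expect_equal(s$productive_templates, 16)
  expect_equal(s$unique_productive_rearrangements, 4)
  expect_equal(s$max_productive_frequency, 0.5)

  expect_error(summarize_repertoire(toy_repertoire(c(5), productive = TRUE)),
               "fewer than 2")
  expect_error(
    summarize_repertoire(toy_repertoire(c(5, 3), productive = c(FALSE, FALSE))),
    "zero productive"
  )
})

test_that("entropy bounds and majorization hold on random repertoires", {
  withr::with_seed(7, {
    for (i in 1:500) {
      s <- sample(2:30, 1)
      counts <- rpois(s, lambda = sample(1:50, 1)) + 1
      rep <- toy_repertoire(counts)
      sm <- summarize_repertoire(rep)
      expect_gte(sm$entropy_bits, 0)
      expect_lte(sm$entropy_bits, log2(sm$unique_productive_rearrangements) + 1e-12)
      expect_gte(sm$clonality, 0)
      expect_lte(sm$clonality, 1)
    }
    # moving a template from the smallest to the largest clone raises clonality
    for (i in 1:100) {
      counts <- sort(rpois(3, 20) + 2)
      moved <- counts + c(-1, 0, 1)
      expect_gt(clonality_from_counts(moved), clonality_from_counts(counts))
    }
  })
})

test_that("tumor-enrichment rule applies the fold and strict-floor criteria", {
  # frequencies engineered via counts out of 10000 templates
  tumor <- toy_repertoire(c(20, 10, 40, 9930), sample_id = "P1-T")
  normal <- repertoire("P1-N", c("CL001", "CL002", "CL004"), c(1, 50, 9949))
  # CL001: tumor 0.2%, normal 0.01% -> ratio 20 < 32: not enriched
  # CL002: tumor 0.1% exactly: strict floor, not enriched regardless of ratio
  # CL003: tumor 0.4%, absent in normal: enriched under default policy
  # CL004: tumor 99.3%, normal ~99.5%: ratio ~1, not enriched
  ov <- detect_tumor_enriched(tumor, normal)
  expect_identical(ov$tumor_enriched, "CL003")
  # boundary: ratio exactly 32 counts as enriched (at least 32-fold)
  t2 <- repertoire("P2-T", c("A", "B"), c(32, 9968))
  n2 <- repertoire("P2-N", c("A", "B"), c(1, 9999))
  ov2 <- detect_tumor_enriched(t2, n2)
  expect_true("A" %in% ov2$tumor_enriched) # 0.32% / 0.01% = 32
  # pseudo-count policy penalizes absent-in-normal ratios
  ov3 <- detect_tumor_enriched(tumor, normal, absent_normal = "pseudocount",
                               pseudocount = 1)
  expect_false("CL003" %in% ov3$tumor_enriched)
  expect_error(detect_tumor_enriched(
    repertoire("E-T", "A", 0), normal
  ), "empty tumor")
})

test_that("detect_tumor_enriched equals a brute-force double loop on random pairs", {
  withr::with_seed(42, {
    for (i in 1:20) {
      n_t <- sample(10:40, 1)
      n_n <- sample(10:40, 1)
      pool <- sprintf("SEQ%02d", 1:50)
      t_ids <- sample(pool, n_t)
      n_ids <- sample(pool, n_n)
      tumor <- repertoire("T", t_ids, rpois(n_t, 30) + 1)
      normal <- repertoire("N", n_ids, rpois(n_n, 30) + 1)
      ov <- detect_tumor_enriched(tumor, normal,
                                  fold_threshold = 4, frequency_floor = 0.02)
      # brute force
      tf <- setNames(tumor$clones$templates / sum(tumor$clones$templates),
                     tumor$clones$clone_id)
      nf <- setNames(normal$clones$templates / sum(normal$clones$templates),
                     normal$clones$clone_id)
      expected <- names(tf)[vapply(names(tf), function(id) {
        f_n <- if (id %in% names(nf)) nf[[id]] else 0
        tf[[id]] > 0.02 && (f_n == 0 || tf[[id]] / f_n >= 4)
      }, logical(1))]
      expect_setequal(ov$tumor_enriched, expected)
    }
  })
})

test_that("fraction of tumor-enriched templates is template-weighted", {
  tumor <- toy_repertoire(c(30, 30, 60), sample_id = "P1-T")
  normal <- repertoire("P1-N", c("CL002", "CL003"), c(30, 60))
  # CL001 absent in normal, frequency 25% -> enriched; carries 30 of 120
  ov <- detect_tumor_enriched(tumor, normal)
  expect_identical(ov$tumor_enriched, "CL001")
  expect_equal(fraction_tumor_enriched(ov, tumor), 0.25)
  # no enriched clones -> 0
  same <- detect_tumor_enriched(tumor, tumor)
  expect_equal(fraction_tumor_enriched(same, tumor), 0)
  # all clones enriched -> 1
  empty_normal <- repertoire("P1-N", "OTHER", 100)
  all_ov <- detect_tumor_enriched(tumor, empty_normal)
  expect_equal(fraction_tumor_enriched(all_ov, tumor), 1)
  expect_error(fraction_tumor_enriched(ov, normal), "mismatch")
})
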