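test_that("icr_score is the per-sample mean of signature genes", {
  sig <- gene_signature("toy", sprintf("G%02d", 1:5))
  m <- toy_expr(n_genes = 10, n_samples = 6)
  s <- icr_score(m, sig)
  # brute-force mean on random matrices, exact
  expect_equal(s, colMeans(m[sig$genes, ]))
  # constant matrix
  mc <- matrix(3.7, 10, 4, dimnames = list(sprintf("G%02d", 1:10), letters[1:4]))
  expect_equal(unname(icr_score(mc, sig)), rep(3.7, 4))
  # hand mean: one sample with values 1..20 over a 20-gene signature
  sig20 <- gene_signature("s20", sprintf("H%02d", 1:20))
  m20 <- matrix(1:20, ncol = 1, dimnames = list(sprintf("H%02d", 1:20), "A"))
  expect_equal(unname(icr_score(m20, sig20)), 10.5)
  # permutation of gene rows changes nothing
  perm <- m[sample(rownames(m)), ]
  expect_equal(icr_score(perm, sig), s)
  # missing genes are named in the error
  expect_error(icr_score(m[-1, ], sig), "G01")
})

test_that("packaged ICR signature has the 20 expected genes", {
  sig <- icr_signature()
  expect_length(sig$genes, 20)
  expect_true(all(c("IFNG", "STAT1", "CD8A", "CXCL9", "GZMB", "PRF1",
                    "CD274", "PDCD1", "CTLA4", "FOXP3", "IDO1") %in% sig$genes))
  expect_false(anyDuplicated(sig$genes) > 0)
})

test_that("calinski_harabasz matches its closed form on hand-computed instances", {
  # two 1-d clusters: {0, 1} and {10, 11}; n = 4, k = 2
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(1, 1, 2, 2)
  # grand mean 5.5; ssb = 2*(0.5-5.5)^2 + 2*(10.5-5.5)^2 = 100; ssw = 1
  expect_equal(calinski_harabasz(x, lab), (100 / 1) * (4 - 2) / (2 - 1))
  # 6-point 2-d instance
  x2 <- rbind(c(0, 0), c(0, 1), c(1, 0), c(5, 5), c(5, 6), c(6, 5))
  lab2 <- rep(1:2, each = 3)
  grand <- colMeans(x2)
  ssb <- 3 * sum((colMeans(x2[1:3, ]) - grand)^2) +
    3 * sum((colMeans(x2[4:6, ]) - grand)^2)
  ssw <- sum(sweep(x2[1:3, ], 2, colMeans(x2[1:3, ]))^2) +
    sum(sweep(x2[4:6, ], 2, colMeans(x2[4:6, ]))^2)
  expect_equal(calinski_harabasz(x2, lab2), (ssb / ssw) * (6 - 2) / (2 - 1))
})

test_that("consensus clustering finds planted blobs and sharp consensus", {
  # two well-separated Gaussian blobs
  withr::with_seed(3, {
    m <- cbind(
      matrix(rnorm(20 * 12, 0, 0.3), 20),
      matrix(rnorm(20 * 12, 4, 0.3), 20)
    )
    dimnames(m) <- list(sprintf("G%02d", 1:20), sprintf("S%02d", 1:24))
  })
  res <- consensus_cluster(m, k_range = 2:4, n_reps = 120, seed = 5)
  expect_equal(res$chosen_k, 2)
  truth <- rep(1:2, each = 12)
  expect_equal(rand_index_adj(res$final_labels, truth), 1)
  # consensus entries concentrate near 0/1 for the planted structure
  cm <- res$consensus[["2"]]
  expect_true(all(abs(cm - 0.5) > 0.45))
  expect_true(isSymmetric(cm))
  expect_equal(unname(diag(cm)), rep(1, 24))
  expect_true(all(cm >= 0 & cm <= 1))
})

test_that("consensus clustering is deterministic under a fixed seed", {
  m <- icr_expr(n_samples = 24, effect = 2, seed = 9)$expr
  a <- consensus_cluster(m, sig = icr_signature(), k_range = 2:3,
                         n_reps = 50, seed = 11)
  b <- consensus_cluster(m, sig = icr_signature(), k_range = 2:3,
                         n_reps = 50, seed = 11)
  expect_identical(a$consensus, b$consensus)
  expect_identical(a$final_labels, b$final_labels)
})

test_that("ICR labeling ranks clusters by mean score with degenerate-k handling", {
  fx <- icr_expr(n_samples = 30, effect = 3, seed = 2)
  res <- consensus_cluster(fx$expr, sig = icr_signature(), k_range = 2:4,
                           n_reps = 100, seed = 4)
  expect_equal(res$chosen_k, 3)
  lab <- assign_icr_labels(res, fx$expr)
  # cluster with highest score must be High, lowest Low
  agg <- tapply(lab$icr_score, lab$icr_cluster, mean)
  expect_true(agg["Low"] < agg["Medium"] && agg["Medium"] < agg["High"])
  # planted group index should match the ordered labels
  expect_gte(mean(as.integer(lab$icr_cluster) - 1 == fx$group), 0.9)

  # k = 2: only High/Low, with a warning
  res2 <- res
  res2$chosen_k <- 2
  res2$final_labels <- res$labels[["2"]]
  expect_warning(lab2 <- assign_icr_labels(res2, fx$expr), "not 3")
  expect_true(all(lab2$icr_cluster %in% c("Low", "High")))
})

test_that("ssgsea scores rank set-loaded samples above set-depleted ones", {
  genes <- sprintf("G%02d", 1:20)
  set <- genes[1:5]
  # sample A: set genes at the top; sample B: at the bottom
  a <- c(seq(10, 9.2, length.out = 5), seq(5, 1, length.out = 15))
  b <- c(seq(1.8, 1, length.out = 5), seq(10, 5, length.out = 15))
  m <- cbind(A = a, B = b)
  rownames(m) <- genes
  sc <- ssgsea_scores(m, list(myset = set))
  expect_gt(sc["myset", "A"], sc["myset", "B"])
  # duplicated sample column gives identical scores
  m2 <- cbind(m, A2 = a)
  rownames(m2) <- genes
  sc2 <- ssgsea_scores(m2, list(myset = set))
  expect_equal(sc2["myset", "A"], sc2["myset", "A2"])
  expect_error(ssgsea_scores(m, list(void = c("NOPE1", "G01"))), "void")
})

test_that("ssgsea with exponent 0 equals the brute-force unweighted walk", {
  withr::with_seed(21, {
    for (i in 1:10) {
      m <- toy_expr(n_genes = 12, n_samples = 3, seed = i)
      set <- sample(rownames(m), 5)
      sc <- ssgsea_scores(m, list(s = set), weight_exponent = 0)
      for (j in seq_len(ncol(m))) {
        expect_equal(
          unname(sc["s", j]),
          oracle_ssgsea_unweighted(m[, j], rownames(m) %in% set)
        )
      }
    }
  })
})
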