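test_that("KM estimate matches hand product-limit computation and trivial limits", {
  # records: 1 censored, events at 2, 3, 4
  time <- c(1, 2, 3, 4)
  event <- c(0, 1, 1, 1)
  km <- km_estimate(time, event)
  # hand: S(2) = 2/3, S(3) = 2/3 * 1/2, S(4) = 0
  expect_equal(km_surv_at(km, c(1.5, 2, 2.9, 3, 4)),
               c(1, 2 / 3, 2 / 3, 1 / 3, 0))
  # oracle at arbitrary query times on random data
  withr::with_seed(14, {
    t2 <- rexp(40) + 0.1
    e2 <- rbinom(40, 1, 0.6)
    km2 <- km_estimate(t2, e2)
    for (q in quantile(t2, c(0.2, 0.5, 0.9))) {
      expect_equal(km_surv_at(km2, q), oracle_km(t2, e2, q))
    }
    # no censoring: KM equals the empirical survival function
    km3 <- km_estimate(t2, rep(1, 40))
    for (q in quantile(t2, c(0.3, 0.7))) {
      expect_equal(km_surv_at(km3, q), mean(t2 > q))
    }
  })
  # single event at t = 5
  km4 <- km_estimate(5, 1)
  expect_equal(km_surv_at(km4, c(4.9, 5, 6)), c(1, 0, 0))
  # all censored
  km5 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km_surv_at(km5, 10), 1)
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank equals brute-force tabulation and respects its null", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 0, 1)
  group <- c("a", "b", "a", "b", "a", "b")
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chisq, oracle_logrank(time, event, group), tolerance = 1e-9)
  expect_equal(lr$df, 1)
  # identical event/censor patterns in both groups: statistic ~ 0
  t2 <- rep(c(1, 2, 3, 4), 2)
  e2 <- rep(c(1, 0, 1, 1), 2)
  g2 <- rep(c("x", "y"), each = 4)
  lr2 <- logrank_test(t2, e2, g2)
  expect_lt(lr2$chisq, 1e-10)
  expect_gt(lr2$p, 0.999)
  # invariance under strictly increasing time transforms
  withr::with_seed(4, {
    t3 <- rexp(60) + 0.5
    e3 <- rbinom(60, 1, 0.7)
    g3 <- rep(c("u", "v"), 30)
    a <- logrank_test(t3, e3, g3)
    b <- logrank_test(log(t3 + 1), e3, g3)
    expect_equal(a$chisq, b$chisq)
  })
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "2 non-empty")
})

test_that("Cox fit equals brute-force partial-likelihood maximization on a toy", {
  # 8 records, distinct times, single binary covariate, no ties
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 1, 0, 1, 0, 1, 0, 0)
  fit <- fit_coxph(time, event, data.frame(x = x), override_min_group = TRUE)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), time, event, x)
  expect_equal(fit$terms$coef, grid[which.max(ll)], tolerance = 1e-3)
  expect_true(fit$terms$lower < fit$terms$hr & fit$terms$hr < fit$terms$upper)
  # group-size guard: a 9-patient arm errors without the override
  tg <- c(rexp(9) + 0.1, rexp(20) + 0.1)
  eg <- rep(1, 29)
  gg <- factor(rep(c("small", "big"), c(9, 20)))
  expect_error(fit_coxph(tg, eg, data.frame(g = gg)), "below the minimum")
  expect_s3_class(
    fit_coxph(tg, eg, data.frame(g = gg), override_min_group = TRUE),
    "cox_fit"
  )
})

test_that("Cox coefficient recovery stays within 3 standard errors", {
  withr::with_seed(99, {
    hits <- vapply(1:25, function(i) {
      d <- toy_survival(n = 150, beta = 0.7, seed = 1000 + i)
      fit <- fit_coxph(d$time, d$event, data.frame(x = d$x))
      se <- sqrt(fit$fit$var[1, 1])
      abs(fit$terms$coef - 0.7) < 3 * se
    }, logical(1))
    expect_gte(mean(hits), 0.99 - 0.12) # 25 runs; allow one miss
  })
})

test_that("Harrell C matches the O(n^2) oracle and its symmetries", {
  withr::with_seed(23, {
    for (i in 1:10) {
      d <- toy_survival(n = 20, beta = 0.5, seed = 300 + i)
      s <- rnorm(20)
      expect_equal(harrell_c(s, d$time, d$event),
                   oracle_harrell_c(s, d$time, d$event))
      # antisymmetry (continuous scores, no ties)
      expect_equal(harrell_c(-s, d$time, d$event),
                   1 - harrell_c(s, d$time, d$event))
    }
    # perfect ranking: higher score = earlier event, no censoring
    t0 <- sort(rexp(15)) + 0.01
    expect_equal(harrell_c(-t0, t0, rep(1, 15)), 1)
    # constant scores: everything ties
    expect_equal(harrell_c(rep(2, 15), t0, rep(1, 15)), 0.5)
  })
  expect_error(harrell_c(1, 5, 0), "usable")
})

test_that("density-matched subsampling is deterministic and null-calibrated", {
  withr::with_seed(55, {
    n <- 300
    score <- rnorm(n)
    d <- toy_survival(n = n, beta = 0, seed = 77)
    target <- rnorm(500)
    res <- density_matched_subsampling(
      d$time, d$event, d$x, score,
      target_score_sample = target,
      n_subsets = 20, subset_size = 100, seed = 9
    )
    res2 <- density_matched_subsampling(
      d$time, d$event, d$x, score,
      target_score_sample = target,
      n_subsets = 20, subset_size = 100, seed = 9
    )
    expect_identical(res$members_uniform, res2$members_uniform)
    expect_identical(res$members_density_matched, res2$members_density_matched)
    # null covariate: few significant subsets under either scheme
    expect_lte(max(res$n_significant), 5)
    expect_error(
      density_matched_subsampling(d$time, d$event, d$x, score,
                                  target_score_sample = rep(1, 100),
                                  subset_size = 100),
      "degenerate"
    )
  })
})
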