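# shared fixtures, built in code at test time

# small expression matrix with named genes/samples
toy_expr <- function(n_genes = 10, n_samples = 6, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, mean = 6),
                nrow = n_genes,
                dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                                sprintf("S%02d", seq_len(n_samples))))
    m
  })
}

# expression matrix carrying the packaged ICR signature plus filler genes
icr_expr <- function(n_samples = 30, effect = 0, seed = 1, noise_sd = 1) {
  sig <- icr_signature()$genes
  genes <- c(sig, sprintf("F%03d", 1:30))
  withr::with_seed(seed, {
    group <- rep(c(0, 1, 2), length.out = n_samples)
    m <- matrix(rnorm(length(genes) * n_samples, mean = 6, sd = noise_sd),
                nrow = length(genes),
                dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
    m[sig, ] <- m[sig, ] + rep(effect * group, each = length(sig))
    list(expr = m, group = group)
  })
}

# tiny repertoire from a count vector
toy_repertoire <- function(counts, productive = rep(TRUE, length(counts)),
                           sample_id = "T01") {
  repertoire(sample_id, sprintf("CL%03d", seq_along(counts)),
             counts, productive)
}

# exponential proportional-hazards survival data with one covariate
toy_survival <- function(n = 100, beta = 0, censor = 0.3, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    t_event <- rexp(n, rate = 0.2 * exp(beta * x))
    cens <- rexp(n, rate = 0.2 * censor / (1 - censor))
    data.frame(
      time = pmin(t_event, cens),
      event = as.integer(t_event <= cens),
      x = x
    )
  })
}

# brute-force oracles ------------------------------------------------------

# product-limit estimator by direct tabulation
oracle_km <- function(time, event, at) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  for (t0 in ts[ts <= at]) {
    n_risk <- sum(time >= t0)
    d <- sum(time == t0 & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# two-group log-rank by direct tabulation over event times
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  ts <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t0 in ts) {
    at_risk <- time >= t0
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t0 & event == 1)
    d1 <- sum(time == t0 & event == 1 & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# Harrell C by explicit double loop
oracle_harrell_c <- function(scores, time, event) {
  num <- den <- 0
  n <- length(scores)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    usable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!usable) next
    den <- den + 1
    if (scores[i] > scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  num / den
}

# Cox partial log-likelihood for a single covariate, Breslow ties
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# unweighted ssGSEA walk by direct enumeration
oracle_ssgsea_unweighted <- function(values, in_set) {
  ord <- order(values, decreasing = TRUE)
  inset_sorted <- in_set[ord]
  n <- length(values)
  p_in <- cumsum(inset_sorted) / sum(inset_sorted)
  p_out <- cumsum(!inset_sorted) / (n - sum(inset_sorted))
  sum(p_in - p_out)
}

# adjusted Rand index between two labelings
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_i * sum_j / comb2(n)
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
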