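#' Kaplan-Meier product-limit estimate
#'
#' Thin, contract-checked wrapper around the product-limit estimator, with
#' a step-function query for survival probability at a horizon (e.g. 5-year
#' survival). The survival function is right-continuous: `S(t)` is the
#' value after all events at times `<= t`.
#'
#' @param time positive event/censoring times.
#' @param event 0 = censored, 1 = event.
#' @return Object of class `"km_curve"`: `time`, `surv`, `n_risk`,
#'   `n_event`, `n_censor` plus the underlying `survfit` object.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop_("need at least one record")
  if (any(time <= 0)) stop_("times must be positive")
  if (!all(event %in% c(0, 1))) stop_("`event` must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(
    list(
      time = fit$time, surv = fit$surv,
      n_risk = fit$n.risk, n_event = fit$n.event, n_censor = fit$n.censor,
      fit = fit
    ),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d time points, %d events\n",
              length(x$time), sum(x$n_event)))
  invisible(x)
}

#' @rdname km_estimate
#' @param curve a `km_curve`.
#' @param at horizon time(s) at which to read the step function.
#' @export
km_surv_at <- function(curve, at) {
  if (!inherits(curve, "km_curve")) stop_("`curve` must be a km_curve")
  vapply(at, function(t0) {
    idx <- which(curve$time <= t0)
    if (!length(idx)) 1 else curve$surv[max(idx)]
  }, numeric(1))
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank comparison of survival between
#' two or more groups, with `groups - 1` degrees of freedom.
#'
#' @param time,event survival data (see [km_estimate()]).
#' @param group group label per record; at least two non-empty groups.
#' @return List with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stop_("need at least 2 non-empty groups")
  if (sum(event) < 1) stop_("need at least 1 event")
  if (any(time <= 0)) stop_("times must be positive")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd_$n) - 1
  list(chisq = unname(sd_$chisq), df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Cox regression (Efron tie handling by default) with
#' the reporting contract used throughout: hazard ratios with Wald 95%
#' confidence intervals on the log-hazard scale, per-term Wald p-values,
#' the overall likelihood-ratio p and the model concordance. When the model
#' is a single two-level contrast, the fit is guarded: both groups must
#' contain at least `min_group_size` patients (default 10) unless
#' `override_min_group = TRUE`.
#'
#' @param time,event survival data.
#' @param covariates data frame of covariates (numeric, factor or ordered;
#'   ordered factors are encoded as their integer level, i.e. an ordinal
#'   trend term).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level confidence level for the HR interval.
#' @param min_group_size minimum per-group size for a two-group contrast.
#' @param override_min_group disable the group-size guard.
#' @return Object of class `"cox_fit"`: `terms` data frame (`term`, `coef`,
#'   `hr`, `lower`, `upper`, `p`), overall `lr_p` (likelihood ratio) and
#'   `score_p` (score test, the log-rank-type overall p), `concordance`,
#'   `n`, `n_event`, and the underlying `coxph` fit.
#' @export
fit_coxph <- function(time, event, covariates, ties = c("efron", "breslow"),
                      conf_level = 0.95, min_group_size = 10,
                      override_min_group = FALSE) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (any(time <= 0)) stop_("times must be positive")
  n_par <- sum(vapply(covariates, function(v) {
    if (is.ordered(v)) 1L
    else if (is.factor(v) || is.character(v)) {
      max(1L, length(unique(v[!is.na(v)])) - 1L)
    } else 1L
  }, integer(1)))
  if (sum(event) < n_par + 1) {
    stop_(sprintf("insufficient events (%d) for %d parameters",
                  sum(event), n_par))
  }
  if (ncol(covariates) == 1 && !override_min_group) {
    v <- covariates[[1]]
    if ((is.factor(v) || is.character(v) || length(unique(v)) == 2)) {
      tab <- table(v)
      if (length(tab) == 2 && any(tab < min_group_size)) {
        stop_(sprintf(
          "group sizes (%s) below the minimum of %d; set override_min_group = TRUE to force",
          paste(tab, collapse = ", "), min_group_size
        ))
      }
    }
  }
  # ordinal covariates enter as integer scores
  covariates[] <- lapply(covariates, function(v) {
    if (is.ordered(v)) as.integer(v) else v
  })
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat, ties = ties),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w))) {
        stop_("Cox model failed to converge: ", conditionMessage(w))
      }
      if (grepl("infinite", conditionMessage(w))) {
        warn_("possible separation: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit, conf.int = conf_level)
  co <- s$coefficients
  ci <- s$conf.int
  terms <- data.frame(
    term = rownames(co),
    coef = co[, "coef"],
    hr = exp(co[, "coef"]),
    lower = ci[, 3],
    upper = ci[, 4],
    p = co[, "Pr(>|z|)"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      terms = terms,
      lr_p = unname(s$logtest["pvalue"]),
      score_p = unname(s$sctest["pvalue"]),
      concordance = unname(s$concordance[1]),
      n = s$n, n_event = fit$nevent,
      ties = ties,
      fit = fit
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, concordance %.3f\n",
              x$n, x$n_event, x$ties, x$concordance))
  df <- x$terms
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %s: HR %.3f (%.3f-%.3f), p = %.3g\n",
                df$term[i], df$hr[i], df$lower[i], df$upper[i], df$p[i]))
  }
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs in which the sample with the higher risk score
#' experienced the event earlier. A pair is usable when the shorter
#' follow-up ended in an event (including ties in time where exactly one
#' member had an event). Score ties count 0.5.
#'
#' @param scores risk scores (higher = higher predicted hazard).
#' @param time,event survival data aligned to `scores`.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(scores, time, event) {
  n <- length(scores)
  if (length(time) != n || length(event) != n) {
    stop_("`scores`, `time` and `event` must be aligned")
  }
  dt <- outer(time, time, "-") # dt[i,j] = t_i - t_j
  ei <- matrix(event == 1, n, n)
  # pair (i, j): i is the "earlier event" member
  usable_ij <- (dt < 0 & ei) | (dt == 0 & ei & t(!ei))
  ds <- outer(scores, scores, "-")
  num <- sum(usable_ij & ds > 0) + 0.5 * sum(usable_ij & ds == 0)
  den <- sum(usable_ij)
  if (den == 0) stop_("no usable pairs for concordance")
  num / den
}

#' Density-matched subsampling experiment
#'
#' Compares two subsampling schemes of a cohort: (A) uniform subsets and
#' (B) subsets drawn with weights proportional to a target density (a
#' piecewise-linear interpolation of a fixed-grid histogram of the target
#' score sample, evaluated at each case's matching score). Each subset is
#' fit with a univariate Cox model of `covariate`; the number of subsets
#' with a significant fit (Wald p < `alpha`) is compared between schemes
#' with a 2x2 chi-squared test. This probes whether an association's
#' significance depends on the cohort's composition along the matching
#' score.
#'
#' @param time,event survival data for the source cohort.
#' @param covariate numeric covariate tested in each subset.
#' @param matching_score per-case score on which the target density is
#'   matched (e.g. a stromal/immune infiltration score).
#' @param target_score_sample scores from the target cohort whose density
#'   scheme B reproduces.
#' @param n_subsets subsets per scheme (default 100).
#' @param subset_size cases per subset (default 200).
#' @param n_bins histogram bins for the target density (default 30).
#' @param alpha significance threshold per subset.
#' @param seed integer seed (subset memberships are deterministic given it).
#' @return List with `n_significant` (named: uniform, density_matched),
#'   `n_subsets`, `chisq`, `p`, and the subset membership index lists.
#' @export
density_matched_subsampling <- function(time, event, covariate,
                                        matching_score, target_score_sample,
                                        n_subsets = 100, subset_size = 200,
                                        n_bins = 30, alpha = 0.05, seed = 1) {
  n <- length(time)
  if (subset_size > n) stop_("`subset_size` exceeds the cohort size")
  if (!all(is.finite(matching_score))) stop_("matching scores must be finite")
  if (diff(range(target_score_sample)) == 0) {
    stop_("degenerate target density: all mass at one point")
  }
  br <- seq(min(target_score_sample), max(target_score_sample),
            length.out = n_bins + 1)
  h <- graphics::hist(target_score_sample, breaks = br, plot = FALSE)
  dens_fun <- approxfun(h$mids, h$density, yleft = 0, yright = 0, rule = 1)
  w <- dens_fun(matching_score)
  w[is.na(w)] <- 0
  if (sum(w > 0) < subset_size) {
    stop_("fewer cases with positive matching weight than `subset_size`")
  }
  w <- w / sum(w)
  run_scheme <- function(prob) {
    sig <- logical(n_subsets)
    members <- vector("list", n_subsets)
    for (b in seq_len(n_subsets)) {
      idx <- sample.int(n, subset_size, replace = FALSE, prob = prob)
      members[[b]] <- sort(idx)
      fit <- survival::coxph(
        survival::Surv(time[idx], event[idx]) ~ covariate[idx]
      )
      p <- summary(fit)$coefficients[1, "Pr(>|z|)"]
      sig[b] <- is.finite(p) && p < alpha
    }
    list(sig = sig, members = members)
  }
  res <- with_seed(seed, {
    a <- run_scheme(NULL)
    b <- run_scheme(w)
    list(a = a, b = b)
  })
  counts <- c(uniform = sum(res$a$sig), density_matched = sum(res$b$sig))
  tab <- rbind(counts, n_subsets - counts)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(
    n_significant = counts,
    n_subsets = n_subsets,
    chisq = unname(ct$statistic),
    p = unname(ct$p.value),
    members_uniform = res$a$members,
    members_density_matched = res$b$members
  )
}
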