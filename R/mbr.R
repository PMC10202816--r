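#' Fit per-taxon standardization parameters on a training table
#'
#' Records the training mean and standard deviation (sample estimator,
#' n - 1 denominator) of each taxon's relative abundance. These parameters
#' travel with the trained MBR model so that any tested sample is z-scored
#' against the TRAINING distribution, never its own cohort's.
#'
#' @param table relative abundance matrix, samples x taxa, >= 2 samples.
#' @return Object of class `"standardization_params"`: data frame with
#'   `taxon`, `mean`, `sd` and a `zero_sd` flag.
#' @export
fit_standardization <- function(table) {
  x <- as.matrix(table)
  if (nrow(x) < 2) stop_("need at least 2 samples to estimate a standard deviation")
  if (is.null(colnames(x))) stop_("table must have taxon column names")
  params <- data.frame(
    taxon = colnames(x),
    mean = colMeans(x),
    sd = apply(x, 2, sd),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  params$zero_sd <- params$sd == 0
  if (any(params$zero_sd)) {
    warn_(sprintf("constant taxa with zero sd flagged: %s",
                  paste(params$taxon[params$zero_sd], collapse = ", ")))
  }
  structure(params, class = c("standardization_params", "data.frame"))
}

#' @rdname fit_standardization
#' @param params a `standardization_params` object.
#' @param invert undo the transform instead of applying it.
#' @export
apply_standardization <- function(table, params, invert = FALSE) {
  x <- as.matrix(table)
  common <- intersect(colnames(x), params$taxon)
  if (!length(common)) stop_("no overlap between table taxa and parameters")
  p <- params[match(common, params$taxon), ]
  x <- x[, common, drop = FALSE]
  sds <- ifelse(p$sd == 0, 1, p$sd)
  if (invert) {
    sweep(sweep(x, 2, sds, "*"), 2, p$mean, "+")
  } else {
    sweep(sweep(x, 2, p$mean, "-"), 2, sds, "/")
  }
}

#' Train the microbiome risk (MBR) signature
#'
#' Fits a relaxed elastic-net Cox model of overall survival on z-scored
#' genus abundances and selects its hyperparameters — the relaxation mixing
#' `gamma` and the penalty `lambda` — by k-fold cross-validated Harrell
#' concordance over a grid (`gamma` in `{0, 0.25, 0.5, 0.75, 1}` crossed
#' with the solver's `lambda` path). Out-of-fold concordance is computed
#' only on held-out samples; the selected point is refit on the full
#' training table. Taxa with nonzero coefficients form the MBR classifier.
#'
#' The penalized Cox solver is glmnet; the cross-validation harness,
#' concordance metric, grid search, standardization and score-transfer
#' logic are implemented here.
#'
#' @param table relative abundance matrix (samples x taxa), already
#'   filtered (see [prevalence_abundance_filter()]).
#' @param time,event overall survival data aligned to the table's rows.
#' @param k_folds cross-validation folds (default 5).
#' @param gamma_grid relaxation mixing values; 1 = fully penalized fit,
#'   0 = unpenalized refit on the active set.
#' @param alpha elastic-net mixing between ridge (0) and lasso (1);
#'   default 0.5.
#' @param nlambda length of the lambda path (default 50).
#' @param lambda_min_ratio smallest lambda as a fraction of the largest
#'   (default 0.05, keeping the relaxed refits well-posed).
#' @param seed integer seed controlling fold assignment.
#' @return Object of class `"mbr_model"`: `taxa`, full `coefficients`
#'   vector, `classifier` (nonzero subset), `standardization`
#'   ([fit_standardization()] on the training table), `hyperparameters`
#'   (`gamma`, `lambda`, `alpha`), `cv` (grid of mean out-of-fold
#'   concordance), `k_folds`, `seed`.
#' @export
train_mbr <- function(table, time, event, k_folds = 5,
                      gamma_grid = c(0, 0.25, 0.5, 0.75, 1),
                      alpha = 0.5, nlambda = 50, lambda_min_ratio = 0.05,
                      seed = 1) {
  x_raw <- as.matrix(table)
  n <- nrow(x_raw)
  if (length(time) != n || length(event) != n) {
    stop_("survival data must align with the table rows")
  }
  if (sum(event) < k_folds) stop_("need at least as many events as folds")
  std <- fit_standardization(x_raw)
  usable <- std$taxon[!std$zero_sd]
  x <- apply_standardization(x_raw, std)[, usable, drop = FALSE]
  y <- survival::Surv(time, event)

  # do.call embeds evaluated arguments: the relaxed path re-evaluates its
  # own call internally, which fails with promises to local variables
  # muffle the solver's benign relaxed-path chatter (empty active set at
  # lambda_max, truncated path); real failures still surface as errors
  quiet_glmnet <- function(args) {
    withCallingHandlers(
      do.call(glmnet::glmnet, args),
      warning = function(w) {
        if (grepl("empty model|Numerical error|Convergence for|solutions for larger",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  path_fit <- quiet_glmnet(list(
    x = x, y = y, family = "cox", alpha = alpha,
    nlambda = nlambda, lambda.min.ratio = lambda_min_ratio,
    standardize = FALSE, relax = TRUE
  ))
  lambda_path <- path_fit$lambda

  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  cv_c <- array(
    NA_real_,
    dim = c(length(gamma_grid), length(lambda_path), k_folds),
    dimnames = list(gamma = gamma_grid, lambda = NULL, fold = NULL)
  )
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    te <- !tr
    if (sum(event[te]) == 0) next
    fit_f <- quiet_glmnet(list(
      x = x[tr, , drop = FALSE], y = y[tr, ], family = "cox",
      alpha = alpha, lambda = lambda_path, standardize = FALSE, relax = TRUE
    ))
    for (gi in seq_along(gamma_grid)) {
      lp <- predict(fit_f, newx = x[te, , drop = FALSE],
                    s = lambda_path, gamma = gamma_grid[gi],
                    type = "link")
      for (li in seq_len(ncol(lp))) {
        cv_c[gi, li, f] <- tryCatch(
          harrell_c(lp[, li], time[te], event[te]),
          error = function(e) 0.5 # constant predictor: no information
        )
      }
    }
  }
  mean_c <- apply(cv_c, c(1, 2), mean, na.rm = TRUE)
  best <- which(mean_c == max(mean_c, na.rm = TRUE), arr.ind = TRUE)
  # deterministic tie-break: largest lambda (sparser), then largest gamma
  best <- best[order(-best[, 2], -best[, 1]), , drop = FALSE][1, ]
  gamma_opt <- gamma_grid[best[1]]
  lambda_opt <- lambda_path[best[2]]

  beta <- as.numeric(predict(path_fit, s = lambda_opt, gamma = gamma_opt,
                             type = "coefficients"))
  names(beta) <- colnames(x)
  coefficients <- setNames(numeric(nrow(std)), std$taxon)
  coefficients[names(beta)] <- beta
  classifier <- coefficients[coefficients != 0]
  if (!length(classifier)) {
    warn_("all coefficients are zero at the selected hyperparameters; empty classifier")
  }
  structure(
    list(
      taxa = std$taxon,
      coefficients = coefficients,
      classifier = classifier,
      standardization = std,
      hyperparameters = list(gamma = gamma_opt, lambda = lambda_opt,
                             alpha = alpha),
      cv = list(gamma_grid = gamma_grid, lambda_path = lambda_path,
                mean_concordance = mean_c,
                best_concordance = max(mean_c, na.rm = TRUE)),
      k_folds = k_folds,
      seed = seed
    ),
    class = "mbr_model"
  )
}

#' @export
print.mbr_model <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<mbr_model> %d taxa, %d in classifier\n",
      "  gamma = %g, lambda = %.5g, alpha = %g; CV concordance %.3f\n"
    ),
    length(x$taxa), length(x$classifier),
    x$hyperparameters$gamma, x$hyperparameters$lambda,
    x$hyperparameters$alpha, x$cv$best_concordance
  ))
  invisible(x)
}

#' Score samples with a trained MBR model
#'
#' A sample's MBR score is the sum over classifier taxa present in the
#' table of coefficient times the abundance z-scored with the TRAINING mean
#' and sd. Classifier taxa absent from the table contribute zero;
#' non-classifier columns are ignored, so scores are invariant to extra
#' columns and to column order, and each sample's score is independent of
#' the other samples in the batch. Scores are binarized at 0: `low` risk
#' strictly below 0, `high` otherwise.
#'
#' @param model an [train_mbr()] model (or one read back with
#'   [read_mbr_model()]).
#' @param table relative abundance matrix, samples x taxa (harmonize taxon
#'   labels first if needed, see [harmonize_taxa()]).
#' @return Data frame with `sample`, `score`, `risk_group`.
#' @export
score_mbr <- function(model, table) {
  if (!inherits(model, "mbr_model")) stop_("`model` must be an mbr_model")
  x <- as.matrix(table)
  if (!length(model$classifier)) stop_("model has an empty classifier")
  cls <- names(model$classifier)
  overlap <- intersect(cls, colnames(x))
  if (!length(overlap)) {
    stop_(sprintf(
      "no classifier taxa found in the table; classifier needs any of: %s",
      paste(cls, collapse = ", ")
    ))
  }
  std <- model$standardization
  p <- std[match(overlap, std$taxon), ]
  drop_sd0 <- p$taxon[p$zero_sd]
  if (length(drop_sd0)) {
    warn_(sprintf("excluding zero-training-sd taxa: %s",
                  paste(drop_sd0, collapse = ", ")))
    overlap <- setdiff(overlap, drop_sd0)
    if (!length(overlap)) stop_("no usable classifier taxa after sd filter")
    p <- std[match(overlap, std$taxon), ]
  }
  z <- sweep(sweep(x[, overlap, drop = FALSE], 2, p$mean, "-"), 2, p$sd, "/")
  score <- as.numeric(z %*% model$classifier[overlap])
  data.frame(
    sample = rownames(x) %||% as.character(seq_len(nrow(x))),
    score = score,
    risk_group = ifelse(score < 0, "low", "high"),
    stringsAsFactors = FALSE
  )
}

#' Evaluate a trained MBR model on a cohort
#'
#' Harrell's concordance of the MBR score against survival, plus the Cox
#' hazard contrast of the high- versus low-risk groups (reference: low).
#'
#' @param model an `mbr_model`.
#' @param table abundance matrix for the evaluation cohort.
#' @param time,event survival data aligned to the table rows.
#' @param ... passed to [fit_coxph()] (e.g. `override_min_group`).
#' @return List with `concordance`, `scores` and `contrast` (a [fit_coxph()]
#'   result, or `NULL` with a message when only one risk group is present).
#' @export
evaluate_mbr <- function(model, table, time, event, ...) {
  sc <- score_mbr(model, table)
  cidx <- harrell_c(sc$score, time, event)
  contrast <- NULL
  if (length(unique(sc$risk_group)) < 2) {
    message("only one risk group present; hazard contrast omitted")
  } else {
    contrast <- fit_coxph(
      time, event,
      data.frame(mbr_group = factor(sc$risk_group, levels = c("low", "high"))),
      ...
    )
  }
  list(concordance = cidx, scores = sc, contrast = contrast)
}

#' Serialize an MBR model to a versioned plain-text file
#'
#' Key/value header plus a tab-separated coefficient table (taxon,
#' coefficient, training mean, training sd). Numbers are written with 17
#' significant digits so the round-trip through [read_mbr_model()] is
#' bit-exact.
#'
#' @param model an `mbr_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mbr_model <- function(model, path) {
  if (!inherits(model, "mbr_model")) stop_("`model` must be an mbr_model")
  num <- function(v) sprintf("%.17g", v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# colomics MBR model",
    "format_version: 1",
    sprintf("alpha: %s", num(model$hyperparameters$alpha)),
    sprintf("gamma: %s", num(model$hyperparameters$gamma)),
    sprintf("lambda: %s", num(model$hyperparameters$lambda)),
    sprintf("k_folds: %d", model$k_folds),
    sprintf("seed: %d", as.integer(model$seed)),
    sprintf("cv_concordance: %s", num(model$cv$best_concordance)),
    "coefficients:",
    "taxon\tcoefficient\tmean\tsd"
  ), con)
  std <- model$standardization
  for (i in seq_along(model$taxa)) {
    writeLines(sprintf(
      "%s\t%s\t%s\t%s",
      model$taxa[i], num(model$coefficients[i]),
      num(std$mean[i]), num(std$sd[i])
    ), con)
  }
  invisible(path)
}

#' @rdname write_mbr_model
#' @export
read_mbr_model <- function(path) {
  lines <- readLines(path)
  kv_line <- function(key) {
    ln <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (!length(ln)) stop_(sprintf("model file missing key '%s'", key))
    sub(paste0("^", key, ": "), "", ln[1])
  }
  hdr <- which(lines == "taxon\tcoefficient\tmean\tsd")
  if (!length(hdr)) stop_("model file missing the coefficient table")
  tab <- read.delim(text = lines[(hdr + 1):length(lines)], header = FALSE,
                    col.names = c("taxon", "coefficient", "mean", "sd"),
                    colClasses = c("character", "numeric", "numeric", "numeric"))
  coefficients <- setNames(tab$coefficient, tab$taxon)
  std <- structure(
    data.frame(taxon = tab$taxon, mean = tab$mean, sd = tab$sd,
               zero_sd = tab$sd == 0, stringsAsFactors = FALSE),
    class = c("standardization_params", "data.frame")
  )
  cvc <- as.numeric(kv_line("cv_concordance"))
  structure(
    list(
      taxa = tab$taxon,
      coefficients = coefficients,
      classifier = coefficients[coefficients != 0],
      standardization = std,
      hyperparameters = list(
        gamma = as.numeric(kv_line("gamma")),
        lambda = as.numeric(kv_line("lambda")),
        alpha = as.numeric(kv_line("alpha"))
      ),
      cv = list(best_concordance = cvc),
      k_folds = as.integer(kv_line("k_folds")),
      seed = as.integer(kv_line("seed"))
    ),
    class = "mbr_model"
  )
}
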