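#' Composite mICRoScore assignment
#'
#' A sample is mICRoScore `high` only when it is both ICR High and MBR low
#' risk; samples that are MBR high risk and/or ICR Medium or Low are
#' mICRoScore `low`. If either input is missing the sample is
#' `unassigned` — missing assays are never silently defaulted.
#'
#' @param icr_cluster `"Low"`/`"Medium"`/`"High"` labels (factor or
#'   character), `NA` for missing.
#' @param mbr_group `"low"`/`"high"` MBR risk groups, `NA` for missing.
#' @return Factor with levels `high`, `low`, `unassigned`.
#' @export
assign_micro_score <- function(icr_cluster, mbr_group) {
  icr <- as.character(icr_cluster)
  mbr <- as.character(mbr_group)
  if (length(icr) != length(mbr)) stop_("inputs must have equal length")
  bad_icr <- !is.na(icr) & !(icr %in% c("Low", "Medium", "High"))
  bad_mbr <- !is.na(mbr) & !(mbr %in% c("low", "high"))
  if (any(bad_icr)) stop_("`icr_cluster` values must be Low/Medium/High or NA")
  if (any(bad_mbr)) stop_("`mbr_group` values must be low/high or NA")
  out <- ifelse(
    is.na(icr) | is.na(mbr), "unassigned",
    ifelse(icr == "High" & mbr == "low", "high", "low")
  )
  factor(out, levels = c("high", "low", "unassigned"))
}

#' Assemble per-platform outputs into one cohort table
#'
#' Merges any number of per-sample data frames (each with a `sample`
#' column) into a master table, one row per sample, keeping samples present
#' in any input; fields missing for a sample stay `NA`.
#'
#' @param ... data frames with a `sample` column.
#' @return Merged data frame keyed by `sample`.
#' @export
assemble_cohort_records <- function(...) {
  pieces <- list(...)
  if (!length(pieces)) stop_("supply at least one data frame")
  for (p in pieces) {
    if (!is.data.frame(p) || !"sample" %in% names(p)) {
      stop_("every input must be a data frame with a `sample` column")
    }
    if (anyDuplicated(p$sample)) stop_("duplicate sample ids within an input")
  }
  Reduce(function(a, b) merge(a, b, by = "sample", all = TRUE), pieces)
}

#' Adjusted multivariable biomarker comparison
#'
#' Assesses each candidate biomarker in its own multivariable Cox model
#' with the fixed clinical adjustment set: age (continuous), stage
#' (ordinal I < II < III < IV), MSI status (binary, MSS reference) and CMS
#' subtype (categorical, CMS4 reference). Candidate encodings follow the
#' same contract: ordered factors enter as ordinal scores, two-level
#' factors as binary contrasts. Complete-case rows are used per candidate
#' and the retained counts reported.
#'
#' @param records cohort data frame with columns `time`, `event`, `age`,
#'   `stage`, `msi`, `cms` and the candidate columns.
#' @param candidates character vector of candidate column names (e.g.
#'   `"icr_cluster"`, `"edited"`, `"mbr_group"`).
#' @param ... passed to [fit_coxph()].
#' @return Named list per candidate: `fit` (a [fit_coxph()] result),
#'   `candidate_term` (the candidate's row of the coefficient table),
#'   `n_used`, `n_events`.
#' @export
adjusted_biomarker_comparison <- function(records,
                                          candidates,
                                          ...) {
  req <- c("time", "event", "age", "stage", "msi", "cms")
  miss <- setdiff(c(req, candidates), names(records))
  if (length(miss)) {
    stop_(sprintf("`records` missing columns: %s", paste(miss, collapse = ", ")))
  }
  stage <- factor(as.character(records$stage), levels = c("I", "II", "III", "IV"),
                  ordered = TRUE)
  msi <- factor(as.character(records$msi), levels = c("MSS", "MSI-H"))
  cms <- stats::relevel(factor(as.character(records$cms),
                               levels = c("CMS1", "CMS2", "CMS3", "CMS4")),
                        ref = "CMS4")
  out <- list()
  for (cand in candidates) {
    v <- records[[cand]]
    if (is.character(v)) v <- factor(v)
    if (is.logical(v)) v <- factor(v, levels = c(FALSE, TRUE),
                                   labels = c("no", "yes"))
    dat <- data.frame(
      time = records$time, event = records$event,
      age = records$age, stage = stage, msi = msi, cms = cms,
      candidate = v
    )
    cc <- stats::complete.cases(dat)
    dat <- dat[cc, , drop = FALSE]
    if (sum(dat$event) < 8) {
      stop_(sprintf("insufficient events (%d) for candidate '%s'",
                    sum(dat$event), cand))
    }
    fit <- fit_coxph(
      dat$time, dat$event,
      dat[, c("age", "stage", "msi", "cms", "candidate")],
      override_min_group = TRUE, ...
    )
    cand_rows <- grepl("^candidate", fit$terms$term)
    terms <- fit$terms
    terms$term <- sub("^candidate", cand, terms$term)
    fit$terms <- terms
    out[[cand]] <- list(
      fit = fit,
      candidate_term = terms[cand_rows, , drop = FALSE],
      n_used = nrow(dat),
      n_events = sum(dat$event)
    )
  }
  out
}

#' Survival report by group
#'
#' Per-group Kaplan-Meier curves with survival read at a fixed horizon
#' (default 5 years), an overall log-rank test, and pairwise Cox hazard
#' ratios honoring the minimum-group-size guard (guarded pairs are
#' reported as `NA` with a note). Empty grouping levels are dropped with a
#' notice.
#'
#' @param time,event survival data.
#' @param group group label per record.
#' @param horizon time at which per-group survival is read (default 5).
#' @param min_group_size guard for the pairwise Cox contrasts.
#' @return List with `groups` (data frame: `group`, `n`, `events`,
#'   `surv_at_horizon`), `logrank`, `pairwise` (data frame of contrasts)
#'   and `curves` (named list of [km_estimate()] objects).
#' @export
survival_by_group_report <- function(time, event, group, horizon = 5,
                                     min_group_size = 10) {
  group <- as.factor(group)
  empty <- levels(group)[table(group) == 0]
  if (length(empty)) {
    message(sprintf("dropping empty group level(s): %s",
                    paste(empty, collapse = ", ")))
    group <- droplevels(group)
  }
  levs <- levels(group)
  curves <- lapply(levs, function(g) km_estimate(time[group == g], event[group == g]))
  names(curves) <- levs
  groups <- data.frame(
    group = levs,
    n = as.integer(table(group)[levs]),
    events = vapply(levs, function(g) sum(event[group == g]), numeric(1)),
    surv_at_horizon = vapply(curves, km_surv_at, numeric(1), at = horizon),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  lr <- if (length(levs) >= 2) logrank_test(time, event, group) else NULL
  pairs <- if (length(levs) >= 2) utils::combn(levs, 2, simplify = FALSE) else list()
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    sel <- group %in% pr
    g2 <- factor(as.character(group[sel]), levels = pr)
    fit <- tryCatch(
      fit_coxph(time[sel], event[sel], data.frame(group = g2),
                min_group_size = min_group_size),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      data.frame(reference = pr[1], comparison = pr[2], hr = NA_real_,
                 lower = NA_real_, upper = NA_real_, p = NA_real_,
                 note = "guarded or inestimable", stringsAsFactors = FALSE)
    } else {
      t1 <- fit$terms[1, ]
      data.frame(reference = pr[1], comparison = pr[2], hr = t1$hr,
                 lower = t1$lower, upper = t1$upper, p = t1$p,
                 note = "", stringsAsFactors = FALSE)
    }
  }))
  list(groups = groups, logrank = lr, pairwise = pw, curves = curves,
       horizon = horizon)
}
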