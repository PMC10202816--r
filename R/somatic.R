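#' Nonsynonymous variant classes
#'
#' The MAF variant classifications counted as nonsynonymous for tumor
#' mutational burden and downstream neoantigen analyses.
#'
#' @return Character vector of class names.
#' @export
nonsynonymous_classes <- function() {
  c(
    "Frame_Shift_Del", "Frame_Shift_Ins",
    "In_Frame_Del", "In_Frame_Ins",
    "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Splice_Site", "Translation_Start_Site"
  )
}

# MAF classes we recognise but do not count as nonsynonymous
.known_silent_classes <- c(
  "Silent", "Synonymous", "3'UTR", "5'UTR", "3'Flank", "5'Flank",
  "Intron", "IGR", "RNA", "Splice_Region", "Nonsense", "lincRNA",
  "Targeted_Region", "De_novo_Start_InFrame", "De_novo_Start_OutOfFrame"
)

#' Filter somatic variants
#'
#' Applies the technical and biological retention rules used before TMB and
#' neoantigen analyses: variant class in the whitelist, variant allele
#' fraction at least `min_vaf` (default 5%), tumor depth strictly greater
#' than `min_depth_exclusive` reads (default > 3, i.e. depth >= 4), and
#' population allele frequency at most `max_pop_af` (default 1%, ExAC-style
#' common-variant exclusion). With `drop_tolerated_benign = TRUE`, variants
#' predicted tolerated by SIFT or benign by PolyPhen are additionally
#' removed (the filter used for gene-frequency analyses).
#'
#' Records whose `variant_class` is outside the known vocabulary are dropped
#' with a warning and counted in the `n_unknown_class` attribute.
#'
#' @param variants data frame with columns `gene`, `variant_class`, `vaf`,
#'   `tumor_depth`, `pop_af`, and optionally logical `sift_tolerated` and
#'   `polyphen_benign`. Missing `pop_af` values are treated as 0 (not seen
#'   in the population).
#' @param min_vaf minimum allele fraction, inclusive.
#' @param min_depth_exclusive depth must strictly exceed this.
#' @param max_pop_af maximum population allele frequency, inclusive.
#' @param class_whitelist retained variant classes.
#' @param drop_tolerated_benign apply the SIFT/PolyPhen effect filter.
#' @return The retained rows, with attributes `n_unknown_class` and
#'   `n_dropped`.
#' @export
filter_somatic_variants <- function(variants,
                                    min_vaf = 0.05,
                                    min_depth_exclusive = 3,
                                    max_pop_af = 0.01,
                                    class_whitelist = nonsynonymous_classes(),
                                    drop_tolerated_benign = FALSE) {
  req <- c("gene", "variant_class", "vaf", "tumor_depth", "pop_af")
  miss <- setdiff(req, names(variants))
  if (length(miss)) {
    stop_(sprintf("`variants` missing columns: %s", paste(miss, collapse = ", ")))
  }
  known <- c(class_whitelist, .known_silent_classes)
  unknown <- !(variants$variant_class %in% known)
  if (any(unknown)) {
    warn_(sprintf(
      "dropping %d variants with unknown class: %s",
      sum(unknown),
      paste(unique(variants$variant_class[unknown]), collapse = ", ")
    ))
  }
  pop_af <- variants$pop_af
  pop_af[is.na(pop_af)] <- 0
  keep <- !unknown &
    variants$variant_class %in% class_whitelist &
    variants$vaf >= min_vaf &
    variants$tumor_depth > min_depth_exclusive &
    pop_af <= max_pop_af
  if (drop_tolerated_benign) {
    tol <- if ("sift_tolerated" %in% names(variants)) {
      isTRUE_vec(variants$sift_tolerated)
    } else rep(FALSE, nrow(variants))
    ben <- if ("polyphen_benign" %in% names(variants)) {
      isTRUE_vec(variants$polyphen_benign)
    } else rep(FALSE, nrow(variants))
    keep <- keep & !(tol | ben)
  }
  out <- variants[keep, , drop = FALSE]
  attr(out, "n_unknown_class") <- sum(unknown)
  attr(out, "n_dropped") <- nrow(variants) - nrow(out)
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Tumor mutational burden and hypermutation class
#'
#' TMB is the nonsynonymous variant count divided by the exome capture size
#' in megabases (default 40 Mb). A sample is hypermutated when TMB strictly
#' exceeds `hyper_threshold` mutations per Mb (default > 12).
#'
#' @param x nonsynonymous variant count(s), non-negative.
#' @param capture_mb capture size in Mb, positive.
#' @param hyper_threshold hypermutation cutoff in mutations/Mb (strict).
#' @return Data frame with `x`, `tmb_per_mb`, `hypermutated`.
#' @export
tmb_and_class <- function(x, capture_mb = 40, hyper_threshold = 12) {
  if (capture_mb <= 0) stop_("`capture_mb` must be positive")
  if (any(x < 0)) stop_("`x` must be non-negative")
  tmb <- x / capture_mb
  data.frame(x = x, tmb_per_mb = tmb, hypermutated = tmb > hyper_threshold)
}

#' Classify microsatellite instability from an instability score
#'
#' MSI-H when the MANTIS-style instability score strictly exceeds the
#' threshold (default 0.4); MSS when at or below it; `"unknown"` when the
#' score is missing.
#'
#' @param mantis_score numeric vector; `NA` allowed.
#' @param threshold classification cutoff (score > threshold is MSI-H).
#' @return Character vector in `{"MSI-H", "MSS", "unknown"}`.
#' @export
classify_msi <- function(mantis_score, threshold = 0.4) {
  out <- ifelse(
    is.na(mantis_score), "unknown",
    ifelse(mantis_score > threshold, "MSI-H", "MSS")
  )
  as.character(out)
}

#' Call neoantigens from paired binding affinities
#'
#' A candidate epitope is a neoantigen when the mutant median IC50 binding
#' affinity is strictly below `mut_max` nM and the corresponding wild-type
#' median IC50 is strictly above `wt_min` nM (default 500 nM on both sides:
#' the mutant binds, the wild type does not).
#'
#' @param candidates data frame with positive columns `mutant_ic50` and
#'   `wt_ic50` (nM medians across prediction algorithms).
#' @param mut_max mutant affinity must be strictly below this.
#' @param wt_min wild-type affinity must be strictly above this.
#' @return List with `count` (number of neoantigens) and logical
#'   `is_neoantigen` per candidate.
#' @export
call_neoantigens <- function(candidates, mut_max = 500, wt_min = 500) {
  req <- c("mutant_ic50", "wt_ic50")
  if (!all(req %in% names(candidates))) {
    stop_("`candidates` needs columns mutant_ic50 and wt_ic50")
  }
  if (any(candidates$mutant_ic50 <= 0) || any(candidates$wt_ic50 <= 0)) {
    stop_("IC50 affinities must be positive")
  }
  flag <- candidates$mutant_ic50 < mut_max & candidates$wt_ic50 > wt_min
  list(count = sum(flag), is_neoantigen = flag)
}

#' Expected-neoantigen linear model
#'
#' The expected number of neoantigens `E(x) = a + b * x` as a linear
#' function of the nonsynonymous mutation count `x`. Defaults are the
#' published coefficients `a = -2.38770`, `b = 0.09171`; [refit_expected_model()]
#' refits them on reference (non-edited) samples.
#'
#' @param intercept,slope model coefficients; `slope` must be positive.
#' @return Object of class `"expected_neoantigen_model"`.
#' @export
expected_neoantigen_model <- function(intercept = -2.38770, slope = 0.09171) {
  if (slope <= 0) stop_("`slope` must be positive for a usable model")
  structure(list(intercept = intercept, slope = slope),
            class = "expected_neoantigen_model")
}

#' @export
print.expected_neoantigen_model <- function(x, ...) {
  cat(sprintf("<expected_neoantigen_model> E(x) = %.5f + %.5f * x\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Refit the expected-neoantigen line
#'
#' Ordinary least squares of observed neoantigen counts on nonsynonymous
#' mutation counts, intended for reference samples without immunoediting.
#'
#' @param x nonsynonymous mutation counts (length >= 3, not all equal).
#' @param observed observed neoantigen counts, same length.
#' @return An [expected_neoantigen_model()].
#' @export
refit_expected_model <- function(x, observed) {
  if (length(x) != length(observed)) stop_("`x` and `observed` lengths differ")
  if (length(x) < 3) stop_("need at least 3 (x, observed) pairs")
  if (var(x) == 0) stop_("degenerate design: all x equal")
  fit <- lm(observed ~ x)
  b <- unname(coef(fit))
  expected_neoantigen_model(intercept = b[1], slope = b[2])
}

#' Genetic immunoediting (GIE) statistic
#'
#' The GIE value is the ratio of observed to expected neoantigens,
#' `GIE = O / E(x)`. Samples whose expected count is non-positive (below
#' the zero crossing of the linear model) are non-evaluable rather than
#' clamped. A sample displays immunoediting (`edited`) when its GIE value
#' is strictly below `edited_cutoff` (default 1: fewer neoantigens than
#' expected).
#'
#' @param observed observed neoantigen count(s), non-negative.
#' @param x nonsynonymous mutation count(s), non-negative, same length.
#' @param model an [expected_neoantigen_model()].
#' @param edited_cutoff binarization cutoff on the GIE value.
#' @return Data frame with `observed`, `x`, `expected`, `gie_value`,
#'   `evaluable`, `edited` (NA when non-evaluable).
#' @export
gie_evaluate <- function(observed, x, model = expected_neoantigen_model(),
                         edited_cutoff = 1) {
  if (!inherits(model, "expected_neoantigen_model")) {
    stop_("`model` must be an expected_neoantigen_model")
  }
  if (length(observed) != length(x)) stop_("`observed` and `x` lengths differ")
  if (any(observed < 0) || any(x < 0)) {
    stop_("`observed` and `x` must be non-negative")
  }
  e <- model$intercept + model$slope * x
  evaluable <- e > 0
  gie <- ifelse(evaluable, observed / e, NA_real_)
  data.frame(
    observed = observed, x = x, expected = e,
    gie_value = gie, evaluable = evaluable,
    edited = ifelse(evaluable, gie < edited_cutoff, NA)
  )
}

#' Four-level immunoediting score (IES)
#'
#' Composite of ICR cluster and GIE presence: IES1 = ICR Low without GIE,
#' IES2 = ICR Low with GIE, IES3 = ICR High without GIE, IES4 = ICR High
#' with GIE. ICR-Medium samples and samples with a non-evaluable GIE value
#' are `"unassigned"` (analyzed separately).
#'
#' @param icr_cluster vector of `"Low"`/`"Medium"`/`"High"` labels (factor
#'   or character); `NA` allowed.
#' @param gie a [gie_evaluate()] result (or a data frame with `evaluable`
#'   and `edited` columns), one row per sample.
#' @return Factor with levels `IES1..IES4, unassigned`.
#' @export
assign_ies <- function(icr_cluster, gie) {
  icr <- as.character(icr_cluster)
  if (is.data.frame(gie)) {
    if (!all(c("evaluable", "edited") %in% names(gie))) {
      stop_("`gie` must have `evaluable` and `edited` columns")
    }
    if (nrow(gie) != length(icr)) stop_("`icr_cluster` and `gie` lengths differ")
    evaluable <- gie$evaluable
    edited <- gie$edited
  } else {
    stop_("`gie` must be a gie_evaluate() result")
  }
  out <- rep("unassigned", length(icr))
  ok <- !is.na(icr) & icr %in% c("Low", "High") & evaluable & !is.na(edited)
  out[ok & icr == "Low" & !edited] <- "IES1"
  out[ok & icr == "Low" & edited] <- "IES2"
  out[ok & icr == "High" & !edited] <- "IES3"
  out[ok & icr == "High" & edited] <- "IES4"
  factor(out, levels = c("IES1", "IES2", "IES3", "IES4", "unassigned"))
}
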