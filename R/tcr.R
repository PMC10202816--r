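#' Construct a TCR repertoire
#'
#' A repertoire is the per-sample clone table produced by targeted TCR-beta
#' sequencing (immunoSEQ-style) or assembled from bulk RNA-seq. Clone
#' identity is the opaque rearrangement sequence string; template counts are
#' the number of observed molecules per clone.
#'
#' @param sample_id single string identifying the sample.
#' @param clone_id character vector of unique clone identifiers
#'   (rearrangement sequences).
#' @param templates non-negative integer template counts, one per clone.
#' @param productive logical vector; `TRUE` for in-frame, stop-codon-free
#'   rearrangements. Defaults to all productive.
#' @param assay `"dna-targeted"` (immunoSEQ-style) or `"rna-derived"`
#'   (MiXCR-style). Metric formulas are identical for both.
#' @return An object of class `"repertoire"`: a list with `sample_id`,
#'   `assay` and a `clones` data frame (`clone_id`, `templates`,
#'   `productive`, and derived `frequency` over productive templates).
#' @export
repertoire <- function(sample_id, clone_id, templates,
                       productive = rep(TRUE, length(clone_id)),
                       assay = c("dna-targeted", "rna-derived")) {
  assay <- match.arg(assay)
  if (length(sample_id) != 1L || !is.character(sample_id)) {
    stop_("`sample_id` must be a single string")
  }
  clone_id <- as.character(clone_id)
  if (anyDuplicated(clone_id)) stop_("clone ids must be unique")
  if (length(templates) != length(clone_id) ||
      length(productive) != length(clone_id)) {
    stop_("`clone_id`, `templates` and `productive` must have equal length")
  }
  if (any(templates < 0) || any(templates != round(templates))) {
    stop_("template counts must be non-negative integers")
  }
  total_prod <- sum(templates[productive])
  freq <- rep(NA_real_, length(templates))
  if (total_prod > 0) freq[productive] <- templates[productive] / total_prod
  structure(
    list(
      sample_id = sample_id,
      assay = assay,
      clones = data.frame(
        clone_id = clone_id,
        templates = as.integer(round(templates)),
        productive = as.logical(productive),
        frequency = freq,
        stringsAsFactors = FALSE
      )
    ),
    class = "repertoire"
  )
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf(
    "<repertoire> sample %s (%s): %d clones, %d productive templates\n",
    x$sample_id, x$assay, nrow(x$clones),
    sum(x$clones$templates[x$clones$productive])
  ))
  invisible(x)
}

#' Clonality of a clone-size distribution
#'
#' Clonality is one minus the Pielou-normalized Shannon entropy of the clone
#' frequency distribution: `H = -sum(p * log2(p))`, `J = H / log2(S)` with
#' `S` the number of clones, and `clonality = 1 - J`. Values near 0 indicate
#' polyclonal repertoires; values near 1 indicate dominance by few clones.
#' The log base cancels in `J`, so the same value is obtained for natural-log
#' entropy; bits are used throughout for reporting.
#'
#' @param counts vector of non-negative clone counts; at least two positive.
#' @return Clonality in `[0, 1)`.
#' @examples
#' clonality_from_counts(c(8, 4, 2, 2)) # 0.125
#' clonality_from_counts(c(1, 1, 1, 1)) # 0
#' @export
clonality_from_counts <- function(counts) {
  if (!is.numeric(counts)) stop_("`counts` must be numeric")
  if (any(counts < 0)) stop_("clone counts must be non-negative")
  counts <- counts[counts > 0]
  s <- length(counts)
  if (s < 2) {
    stop_("normalized entropy undefined: need at least 2 clones with positive counts")
  }
  p <- counts / sum(counts)
  h <- -sum(p * log2(p))
  1 - h / log2(s)
}

#' Summarize a TCR repertoire
#'
#' Computes template totals, richness, Shannon entropy (bits), Pielou's
#' evenness and clonality over the productive clones of a repertoire.
#' Non-productive clones contribute to `total_templates` only.
#'
#' @param rep a [repertoire()].
#' @return An object of class `"repertoire_summary"`: list with
#'   `total_templates`, `productive_templates`,
#'   `unique_productive_rearrangements`, `entropy_bits`,
#'   `normalized_entropy` (Pielou J), `clonality` and
#'   `max_productive_frequency`.
#' @export
summarize_repertoire <- function(rep) {
  if (!inherits(rep, "repertoire")) stop_("`rep` must be a repertoire object")
  cl <- rep$clones
  prod <- cl[cl$productive & cl$templates > 0, , drop = FALSE]
  if (sum(prod$templates) == 0) {
    stop_("repertoire has zero productive templates")
  }
  s <- nrow(prod)
  if (s < 2) {
    stop_("normalized entropy undefined: fewer than 2 unique productive rearrangements")
  }
  p <- prod$templates / sum(prod$templates)
  h <- -sum(p * log2(p))
  j <- h / log2(s)
  structure(
    list(
      sample_id = rep$sample_id,
      total_templates = sum(cl$templates),
      productive_templates = sum(prod$templates),
      unique_productive_rearrangements = s,
      entropy_bits = h,
      normalized_entropy = j,
      clonality = 1 - j,
      max_productive_frequency = max(p)
    ),
    class = "repertoire_summary"
  )
}

#' @export
print.repertoire_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<repertoire_summary> %s\n",
      "  templates: %d total, %d productive over %d rearrangements\n",
      "  entropy %.4f bits, evenness %.4f, clonality %.4f\n"
    ),
    x$sample_id, x$total_templates, x$productive_templates,
    x$unique_productive_rearrangements,
    x$entropy_bits, x$normalized_entropy, x$clonality
  ))
  invisible(x)
}

#' Detect tumor-enriched TCR clones against a matched normal repertoire
#'
#' A clone is tumor-enriched when its productive frequency in the tumor
#' strictly exceeds `frequency_floor` (default 0.1%) AND its tumor/normal
#' frequency ratio is at least `fold_threshold` (default 32-fold). Clones
#' present in tumor but undetected in normal satisfy the fold criterion
#' under the default `"enriched"` policy (they are maximally enriched); the
#' `"pseudocount"` policy instead adds `pseudocount` to the normal frequency
#' before forming the ratio.
#'
#' @param tumor,normal [repertoire()] objects for the matched pair.
#' @param fold_threshold minimum tumor/normal frequency ratio (inclusive).
#' @param frequency_floor tumor productive frequency that must be strictly
#'   exceeded (proportion, default `0.001` = 0.1%).
#' @param absent_normal policy for clones absent from normal: `"enriched"`
#'   (default) or `"pseudocount"`.
#' @param pseudocount normal-frequency pseudo-count for the
#'   `"pseudocount"` policy; defaults to one template in the normal sample.
#' @return Object of class `"overlap_analysis"`: list with `tumor_sample`,
#'   `normal_sample`, `clones` (per productive tumor clone: frequencies,
#'   fold ratio, enrichment call), `shared_ids`, `tumor_enriched` ids and
#'   `fraction_enriched` (template-weighted, see
#'   [fraction_tumor_enriched()]).
#' @export
detect_tumor_enriched <- function(tumor, normal,
                                  fold_threshold = 32,
                                  frequency_floor = 0.001,
                                  absent_normal = c("enriched", "pseudocount"),
                                  pseudocount = NULL) {
  absent_normal <- match.arg(absent_normal)
  if (!inherits(tumor, "repertoire") || !inherits(normal, "repertoire")) {
    stop_("`tumor` and `normal` must be repertoire objects")
  }
  tprod <- tumor$clones[tumor$clones$productive & tumor$clones$templates > 0, ]
  if (nrow(tprod) == 0) stop_("empty tumor repertoire: no productive clones")
  nprod <- normal$clones[normal$clones$productive & normal$clones$templates > 0, ]
  tfreq <- tprod$templates / sum(tprod$templates)
  ntotal <- sum(nprod$templates)
  nfreq <- setNames(
    if (nrow(nprod)) nprod$templates / ntotal else numeric(0),
    nprod$clone_id
  )
  normal_freq <- unname(nfreq[tprod$clone_id])
  normal_freq[is.na(normal_freq)] <- 0
  if (is.null(pseudocount)) {
    pseudocount <- if (ntotal > 0) 1 / ntotal else 1e-6
  }
  fold <- ifelse(
    normal_freq > 0,
    tfreq / normal_freq,
    if (absent_normal == "enriched") Inf else tfreq / pseudocount
  )
  if (absent_normal == "pseudocount") {
    fold <- tfreq / (normal_freq + pseudocount)
  }
  enriched <- tfreq > frequency_floor & fold >= fold_threshold
  clones <- data.frame(
    clone_id = tprod$clone_id,
    tumor_templates = tprod$templates,
    tumor_frequency = tfreq,
    normal_frequency = normal_freq,
    fold_ratio = fold,
    enriched = enriched,
    stringsAsFactors = FALSE
  )
  out <- structure(
    list(
      tumor_sample = tumor$sample_id,
      normal_sample = normal$sample_id,
      clones = clones,
      shared_ids = intersect(tprod$clone_id, nprod$clone_id),
      tumor_enriched = clones$clone_id[clones$enriched],
      fold_threshold = fold_threshold,
      frequency_floor = frequency_floor,
      fraction_enriched = NA_real_
    ),
    class = "overlap_analysis"
  )
  out$fraction_enriched <- fraction_tumor_enriched(out, tumor)
  out
}

#' @export
print.overlap_analysis <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<overlap_analysis> tumor %s vs normal %s\n",
      "  %d shared clones; %d tumor-enriched (>=%g-fold, >%g%% tumor frequency)\n",
      "  template-weighted enriched fraction: %.4f\n"
    ),
    x$tumor_sample, x$normal_sample, length(x$shared_ids),
    length(x$tumor_enriched), x$fold_threshold, 100 * x$frequency_floor,
    x$fraction_enriched
  ))
  invisible(x)
}

#' Template-weighted fraction of tumor-enriched clones
#'
#' Divides the number of productive templates carried by tumor-enriched
#' clones by the total number of productive templates in the tumor sample.
#'
#' @param analysis an [detect_tumor_enriched()] result.
#' @param tumor the tumor [repertoire()] the analysis was derived from.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_tumor_enriched <- function(analysis, tumor) {
  if (!inherits(analysis, "overlap_analysis")) {
    stop_("`analysis` must be an overlap_analysis")
  }
  if (!identical(analysis$tumor_sample, tumor$sample_id)) {
    stop_(sprintf(
      "sample mismatch: analysis is for %s but repertoire is %s",
      analysis$tumor_sample, tumor$sample_id
    ))
  }
  prod <- tumor$clones[tumor$clones$productive & tumor$clones$templates > 0, ]
  total <- sum(prod$templates)
  enriched <- sum(prod$templates[prod$clone_id %in% analysis$tumor_enriched])
  enriched / total
}
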