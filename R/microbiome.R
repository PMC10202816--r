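#' Convert a count table to relative abundances
#'
#' Row-normalizes a samples x taxa table so each sample sums to one. Input
#' that already looks relative (every row sum within 1e-6 of 1) is returned
#' unchanged with a message.
#'
#' @param table numeric matrix or data frame, samples in rows, taxa in
#'   columns, non-negative values.
#' @return Relative abundance matrix with the same dimnames.
#' @export
to_relative_abundance <- function(table) {
  x <- as.matrix(table)
  if (any(x < 0)) stop_("abundances must be non-negative")
  rs <- rowSums(x)
  zero <- rs == 0
  if (any(zero)) {
    nm <- rownames(x)[zero] %||% which(zero)
    stop_(sprintf("all-zero sample(s): %s", paste(nm, collapse = ", ")))
  }
  if (all(abs(rs - 1) < 1e-6)) {
    message("table already appears to be relative abundances; returned unchanged")
    return(x)
  }
  x / rs
}

#' Genus prevalence/abundance filter
#'
#' Retains taxa present (abundance strictly > 0) in at least
#' `min_prevalence` of the samples AND reaching at least
#' `min_max_abundance` relative abundance in at least one sample
#' (defaults: 10% of samples, 1% abundance). The filter is idempotent.
#'
#' @param table relative abundance matrix, samples x taxa.
#' @param min_prevalence minimum fraction of samples with nonzero
#'   abundance, inclusive.
#' @param min_max_abundance minimum of the per-taxon maximum relative
#'   abundance, inclusive.
#' @return The table restricted to retained taxa, with attribute
#'   `retained_taxa`.
#' @export
prevalence_abundance_filter <- function(table, min_prevalence = 0.10,
                                        min_max_abundance = 0.01) {
  x <- as.matrix(table)
  prevalence <- colMeans(x > 0)
  max_ab <- apply(x, 2, max)
  keep <- prevalence >= min_prevalence & max_ab >= min_max_abundance
  out <- x[, keep, drop = FALSE]
  attr(out, "retained_taxa") <- colnames(x)[keep]
  out
}

#' Alpha diversity summaries
#'
#' Observed richness, Chao1, Shannon (natural log) and inverse Simpson per
#' sample. Chao1 requires integer counts; the default bias-corrected form is
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1`/`F2` the singleton and
#' doubleton counts (classic form `S_obs + F1^2 / (2 F2)` by flag). Shannon
#' and inverse Simpson are computed on proportions and accept non-integer
#' input. Note the natural-log convention here, distinct from the base-2
#' entropy used for TCR clonality.
#'
#' @param counts numeric vector (one sample) or matrix with samples in
#'   rows.
#' @param chao1 `"bias-corrected"` (default) or `"classic"`.
#' @return Data frame with `observed`, `chao1`, `shannon`, `inv_simpson`
#'   per sample.
#' @export
alpha_diversity <- function(counts, chao1 = c("bias-corrected", "classic")) {
  chao1 <- match.arg(chao1)
  x <- if (is.matrix(counts) || is.data.frame(counts)) {
    as.matrix(counts)
  } else {
    matrix(counts, nrow = 1, dimnames = list("sample", names(counts)))
  }
  if (any(x < 0)) stop_("counts must be non-negative")
  if (any(rowSums(x) <= 0)) stop_("each sample needs at least one positive count")
  if (any(x != round(x))) {
    stop_("Chao1 requires integer counts; round or rarefy upstream")
  }
  observed <- rowSums(x > 0)
  f1 <- rowSums(x == 1)
  f2 <- rowSums(x == 2)
  chao <- if (chao1 == "bias-corrected") {
    observed + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    # classic form is undefined at F2 = 0; fall back to the corrected term
    observed + ifelse(f2 > 0, f1^2 / (2 * f2), f1 * (f1 - 1) / 2)
  }
  shannon <- vegan::diversity(x, index = "shannon")
  inv_simpson <- vegan::diversity(x, index = "invsimpson")
  data.frame(
    observed = as.integer(observed),
    chao1 = as.numeric(chao),
    shannon = as.numeric(shannon),
    inv_simpson = as.numeric(inv_simpson),
    row.names = rownames(x)
  )
}

#' Harmonize taxon labels
#'
#' Applies a many-to-one renaming of taxon columns (e.g. collapsing the
#' amplicon classifier's "Ruminococcus 1"/"Ruminococcus 2" into
#' "Ruminococcus" so that 16S-derived signatures transfer to shotgun
#' profiles), summing abundances of merged taxa. Total abundance per sample
#' is conserved.
#'
#' @param table abundance matrix, samples x taxa.
#' @param mapping named character vector `old name -> new name`. Names not
#'   present in the table are ignored.
#' @return Matrix with canonical taxon columns.
#' @export
harmonize_taxa <- function(table, mapping = ruminococcus_mapping()) {
  x <- as.matrix(table)
  if (is.null(names(mapping)) || any(!nzchar(names(mapping)))) {
    stop_("`mapping` must be a named character vector old -> new")
  }
  remapped_sources <- names(mapping)[mapping != names(mapping)]
  conflict <- intersect(unname(mapping), remapped_sources)
  if (length(conflict)) {
    stop_(sprintf(
      "conflicting mapping: %s appear(s) both as target and as renamed source",
      paste(conflict, collapse = ", ")
    ))
  }
  new_names <- colnames(x)
  hit <- new_names %in% names(mapping)
  new_names[hit] <- unname(mapping[new_names[hit]])
  groups <- split(seq_along(new_names), new_names)
  out <- vapply(
    groups,
    function(idx) rowSums(x[, idx, drop = FALSE]),
    numeric(nrow(x))
  )
  if (nrow(x) == 1) out <- matrix(out, nrow = 1, dimnames = list(rownames(x), names(groups)))
  # keep first-appearance column order
  first <- vapply(groups, min, numeric(1))
  out[, order(first), drop = FALSE]
}

#' @rdname harmonize_taxa
#' @export
ruminococcus_mapping <- function() {
  c("Ruminococcus 1" = "Ruminococcus", "Ruminococcus 2" = "Ruminococcus")
}

#' Paired differential abundance between tumor and normal tissue
#'
#' Per taxon, a two-sided paired rank test (Wilcoxon signed-rank, the
#' paired form of the Mann-Whitney U-test) between tumor and matched normal
#' relative abundances, with Benjamini-Hochberg FDR across tested taxa.
#' Taxa are the union of the two tables' columns (absent columns count as
#' zero abundance). Fold change is the ratio of tumor to normal mean
#' abundance with a pseudo-count guarding zero means.
#'
#' @param tumor,normal relative abundance matrices with identical row
#'   (patient) ordering, or rownames that can be matched.
#' @param pseudocount relative-abundance pseudo-count for fold changes
#'   (default 1e-6).
#' @return Data frame per taxon: `taxon`, `mean_tumor`, `mean_normal`,
#'   `fold_change`, `direction`, `p`, `fdr`.
#' @export
paired_differential_abundance <- function(tumor, normal, pseudocount = 1e-6) {
  t_ <- as.matrix(tumor)
  n_ <- as.matrix(normal)
  if (!is.null(rownames(t_)) && !is.null(rownames(n_))) {
    if (!setequal(rownames(t_), rownames(n_))) {
      stop_("tumor and normal tables must cover the same patients")
    }
    n_ <- n_[rownames(t_), , drop = FALSE]
  } else if (nrow(t_) != nrow(n_)) {
    stop_("tumor and normal tables must have the same number of rows")
  }
  if (nrow(t_) < 2) stop_("need at least 2 pairs")
  taxa <- union(colnames(t_), colnames(n_))
  pad <- function(x) {
    miss <- setdiff(taxa, colnames(x))
    if (length(miss)) {
      x <- cbind(x, matrix(0, nrow(x), length(miss),
                           dimnames = list(rownames(x), miss)))
    }
    x[, taxa, drop = FALSE]
  }
  t_ <- pad(t_)
  n_ <- pad(n_)
  p <- vapply(taxa, function(tx) {
    d <- t_[, tx] - n_[, tx]
    if (all(d == 0)) return(1)
    wilcox.test(t_[, tx], n_[, tx], paired = TRUE, exact = FALSE)$p.value
  }, numeric(1))
  mt <- colMeans(t_)
  mn <- colMeans(n_)
  fc <- (mt + pseudocount) / (mn + pseudocount)
  data.frame(
    taxon = taxa,
    mean_tumor = unname(mt),
    mean_normal = unname(mn),
    fold_change = unname(fc),
    direction = ifelse(fc > 1, "up_in_tumor",
                       ifelse(fc < 1, "down_in_tumor", "unchanged")),
    p = unname(p),
    fdr = p.adjust(p, method = "BH"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
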