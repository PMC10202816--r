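#' Gene signature constructor and the packaged ICR signature
#'
#' `gene_signature()` bundles a name with an ordered, duplicate-free gene
#' list. `icr_signature()` returns the 20-gene Immunologic Constant of
#' Rejection (ICR) signature: Th1 polarization, effector/cytotoxic and
#' immune-regulatory transcripts whose mean log2 expression defines the ICR
#' score.
#'
#' @param name single string naming the signature.
#' @param genes character vector of gene identifiers.
#' @return An object of class `"gene_signature"`.
#' @export
gene_signature <- function(name, genes) {
  if (length(name) != 1L || !is.character(name) || !nzchar(name)) {
    stop_("`name` must be a non-empty string")
  }
  genes <- as.character(genes)
  if (length(genes) == 0) stop_("signature must contain at least one gene")
  if (anyDuplicated(genes)) stop_("signature genes must be unique")
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' @rdname gene_signature
#' @export
icr_signature <- function() {
  gene_signature("ICR", c(
    "IFNG", "IRF1", "STAT1", "IL12B", "TBX21",
    "CD8A", "CD8B", "CXCL9", "CXCL10", "CCL5",
    "GZMB", "GNLY", "PRF1", "GZMH", "GZMA",
    "CD274", "PDCD1", "CTLA4", "FOXP3", "IDO1"
  ))
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' ICR score: mean signature-gene expression per sample
#'
#' The ICR score of a sample is the arithmetic mean of the log2-normalized
#' expression values of the signature genes. All signature genes must be
#' present in the matrix; missing genes raise an error naming them rather
#' than silently subsetting.
#'
#' @param expr numeric matrix of log2-normalized expression, genes in rows
#'   (rownames = gene ids), samples in columns (colnames = sample ids).
#' @param sig a [gene_signature()]; defaults to the packaged
#'   [icr_signature()].
#' @return Named numeric vector of per-sample scores.
#' @export
icr_score <- function(expr, sig = icr_signature()) {
  assert_matrix_named(expr, "expr")
  if (!inherits(sig, "gene_signature")) stop_("`sig` must be a gene_signature")
  missing <- setdiff(sig$genes, rownames(expr))
  if (length(missing)) {
    stop_(sprintf(
      "signature '%s' genes missing from expression matrix: %s",
      sig$name, paste(missing, collapse = ", ")
    ))
  }
  colMeans(expr[sig$genes, , drop = FALSE])
}

#' Calinski-Harabasz criterion
#'
#' Variance-ratio criterion for a clustering: between-cluster dispersion
#' over within-cluster dispersion, scaled by `(n - k) / (k - 1)`. Larger is
#' better; used to select the number of consensus clusters.
#'
#' @param x numeric matrix, observations in rows.
#' @param labels cluster assignment per row (coercible to factor).
#' @return Single non-negative number; `NaN` when within-cluster dispersion
#'   is 0.
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nrow(x) != length(labels)) stop_("`labels` must match rows of `x`")
  k <- nlevels(labels)
  n <- nrow(x)
  if (k < 2) stop_("need at least 2 clusters")
  grand <- colMeans(x)
  ssb <- 0
  ssw <- 0
  for (lev in levels(labels)) {
    xi <- x[labels == lev, , drop = FALSE]
    ci <- colMeans(xi)
    ssb <- ssb + nrow(xi) * sum((ci - grand)^2)
    ssw <- ssw + sum(sweep(xi, 2, ci)^2)
  }
  (ssb / ssw) * (n - k) / (k - 1)
}

#' Resampling consensus clustering with Calinski-Harabasz model selection
#'
#' Repeatedly subsamples the cohort, clusters each subsample with
#' Ward-linkage agglomerative clustering (Euclidean distance on per-gene
#' z-scored signature expression), and accumulates, for every sample pair
#' and every candidate `k`, the fraction of co-sampled repeats in which the
#' pair co-clustered. Final labels come from complete-linkage hierarchical
#' clustering of the consensus dissimilarity `1 - consensus`, cut at `k`;
#' the reported `chosen_k` maximizes the Calinski-Harabasz criterion of the
#' final labels on the z-scored signature data.
#'
#' @param expr expression matrix (genes x samples) restricted, or
#'   restrictable via `sig`, to the signature genes.
#' @param sig optional [gene_signature()]; when supplied, `expr` is first
#'   restricted to its genes (all must be present).
#' @param k_range candidate cluster numbers (default `2:6`).
#' @param n_reps number of subsampling repeats (default 250; use more for
#'   production runs, e.g. 5000).
#' @param subsample_fraction fraction of samples drawn without replacement
#'   per repeat (default 0.8).
#' @param seed integer seed making the resampling deterministic.
#' @param scale_rows z-score each gene across samples before clustering
#'   (default `TRUE`).
#' @return Object of class `"consensus_clustering"`: list with `consensus`
#'   (per-k sample x sample matrices), `labels` (per-k integer labels),
#'   `criterion` (per-k Calinski-Harabasz values), `chosen_k`, and
#'   `final_labels` for the chosen k.
#' @export
consensus_cluster <- function(expr, sig = NULL, k_range = 2:6, n_reps = 250,
                              subsample_fraction = 0.8, seed = 1,
                              scale_rows = TRUE) {
  if (!is.null(sig)) {
    missing <- setdiff(sig$genes, rownames(expr))
    if (length(missing)) {
      stop_(sprintf("signature genes missing: %s", paste(missing, collapse = ", ")))
    }
    expr <- expr[sig$genes, , drop = FALSE]
  }
  assert_matrix_named(expr, "expr")
  n <- ncol(expr)
  k_range <- sort(unique(as.integer(k_range)))
  if (n < 2 * max(k_range)) {
    stop_("need at least 2 * max(k_range) samples")
  }
  assert_scalar_number(subsample_fraction, "subsample_fraction", 0, 1)
  m <- if (scale_rows) {
    sds <- apply(expr, 1, sd)
    keep <- sds > 0
    t((expr[keep, , drop = FALSE] - rowMeans(expr[keep, , drop = FALSE])) / sds[keep])
  } else {
    t(expr)
  }
  size <- max(2L, floor(subsample_fraction * n))
  cosample <- matrix(0, n, n)
  cocluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(cocluster) <- as.character(k_range)
  with_seed(seed, {
    for (rep_i in seq_len(n_reps)) {
      idx <- sort(sample.int(n, size))
      cosample[idx, idx] <- cosample[idx, idx] + 1
      hc <- hclust(dist(m[idx, , drop = FALSE]), method = "ward.D2")
      for (k in k_range) {
        lab <- cutree(hc, k)
        same <- outer(lab, lab, "==")
        key <- as.character(k)
        cocluster[[key]][idx, idx] <- cocluster[[key]][idx, idx] + same
      }
    }
  })
  off <- upper.tri(cosample)
  if (any(cosample[off] == 0)) {
    stop_(paste(
      "some sample pairs were never co-sampled;",
      "increase n_reps or subsample_fraction"
    ))
  }
  samples <- colnames(expr)
  consensus <- list()
  labels <- list()
  criterion <- setNames(numeric(length(k_range)), as.character(k_range))
  for (k in k_range) {
    key <- as.character(k)
    cm <- cocluster[[key]] / cosample
    diag(cm) <- 1
    dimnames(cm) <- list(samples, samples)
    consensus[[key]] <- cm
    hc_final <- hclust(stats::as.dist(1 - cm), method = "complete")
    lab <- cutree(hc_final, k)
    labels[[key]] <- lab
    criterion[key] <- calinski_harabasz(m, lab)
  }
  chosen_k <- k_range[which.max(criterion)]
  structure(
    list(
      consensus = consensus,
      labels = labels,
      criterion = criterion,
      chosen_k = chosen_k,
      final_labels = labels[[as.character(chosen_k)]],
      k_range = k_range,
      n_reps = n_reps,
      subsample_fraction = subsample_fraction,
      seed = seed
    ),
    class = "consensus_clustering"
  )
}

#' @export
print.consensus_clustering <- function(x, ...) {
  cat(sprintf(
    "<consensus_clustering> %d samples, k in {%s}, %d repeats\n  chosen k = %d (Calinski-Harabasz %s)\n",
    length(x$final_labels), paste(x$k_range, collapse = ","), x$n_reps,
    x$chosen_k,
    paste(sprintf("%s:%.1f", names(x$criterion), x$criterion), collapse = " ")
  ))
  invisible(x)
}

#' Label consensus clusters as ICR Low / Medium / High
#'
#' Ranks clusters by the mean ICR score of their members: the top cluster is
#' `High`, the bottom `Low`, and (for three clusters) the middle `Medium`.
#' With k = 2 only `High`/`Low` are assigned; with k > 3 only the extreme
#' clusters are labeled and intermediate clusters are left `NA` — both cases
#' emit a warning. Ties between cluster means are broken deterministically
#' by cluster size then by the lexicographically smallest member sample id,
#' with a warning.
#'
#' @param result a [consensus_cluster()] result.
#' @param expr the expression matrix the clustering was run on (full matrix
#'   is fine; scores use `sig`).
#' @param sig the [gene_signature()] defining the score (default
#'   [icr_signature()]).
#' @return Data frame with `sample`, `icr_score` and ordered factor
#'   `icr_cluster` (`Low < Medium < High`).
#' @export
assign_icr_labels <- function(result, expr, sig = icr_signature()) {
  if (!inherits(result, "consensus_clustering")) {
    stop_("`result` must come from consensus_cluster()")
  }
  scores <- icr_score(expr, sig)
  lab <- result$final_labels
  if (!all(names(lab) %in% names(scores))) {
    stop_("clustered samples missing from expression matrix")
  }
  scores <- scores[names(lab)]
  k <- length(unique(lab))
  cl_mean <- tapply(scores, lab, mean)
  cl_size <- tapply(scores, lab, length)
  cl_minid <- tapply(names(lab), lab, function(s) min(s))
  if (anyDuplicated(cl_mean)) {
    warn_("tie in cluster mean ICR scores; breaking by size then sample id")
  }
  ord <- order(cl_mean, cl_size, rank(cl_minid)) # ascending: Low first
  ranked <- names(cl_mean)[ord]
  cluster_label <- setNames(rep(NA_character_, k), ranked)
  cluster_label[ranked[1]] <- "Low"
  cluster_label[ranked[k]] <- "High"
  if (k == 3) {
    cluster_label[ranked[2]] <- "Medium"
  } else {
    warn_(sprintf(
      "chosen k = %d (not 3): only extreme clusters labeled High/Low", k
    ))
  }
  data.frame(
    sample = names(lab),
    icr_score = unname(scores),
    icr_cluster = factor(
      cluster_label[as.character(lab)],
      levels = c("Low", "Medium", "High"), ordered = TRUE
    ),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Single-sample gene-set enrichment scores
#'
#' For each sample independently, genes are ranked by expression; the score
#' of a gene set is the sum over all ranks of the difference between the
#' weighted empirical cumulative distribution of in-set genes (weights are
#' the expression ranks raised to `weight_exponent`) and the uniform
#' cumulative distribution of out-of-set genes — the standard single-sample
#' enrichment random walk. With `weight_exponent = 0` the walk is
#' unweighted.
#'
#' @param expr expression matrix, genes x samples.
#' @param gene_sets a named list of character vectors, or a list of
#'   [gene_signature()] objects.
#' @param weight_exponent rank-weight exponent (default 0.25).
#' @param normalize divide each gene set's scores by their range across
#'   samples (default `FALSE`).
#' @return Numeric matrix, gene sets x samples.
#' @export
ssgsea_scores <- function(expr, gene_sets, weight_exponent = 0.25,
                          normalize = FALSE) {
  assert_matrix_named(expr, "expr")
  if (inherits(gene_sets, "gene_signature")) gene_sets <- list(gene_sets)
  sets <- lapply(gene_sets, function(gs) {
    if (inherits(gs, "gene_signature")) gs$genes else as.character(gs)
  })
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    nms <- vapply(seq_along(gene_sets), function(i) {
      gs <- gene_sets[[i]]
      if (inherits(gs, "gene_signature")) gs$name else paste0("set", i)
    }, character(1))
    names(sets) <- nms
  }
  n_genes <- nrow(expr)
  set_idx <- lapply(names(sets), function(nm) {
    idx <- which(rownames(expr) %in% sets[[nm]])
    if (length(idx) < 2) {
      stop_(sprintf("gene set '%s' overlaps the matrix by fewer than 2 genes", nm))
    }
    idx
  })
  names(set_idx) <- names(sets)
  scores <- matrix(
    0, nrow = length(sets), ncol = ncol(expr),
    dimnames = list(names(sets), colnames(expr))
  )
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average") # 1 = lowest expression
    ord <- order(r, decreasing = TRUE)
    r_sorted <- r[ord]
    for (s in seq_along(set_idx)) {
      in_set <- ord %in% set_idx[[s]]
      w <- abs(r_sorted)^weight_exponent
      w[!in_set] <- 0
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!in_set) / (n_genes - sum(in_set))
      scores[s, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- apply(scores, 1, function(v) diff(range(v)))
    rng[rng == 0] <- 1
    scores <- scores / rng
  }
  scores
}
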