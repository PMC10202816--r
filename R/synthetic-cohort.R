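#' Configuration for a synthetic multi-omics cohort
#'
#' Bundles and validates every knob of the linked cohort generator. The
#' defaults describe a mid-sized colon-cancer cohort with three planted
#' immune (ICR) groups of roughly equal size, a clear signature effect in
#' log2 expression, group-graded TCR clonality, a hypermutated minority,
#' immunoediting in half the cohort, and five survival-linked taxa among
#' one hundred; see the methods vignette for the rationale behind each
#' value.
#'
#' @param n_samples number of patients.
#' @param n_genes genes in the expression matrix (includes the 20
#'   signature genes).
#' @param icr_group_proportions length-3 proportions (Low, Medium, High)
#'   summing to 1.
#' @param icr_effect expression shift (log2 units) added to signature genes
#'   per group step (Low +0, Medium +1x, High +2x).
#' @param noise_sd expression noise sd in log2 units.
#' @param clone_richness clones per simulated repertoire (>= 2).
#' @param clonality_targets length-3 target clonality per ICR group
#'   (Low, Medium, High), each in `[0, 1)`.
#' @param hypermutated_fraction fraction of hypermutated tumors.
#' @param editing_fraction fraction of tumors with immunoediting.
#' @param editing_strength multiplier in (0, 1] applied to the expected
#'   neoantigen count of edited tumors (1 = no editing).
#' @param neoantigen_noise_sd sd of the additive noise on observed
#'   neoantigen counts.
#' @param n_taxa number of microbiome genera.
#' @param n_risk_taxa,n_protective_taxa numbers of survival-linked taxa.
#' @param hazard_coefficients named list of log-hazard weights for the
#'   ground-truth variables: `icr_level` (per ordinal step, centered at
#'   Medium), `edited` (0/1), `risk_taxon` and `protective_taxon` (per
#'   latent taxon z-value).
#' @param censoring_rate expected fraction of censored samples.
#' @param tcr_missing_fraction fraction of samples without TCR assay data
#'   (`ceiling(n * fraction)` samples are dropped from the repertoire set).
#' @param total_templates sequenced T cell templates per repertoire.
#' @param seed integer master seed; a fixed config is byte-reproducible.
#' @return A validated object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 150,
                          n_genes = 500,
                          icr_group_proportions = c(1, 1, 1) / 3,
                          icr_effect = 3,
                          noise_sd = 1,
                          clone_richness = 500,
                          clonality_targets = c(0.08, 0.18, 0.30),
                          hypermutated_fraction = 0.25,
                          editing_fraction = 0.5,
                          editing_strength = 0.5,
                          neoantigen_noise_sd = 0.75,
                          n_taxa = 100,
                          n_risk_taxa = 3,
                          n_protective_taxa = 2,
                          hazard_coefficients = list(
                            icr_level = -0.35,
                            edited = -0.35,
                            risk_taxon = 0.8,
                            protective_taxon = -0.8
                          ),
                          censoring_rate = 0.55,
                          tcr_missing_fraction = 0,
                          total_templates = 20000,
                          seed = 1L) {
  cfg <- list(
    n_samples = n_samples, n_genes = n_genes,
    icr_group_proportions = icr_group_proportions,
    icr_effect = icr_effect, noise_sd = noise_sd,
    clone_richness = clone_richness,
    clonality_targets = clonality_targets,
    hypermutated_fraction = hypermutated_fraction,
    editing_fraction = editing_fraction,
    editing_strength = editing_strength,
    neoantigen_noise_sd = neoantigen_noise_sd,
    n_taxa = n_taxa, n_risk_taxa = n_risk_taxa,
    n_protective_taxa = n_protective_taxa,
    hazard_coefficients = hazard_coefficients,
    censoring_rate = censoring_rate,
    tcr_missing_fraction = tcr_missing_fraction,
    total_templates = total_templates,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_samples < 1 || cfg$n_samples != round(cfg$n_samples)) {
    stop_("`n_samples` must be a positive integer")
  }
  if (cfg$n_genes < 20 || cfg$n_genes != round(cfg$n_genes)) {
    stop_("`n_genes` must be an integer >= 20 (to hold the signature genes)")
  }
  p <- cfg$icr_group_proportions
  if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop_("`icr_group_proportions` must be a 3-vector summing to 1")
  }
  assert_scalar_number(cfg$icr_effect, "icr_effect", 0)
  assert_scalar_number(cfg$noise_sd, "noise_sd", 0)
  if (cfg$clone_richness < 2) {
    stop_("`clone_richness` < 2: normalized entropy undefined")
  }
  ct <- cfg$clonality_targets
  if (length(ct) != 3 || any(ct < 0) || any(ct >= 1)) {
    stop_("`clonality_targets` must be three values in [0, 1)")
  }
  for (nm in c("hypermutated_fraction", "editing_fraction",
               "censoring_rate", "tcr_missing_fraction")) {
    assert_scalar_number(cfg[[nm]], nm, 0, 1)
  }
  if (cfg$editing_strength <= 0 || cfg$editing_strength > 1) {
    stop_("`editing_strength` must be in (0, 1]")
  }
  if (cfg$n_risk_taxa + cfg$n_protective_taxa > cfg$n_taxa) {
    stop_("designated risk + protective taxa exceed `n_taxa`")
  }
  need <- c("icr_level", "edited", "risk_taxon", "protective_taxon")
  if (!all(need %in% names(cfg$hazard_coefficients))) {
    stop_(sprintf("`hazard_coefficients` must name: %s",
                  paste(need, collapse = ", ")))
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> n = %d, %d genes, effect %.1f (sd %.1f), %d taxa, seed %d\n",
    x$n_samples, x$n_genes, x$icr_effect, x$noise_sd, x$n_taxa, x$seed
  ))
  invisible(x)
}

sample_ids <- function(n) sprintf("S%04d", seq_len(n))

draw_icr_groups <- function(cfg) {
  counts <- floor(cfg$n_samples * cfg$icr_group_proportions)
  while (sum(counts) < cfg$n_samples) {
    i <- which.max(cfg$n_samples * cfg$icr_group_proportions - counts)
    counts[i] <- counts[i] + 1
  }
  lev <- c("Low", "Medium", "High")
  factor(sample(rep(lev, counts)), levels = lev, ordered = TRUE)
}

#' Generate a planted-group expression matrix
#'
#' Log2-scale expression for `n_genes` x `n_samples`: per-gene baselines,
#' Gaussian noise with sd `noise_sd`, and — for the 20 ICR signature genes
#' only — a mean shift of `icr_effect` per ICR group step (Low +0,
#' Medium +1, High +2). All other genes are pure noise around their
#' baseline.
#'
#' @param config a [cohort_config()].
#' @return List with `expression` (matrix, genes x samples) and `truth`
#'   (data frame with `sample`, `true_icr_level`).
#' @export
generate_expression <- function(config) {
  cfg <- validate_cohort_config(config)
  with_seed(cfg$seed, {
    ids <- sample_ids(cfg$n_samples)
    sig <- icr_signature()$genes
    genes <- c(sig, sprintf("GENE%04d", seq_len(cfg$n_genes - length(sig))))
    group <- draw_icr_groups(cfg)
    baseline <- runif(cfg$n_genes, 2, 10)
    shift <- cfg$icr_effect * (as.integer(group) - 1) # 0, 1x, 2x
    m <- matrix(
      rnorm(cfg$n_genes * cfg$n_samples, sd = cfg$noise_sd),
      nrow = cfg$n_genes,
      dimnames = list(genes, ids)
    ) + baseline
    m[sig, ] <- m[sig, ] + rep(shift, each = length(sig))
    list(
      expression = m,
      truth = data.frame(sample = ids, true_icr_level = group,
                         stringsAsFactors = FALSE)
    )
  })
}

# normalized geometric clone weights w_i proportional to (1-q)^(i-1)
.geometric_weights <- function(q, s) {
  if (q <= 0) return(rep(1 / s, s))
  w <- (1 - q)^(seq_len(s) - 1)
  w / sum(w)
}

# expected template counts when every clone keeps a one-template baseline
# (so richness survives multinomial sampling and clonality stays on target)
.expected_counts <- function(q, s, total) {
  .geometric_weights(q, s) * (total - s) + 1
}

# monotone map from geometric skew q to the clonality of the expected
# counts; invert by bisection
calibrate_clone_skew <- function(target, s, total, tol = 1e-9) {
  if (target < 1e-9) return(0)
  lo <- 1e-12
  hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (clonality_from_counts(.expected_counts(mid, s, total)) < target) {
      lo <- mid
    } else {
      hi <- mid
    }
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Generate a matched tumor/normal TCR repertoire pair
#'
#' Tumor clone frequencies follow a geometric (stick-breaking) law whose
#' skew is calibrated by bisection so the clonality of the repertoire hits
#' `clonality_target`; template counts are a one-template baseline per
#' clone plus a multinomial draw from the geometric weights (the baseline
#' keeps the richness — and hence the entropy normalization — stable under
#' sampling). The normal repertoire shares a rank-aligned background clone
#' pool with the tumor at its own (lower) clonality: rank alignment bounds
#' background tumor/normal frequency ratios well below the enrichment
#' fold, so with the default fully shared pool the planted clones are the
#' only tumor-enriched ones. `n_spiked` planted clones get deterministic
#' counts at `spike_frequency` in the tumor and `spike_frequency /
#' spike_fold` in the normal, satisfying the 32-fold / 0.1% enrichment
#' rule by construction at the defaults. With `shared_fraction < 1` the
#' lowest-frequency ranks become private to each tissue; private tumor
#' clones above the frequency floor then also count as enriched under the
#' absent-in-normal policy.
#'
#' @param config a [cohort_config()] (supplies richness and template
#'   counts).
#' @param clonality_target tumor clonality target in `[0, 1)`.
#' @param sample_id base sample identifier.
#' @param n_spiked planted tumor-enriched clones.
#' @param spike_frequency tumor frequency of each planted clone.
#' @param spike_fold tumor/normal frequency ratio of planted clones.
#' @param normal_clonality clonality target of the normal repertoire.
#' @param shared_fraction fraction of background clones shared between the
#'   tumor and normal pools (1 = fully shared, 0 = disjoint).
#' @param seed per-pair seed; defaults to the config seed.
#' @return List with `tumor` and `normal` [repertoire()] objects and
#'   `spiked_ids`.
#' @export
generate_repertoire_pair <- function(config, clonality_target,
                                     sample_id = "S0001",
                                     n_spiked = 0,
                                     spike_frequency = 0.005,
                                     spike_fold = 64,
                                     normal_clonality = 0.05,
                                     shared_fraction = 1,
                                     seed = NULL) {
  cfg <- validate_cohort_config(config)
  assert_scalar_number(clonality_target, "clonality_target", 0, 1 - 1e-12)
  s <- cfg$clone_richness
  total <- cfg$total_templates
  if (n_spiked > 0 && n_spiked * spike_frequency >= 0.5) {
    stop_("spiked clones would dominate the repertoire; lower `n_spiked` or `spike_frequency`")
  }
  with_seed(seed %||% cfg$seed, {
    # rank-aligned background pool: rank i has weight w[i] in both tissues;
    # the tail (lowest-frequency) ranks become tissue-private when
    # shared_fraction < 1
    n_shared <- round(shared_fraction * s)
    tumor_ids <- normal_ids <- sprintf("TCR-BG-%05d", seq_len(s))
    if (n_shared < s) {
      tail_idx <- (n_shared + 1):s
      tumor_ids[tail_idx] <- sprintf("TCR-TU-%05d", tail_idx)
      normal_ids[tail_idx] <- sprintf("TCR-NO-%05d", tail_idx)
    }
    spike_ids <- if (n_spiked > 0) sprintf("TCR-SP-%03d", seq_len(n_spiked)) else character(0)

    spike_count_t <- round(spike_frequency * total)
    spike_count_n <- round(spike_frequency / spike_fold * total)
    bg_total_t <- total - n_spiked * spike_count_t
    bg_total_n <- total - n_spiked * spike_count_n

    q_t <- calibrate_clone_skew(clonality_target, s, bg_total_t)
    q_n <- calibrate_clone_skew(normal_clonality, s, bg_total_n)
    w_t <- .geometric_weights(q_t, s)
    w_n <- .geometric_weights(q_n, s)
    counts_t <- 1L + as.integer(rmultinom(1, bg_total_t - s, w_t))
    counts_n <- 1L + as.integer(rmultinom(1, bg_total_n - s, w_n))

    # a small unproductive tail exercises the productive-only accounting
    n_unprod <- max(3L, round(0.02 * s))
    unprod_ids <- function(tag) sprintf("TCR-%s-X%03d", tag, seq_len(n_unprod))
    unprod_counts <- function() 1L + stats::rpois(n_unprod, 3)

    tumor <- repertoire(
      sample_id = paste0(sample_id, "-T"),
      clone_id = c(spike_ids, tumor_ids, unprod_ids("TU")),
      templates = c(rep(spike_count_t, n_spiked), counts_t, unprod_counts()),
      productive = c(rep(TRUE, n_spiked + s), rep(FALSE, n_unprod))
    )
    normal <- repertoire(
      sample_id = paste0(sample_id, "-N"),
      clone_id = c(spike_ids, normal_ids, unprod_ids("NO")),
      templates = c(rep(spike_count_n, n_spiked), counts_n, unprod_counts()),
      productive = c(rep(TRUE, n_spiked + s), rep(FALSE, n_unprod))
    )
    list(tumor = tumor, normal = normal, spiked_ids = spike_ids)
  })
}

#' Generate mutation counts and observed neoantigens with planted editing
#'
#' Nonsynonymous counts `x` come from a two-component log-normal mixture
#' (hypermutated tumors well above the 12/Mb burden cutoff, non-hypermutated
#' below it); draws at or below the expected-neoantigen model's zero
#' crossing are rejected and redrawn, so every sample is evaluable.
#' Observed neoantigens are `O = max(0, round(E(x) * m + eps))` with
#' `m = editing_strength` for edited samples and 1 otherwise. A MANTIS-like
#' instability score is attached (MSI-H arising within the hypermutated
#' component).
#'
#' @param config a [cohort_config()].
#' @param truth data frame with a `sample` column (e.g. from
#'   [generate_expression()]); row count fixes the cohort size.
#' @param model the [expected_neoantigen_model()] used as generative truth.
#' @return Data frame per sample: `sample`, `x`, `tmb_per_mb`,
#'   `hypermutated_true`, `mantis_score`, `edited_true`,
#'   `observed_neoantigens`.
#' @export
generate_mutation_neoantigen <- function(config, truth,
                                         model = expected_neoantigen_model()) {
  cfg <- validate_cohort_config(config)
  n <- nrow(truth)
  zero_cross <- -model$intercept / model$slope
  x_floor <- ceiling(zero_cross) + 3 # stay clear of E(x) <= 0
  with_seed(cfg$seed + 1L, {
    hyper <- runif(n) < cfg$hypermutated_fraction
    draw_x <- function(m_log, s_log, lo, hi) {
      x <- round(rlnorm(1, m_log, s_log))
      tries <- 0
      while ((x < lo || x > hi) && tries < 1000) {
        x <- round(rlnorm(1, m_log, s_log))
        tries <- tries + 1
      }
      max(lo, min(x, hi))
    }
    x <- vapply(seq_len(n), function(i) {
      if (hyper[i]) {
        draw_x(log(1500), 0.4, 481, Inf) # burden > 12/Mb over 40 Mb
      } else {
        draw_x(log(120), 0.35, x_floor, 480)
      }
    }, numeric(1))
    edited <- runif(n) < cfg$editing_fraction
    e <- model$intercept + model$slope * x
    m <- ifelse(edited, cfg$editing_strength, 1)
    o <- pmax(0, round(e * m + rnorm(n, sd = cfg$neoantigen_noise_sd)))
    mantis <- ifelse(hyper, runif(n, 0.42, 1.2), runif(n, 0.05, 0.38))
    data.frame(
      sample = truth$sample,
      x = as.integer(x),
      tmb_per_mb = x / 40,
      hypermutated_true = hyper,
      mantis_score = mantis,
      edited_true = edited,
      observed_neoantigens = as.integer(o),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate linked microbiome compositions and survival times
#'
#' Compositions are Dirichlet draws (gamma construction) with per-sample
#' log-scale perturbations `exp(0.8 * z)`, `z ~ N(0, 1)`, on the designated
#' risk and protective taxa, giving them survival-relevant abundance
#' variation. The proportional-hazards linear predictor combines the ICR
#' level and editing status with the cohort-standardized abundance
#' (z-value) of each designated taxon, weighted by the configured
#' `hazard_coefficients` — so the planted truth is linear in exactly the
#' standardized abundances a microbiome risk model sees. Event times are exponential with
#' baseline rate log(2)/5 per year (median survival 5 years at the null
#' linear predictor); censoring is independent Uniform(0, b) with `b`
#' calibrated so the expected censored fraction equals `censoring_rate`.
#'
#' @param config a [cohort_config()].
#' @param truth data frame with `sample`, `true_icr_level` and
#'   `edited_true` columns.
#' @return List with `abundance` (samples x taxa relative abundances),
#'   `survival` (data frame `sample`, `time`, `event`, `endpoint`),
#'   `taxon_truth` (per-taxon sign) and `linear_predictor`.
#' @export
generate_microbiome_survival <- function(config, truth) {
  cfg <- validate_cohort_config(config)
  n <- nrow(truth)
  hz <- cfg$hazard_coefficients
  with_seed(cfg$seed + 2L, {
    taxa <- sprintf("Genus%03d", seq_len(cfg$n_taxa))
    risk_idx <- seq_len(cfg$n_risk_taxa)
    prot_idx <- cfg$n_risk_taxa + seq_len(cfg$n_protective_taxa)
    sign_vec <- rep("0", cfg$n_taxa)
    sign_vec[risk_idx] <- "+"
    sign_vec[prot_idx] <- "-"
    conc <- rlnorm(cfg$n_taxa, meanlog = -1, sdlog = 1.2)
    # designated taxa get common-genus concentrations so they survive the
    # prevalence/abundance filter
    conc[c(risk_idx, prot_idx)] <- runif(length(c(risk_idx, prot_idx)), 1.5, 3)
    z <- matrix(rnorm(n * cfg$n_taxa), n, cfg$n_taxa)
    g <- matrix(
      rgamma(n * cfg$n_taxa, shape = rep(conc, each = n), rate = 1),
      n, cfg$n_taxa
    )
    pert <- c(risk_idx, prot_idx)
    g[, pert] <- g[, pert] * exp(0.8 * z[, pert])
    abundance <- g / rowSums(g)
    dimnames(abundance) <- list(truth$sample, taxa)

    icr_idx <- as.integer(factor(truth$true_icr_level,
                                 levels = c("Low", "Medium", "High")))
    za <- scale(abundance[, pert, drop = FALSE]) # cohort-standardized taxa
    lp <- hz$icr_level * (icr_idx - 2) +
      hz$edited * as.numeric(truth$edited_true) +
      hz$risk_taxon * rowSums(za[, seq_along(risk_idx), drop = FALSE]) +
      hz$protective_taxon *
        rowSums(za[, length(risk_idx) + seq_along(prot_idx), drop = FALSE])
    base_rate <- log(2) / 5
    rate <- base_rate * exp(lp)
    t_event <- rexp(n, rate = rate)
    if (cfg$censoring_rate > 0) {
      # expected censored fraction under C ~ U(0, b):
      # P(T > C) = mean_i (1 - exp(-rate_i * b)) / (rate_i * b)
      cens_frac <- function(b) mean((1 - exp(-rate * b)) / (rate * b))
      b <- uniroot(function(b) cens_frac(b) - cfg$censoring_rate,
                   lower = 1e-6, upper = 1e6, tol = 1e-9)$root
      c_time <- runif(n, 0, b)
      time <- pmin(t_event, c_time)
      event <- as.integer(t_event <= c_time)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    list(
      abundance = abundance,
      survival = data.frame(
        sample = truth$sample, time = time, event = event,
        endpoint = "OS", stringsAsFactors = FALSE
      ),
      taxon_truth = data.frame(
        taxon = taxa, true_risk_sign = sign_vec, stringsAsFactors = FALSE
      ),
      linear_predictor = setNames(lp, truth$sample)
    )
  })
}

#' Generate a fully linked synthetic cohort
#'
#' Runs every per-platform generator under one master seed and returns all
#' tables keyed by the same sample ids, plus the ground truth needed to
#' check recovery: planted ICR groups, editing flags, per-taxon risk signs
#' and the true linear predictor. TCR repertoires are generated for the
#' samples not masked by `tcr_missing_fraction` and at the clonality
#' target of the sample's ICR group. Clinical covariates (age, stage, CMS;
#' MSI from the MANTIS-like score) are drawn independently of the hazard.
#'
#' @param config a [cohort_config()].
#' @return Object of class `"synthetic_cohort"`: list with `config`,
#'   `expression`, `repertoires` (named list of tumor/normal pairs),
#'   `mutation`, `abundance`, `survival`, `clinical` and `truth`.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  expr <- generate_expression(cfg)
  truth <- expr$truth
  mut <- generate_mutation_neoantigen(cfg, truth)
  truth$edited_true <- mut$edited_true
  micro <- generate_microbiome_survival(cfg, truth)
  truth$true_linear_predictor <- unname(micro$linear_predictor[truth$sample])

  n <- cfg$n_samples
  n_missing <- ceiling(cfg$tcr_missing_fraction * n)
  reps <- with_seed(cfg$seed + 3L, {
    with_tcr <- if (n_missing > 0) {
      sort(sample.int(n, n - n_missing))
    } else {
      seq_len(n)
    }
    targets <- cfg$clonality_targets[
      as.integer(factor(truth$true_icr_level, c("Low", "Medium", "High")))
    ]
    pair_seeds <- sample.int(.Machine$integer.max %/% 2L, n)
    out <- lapply(with_tcr, function(i) {
      generate_repertoire_pair(
        cfg, clonality_target = targets[i], sample_id = truth$sample[i],
        seed = pair_seeds[i]
      )
    })
    names(out) <- truth$sample[with_tcr]
    out
  })
  clinical <- with_seed(cfg$seed + 4L, {
    data.frame(
      sample = truth$sample,
      age = round(rnorm(n, 66, 10)),
      stage = factor(sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                            prob = c(0.18, 0.38, 0.3, 0.14)),
                     levels = c("I", "II", "III", "IV"), ordered = TRUE),
      msi = classify_msi(mut$mantis_score),
      cms = factor(sample(paste0("CMS", 1:4), n, replace = TRUE,
                          prob = c(0.15, 0.4, 0.15, 0.3))),
      stringsAsFactors = FALSE
    )
  })
  structure(
    list(
      config = cfg,
      expression = expr$expression,
      repertoires = reps,
      mutation = mut,
      abundance = micro$abundance,
      survival = micro$survival,
      clinical = clinical,
      truth = list(samples = truth, taxa = micro$taxon_truth)
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<synthetic_cohort> %d samples (seed %d)\n",
      "  expression %d x %d; %d TCR pairs; %d taxa; %d events\n"
    ),
    x$config$n_samples, x$config$seed,
    nrow(x$expression), ncol(x$expression), length(x$repertoires),
    ncol(x$abundance), sum(x$survival$event)
  ))
  invisible(x)
}
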