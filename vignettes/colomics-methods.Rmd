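---
title: "Methods: multi-omics immune prognostic scoring with colomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics immune prognostic scoring with colomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(colomics)
```

`colomics` integrates four molecular platforms measured on the same colon
cancer patients — bulk tumor transcriptome, somatic mutations from
whole-exome sequencing, the T cell receptor (TCR) repertoire and the
tumor-associated microbiome — into per-patient prognostic scores. This
vignette is the package's own account of the models, the tunable
parameters, the numerical choices, and what the synthetic-data tests do
and do not demonstrate.

## ICR score and immune subtypes

The Immunologic Constant of Rejection is a fixed 20-gene signature of
Th1 polarization (*IFNG, IL12B, TBX21, STAT1, IRF1*), CD8 T cell
effector/cytotoxic function (*CD8A, CD8B, GZMA, GZMB, GZMH, GNLY, PRF1*),
chemoattraction (*CXCL9, CXCL10, CCL5*) and counter-regulation (*CD274,
PDCD1, CTLA4, FOXP3, IDO1*). The **ICR score** of a sample is simply the
arithmetic mean of the log2-normalized expression of these 20 genes —
no weighting, no normalization beyond what the expression matrix already
carries. `icr_score()` refuses to run if any signature gene is absent,
rather than silently averaging a subset.

**Consensus clustering.** Immune subtypes come from subsample-and-cluster
consensus: in each repeat a fraction of samples (default 0.8, the
convention of the standard consensus-clustering tooling; the choice is
exposed) is drawn without replacement and clustered with Ward-linkage
agglomerative clustering into k groups. Distances are Euclidean on
per-gene z-scored signature expression: z-scoring keeps highly expressed
genes from dominating the metric and matches how such signatures are
displayed and clustered in practice (`scale_rows = FALSE` disables it).
The consensus index of a sample pair at a given k is the fraction of
co-sampled repeats in which the pair co-clustered; final labels come
from complete-linkage clustering of the consensus dissimilarity
1 − consensus ("complete outer linkage"), cut at k. The number of
clusters is chosen over k = 2–6 (the search range is open; the optimum
reported for these data is 3) by maximizing the Calinski–Harabasz
variance-ratio criterion of the final labels on the same z-scored data.
The production default for repeats is large (5,000); the tests use
150–250 repeats, which is where the consensus matrix for well-separated
groups has already sharpened to near 0/1 entries — the test sizes are
reported in each test and are the package's own choice of problem size.
Clusters are then ranked by their members' mean ICR score: top = High,
bottom = Low, middle = Medium. Ties in cluster means are broken by
cluster size then lexicographic sample id, with a warning; a chosen k
other than 3 labels only the extremes and warns.

**Single-sample enrichment.** `ssgsea_scores()` implements the standard
single-sample enrichment walk: per sample, genes are ranked by
expression; the score of a set is the summed difference between the
weighted in-set cumulative distribution (weights = expression rank to
the power 0.25, the cited method's convention; exponent 0 gives the
unweighted walk used as a brute-force oracle in the tests) and the
uniform out-of-set cumulative distribution. Gene-set contents (immune
traits, tumor pathways, cell-type signatures) are user-supplied.

## TCR repertoire metrics

Over the productive (in-frame, stop-free) clones of a repertoire with
frequencies p:

- Shannon entropy H = −Σ p·log2 p (bits),
- Pielou evenness J = H / log2 S, S = number of unique productive
  rearrangements,
- clonality = 1 − J.

Clonality lives in [0, 1): 0 for a perfectly even repertoire, values
near 1 when few clones dominate. The same formulas serve DNA-targeted
(immunoSEQ-style) and RNA-derived (MiXCR-style) clone tables; the log
base cancels in J, so natural-log entropy gives the identical clonality.
J is undefined for S < 2 and the package raises an error rather than
returning a sentinel.

A clone is **tumor-enriched** versus the matched normal tissue when its
tumor productive frequency strictly exceeds 0.1% *and* its tumor/normal
frequency ratio is at least 32 (both constants exposed). Clones detected
in tumor but absent from normal satisfy the fold criterion under the
default policy — an undetected clone is maximally enriched — with a
pseudo-count alternative (`absent_normal = "pseudocount"`) for
sensitivity analyses; the frequency floor applies regardless. Clone
identity is the exact rearrangement sequence string. The cohort-level
summary is template-weighted: the fraction of productive templates
carried by enriched clones.

## Somatic mutations, neoantigens, immunoediting

Variant retention: class in the nonsynonymous whitelist (frameshift
indels, in-frame indels, missense, nonsense, nonstop, splice site,
translation start site), allele fraction ≥ 5%, tumor depth > 3 reads
(i.e. ≥ 4), population allele frequency ≤ 1%. An optional effect filter
(used for gene-frequency analyses) additionally drops variants
predicted tolerated by SIFT or benign by PolyPhen. TMB is the retained
nonsynonymous count divided by the 40 Mb capture; hypermutation is
strictly above 12/Mb. MSI labels follow the instability-score rule:
MSI-H strictly above 0.4, MSS at or below.

A candidate epitope is a **neoantigen** when the mutant median IC50 is
strictly below 500 nM while the wild-type median is strictly above
500 nM. The **GIE value** is observed/expected neoantigens, with the
expected count linear in the nonsynonymous mutation count:
E(x) = −2.38770 + 0.09171·x (defaults; `refit_expected_model()` refits
by OLS on reference samples). Below the line's zero crossing
(x ≈ 26) the ratio is undefined; such samples are flagged non-evaluable
and excluded from downstream composites instead of being clamped —
fabricating a ratio there would be worse than missingness. A sample
"displays GIE" when its ratio falls below 1 (fewer neoantigens than
expected); the cutoff is exposed because only the direction, not a
printed threshold, is prescribed.

The **IES** composite is: IES1 = ICR Low without GIE, IES2 = ICR Low
with GIE, IES3 = ICR High without GIE, IES4 = ICR High with GIE;
ICR-Medium or non-evaluable samples are unassigned and analyzed
separately.

## Microbiome profile

Genus-level relative abundances (per-sample closure to 1) are filtered
to genera present (> 0) in at least 10% of samples *and* reaching at
least 1% abundance in at least one sample; both bounds are inclusive
("at least"), presence is strictly positive. Alpha diversity reports
observed richness, Chao1 (bias-corrected form
S + F1(F1−1)/(2(F2+1)) by default, classic F1²/(2F2) by flag; integer
counts required), Shannon in natural log — deliberately distinct from
the base-2 TCR entropy, matching ecology convention — and inverse
Simpson. Shannon and inverse Simpson delegate to vegan.

Taxon-label harmonization is a many-to-one rename with summed
abundances (mass conserved per sample); the packaged default collapses
the amplicon classifier's "Ruminococcus 1"/"Ruminococcus 2" into
"Ruminococcus" so 16S-trained signatures can transfer to shotgun
profiles. Tumor-normal differential abundance uses the two-sided paired
Wilcoxon signed-rank test per taxon with Benjamini–Hochberg FDR; fold
changes are ratios of means with a 1e-6 relative-abundance pseudo-count
(zero-abundance taxa would otherwise produce infinite ratios).

## The MBR signature

Training z-scores every genus column with the training mean and
*sample* (n−1) standard deviation — the estimator is fixed and recorded,
because scores must transfer: a tested sample is always standardized
against the training distribution, never its own cohort's. The risk
model is a relaxed elastic-net Cox regression (solver: glmnet). The
hyperparameter grid crosses the relaxation mixing γ ∈ {0, 0.25, 0.5,
0.75, 1} (1 = fully penalized, 0 = unpenalized refit on the active set)
with a 50-value λ path truncated at 5% of λ_max — below that the
relaxed refits degenerate into unpenalized fits over ~all taxa, which
are slow and ill-conditioned; the elastic-net mixing α defaults to 0.5.
Selection maximizes the mean out-of-fold Harrell concordance over 5
folds (fold assignment seeded; out-of-fold scores are computed only on
held-out samples); ties prefer the larger λ (sparser model), then the
larger γ. The winning point is refit on the full training set, and the
nonzero-coefficient genera form the classifier.

Scoring is per-sample and overlap-based: score = Σ coefficient ×
training-z(abundance) over classifier taxa present in the table.
Classifier taxa absent from a cohort contribute zero, so scores depend
only on the overlapping genera and are independent across samples.
Scores binarize at 0: strictly negative = low risk. A score of exactly
0 is assigned to the high-risk side — "low" is defined strictly below
0, and leaving 0 unassigned would create a silent gap — and the choice
is documented here because it is a closure of the published wording,
not part of it. Taxa with zero training variance cannot be z-scored and
are excluded with a warning. Models serialize to a versioned plain-text
file with 17-significant-digit numbers, so a write/read cycle is
bit-exact.

Under permuted survival the grid of out-of-fold concordances centers on
0.5 (verified in the acceptance suite). Note that the *selected*
maximum of that grid exceeds 0.5 by a few points under the null — the
usual winner's-curse of picking the best of ~250 noisy cells — which is
why honest performance claims for a trained model come from external
cohorts or nested validation, not from the selection criterion itself.

## Survival machinery

Kaplan–Meier estimation, the log-rank test and Cox proportional-hazards
fits delegate to the survival package behind a contract-checking
surface: Efron tie handling by default (Breslow by flag), Wald 95%
confidence intervals on the log-hazard scale, and a guard refusing
two-group hazard contrasts when either arm has fewer than 10 patients
(overridable). Ordered factors enter Cox models as integer scores
(ordinal trend); the fixed clinical adjustment set encodes age
continuous, stage ordinal I–IV, MSI binary with MSS reference, CMS
categorical with CMS4 reference. Harrell's concordance is implemented
in the package (pairs usable when the shorter follow-up ended in an
event; score ties 0.5) because it is also the cross-validation metric
and must be available standalone; it is checked against an O(n²)
enumeration oracle.

`density_matched_subsampling()` asks whether an association survives
reweighting a cohort toward another cohort's composition: scheme A
draws subsets uniformly, scheme B draws them with weights proportional
to a target density — a piecewise-linear interpolation of a fixed-grid
histogram (default 30 bins) of the target score sample, evaluated at
each case's matching score — and the count of subsets with a
significant (p < 0.05) univariate Cox fit is compared between schemes
with a 2×2 chi-squared test. The default is 100 subsets of 200; the
tests use smaller runs of the same machinery.

## The mICRoScore

mICRoScore high ⇔ ICR High *and* MBR low risk; everything else with
both inputs present is low; a missing input yields "unassigned" rather
than a default, and per-analysis complete-case counts are reported by
the assembly helpers. The truth table is enumerated exhaustively in the
tests, including all missingness patterns.

Group survival summaries read the Kaplan–Meier step function at the
horizon (default t = 5 years) with the estimator's usual
right-continuous convention: an event at exactly t = 5.0 counts
against 5-year survival. With continuous follow-up times the two step
conventions differ only on ties at the query point.

## The synthetic cohort generator

The generator exists so that every downstream stage has a planted,
recoverable truth. Its defaults are fixed once and describe the study
conditions the tests assume:

- **Expression**: 150 samples, 500 genes, three ICR groups in equal
  proportions; signature genes shifted by 3 log2 units per group step
  with Gaussian noise (sd 1) — log2-scale Gaussian noise matches the
  log2-normalized substrate the ICR score averages. Other genes are
  pure noise, so any recovered structure is the planted one.
- **Repertoires**: 500 clones, 20,000 templates. Clone weights follow a
  geometric (stick-breaking) law whose single skew parameter maps
  monotonically to clonality and is inverted by bisection; calibration
  targets the clonality of the expected counts including a one-template
  floor per clone, which keeps realized richness — and hence the
  entropy normalization — stable under multinomial sampling (realized
  clonality lands within ±0.05 of target). Group targets 0.08 / 0.18 /
  0.30 for ICR Low/Medium/High mirror the positive association between
  immune activity and clonal expansion. Tumor and normal share a
  rank-aligned background pool, bounding background fold-ratios well
  below 32, so planted spiked clones (deterministic counts at 0.5%
  tumor frequency, 64× the normal) are exactly the tumor-enriched set.
- **Mutations/neoantigens**: a two-component log-normal mixture for the
  nonsynonymous count (25% hypermutated, drawn above the 12/Mb class
  boundary; draws below the expected-neoantigen zero crossing are
  rejected), observed neoantigens E(x)·m + Gaussian noise (sd 0.75)
  with m = 0.5 for the edited half of the cohort. Recovery experiments
  binarize at 0.75, the midpoint between the null ratio 1 and the
  planted edited ratio 0.5: non-edited samples sit *on* the default
  cutoff of 1 by construction, so the midpoint is the right probe of
  whether editing is recoverable (the analysis default stays 1).
- **Microbiome/survival**: Dirichlet compositions with designated risk
  and protective taxa (3 + 2 among 100) given common-genus
  concentrations so they pass the prevalence filter, perturbed per
  sample on the log scale. The proportional-hazards linear predictor is
  linear in the cohort-standardized abundances of the designated taxa
  (±0.8 per SD) plus ICR level (−0.35 per step) and editing status
  (−0.35) — i.e. the planted truth lives in exactly the feature space a
  standardized-abundance Cox model sees. Event times are exponential
  (median 5 years at the null predictor); censoring is independent
  Uniform(0, b) with b calibrated by root-finding so the expected
  censored fraction equals the target (default 0.55, matching a cohort
  with roughly 154 events among 348 patients). The MBR recovery
  experiments use 246 samples, a realistic 16S training-cohort size.

**What passing tests show — and what they don't.** The generator's
groups are well-separated Gaussians, its compositional noise is
Dirichlet, its hazards are exactly proportional and its censoring
independent. Real cohorts have batch effects, zero-inflated and
phylogenetically structured microbiomes, non-proportional hazards and
informative missingness, none of which are emulated. Recovery results
(clustering ARI ≥ 0.9, ≥ 4/5 prognostic taxa with correct signs,
GIE-flag accuracy ≥ 90%) therefore validate the *implementations* under
their stated assumptions; they are not effect-size claims about
patient data.

## Numerical choices and degenerate inputs

- Entropy in bits for TCR metrics, natural log for ecology diversity;
  both documented at the function level.
- Consensus matrices are exact ratios of co-cluster to co-sample
  counts; a pair never co-sampled raises an error suggesting more
  repeats rather than imputing.
- Bisection tolerances: clone-skew calibration 1e-9 on the skew;
  censoring calibration 1e-9 via `uniroot`.
- All-zero samples, S < 2 repertoires, non-positive survival times,
  empty classifiers, degenerate (point-mass) target densities and
  non-overlapping taxa sets raise immediate, named errors.
- Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; a fixed configuration reproduces byte-identical
  written bundles.

## Known limitations

- Consensus clustering stores one n × n consensus matrix per k; for
  cohorts beyond a few thousand samples memory becomes the binding
  constraint.
- `harrell_c()` is an O(n²) pair enumeration — exact and fine for
  cohorts of hundreds, deliberately not the O(n log n) algorithm.
- The MBR trainer assumes right-censored overall survival with
  exponential-family hazards; competing risks and time-varying effects
  are out of scope.
- CMS calling, gene-set curation, variant calling, HLA typing and OTU
  denoising are upstream of the package: it consumes their tabular
  outputs.
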