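---
title: "Metabolic subtyping of tumor and stroma compartments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic subtyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the models behind
each stage, the parameters that matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where the methodology was genuinely open.

## The analysis in one paragraph

Imaging mass spectrometry (IMS) of tissue-microarray cores yields a mass
spectrum per pixel. Co-registered immunofluorescence (pan-cytokeratin for
tumor epithelium, vimentin for stroma) labels each pixel's compartment;
pixel spectra are RMS-normalized and averaged into one metabolite profile
per patient and compartment. Resampling consensus clustering of those
profiles — run separately for tumor and stroma — identifies metabolic
subtypes and selects their number by the CDF delta-area rule. The subtypes
are then characterized against immunomarkers, clinicopathological variables
and survival, described by metabolite correlation networks with pathway
over-representation, and transferred to an independent chemotherapy-treated
cohort through a nearest-centroid classifier.

## Annotation model

**Co-registration.** Fluorescence images arrive at higher resolution than
the MALDI grid. We downscale by *block-mean pooling*: each grid pixel's
channel value is the exact area-weighted mean of the image region mapped
onto it (proportional-area weights handle non-integer scale factors). Mean
pooling was chosen over interpolation because it is exactly linear,
conserves the global mean, and has a closed-form oracle for testing.

**Positivity thresholds.** The compartment rule is: pan-cytokeratin
positive → tumor; otherwise vimentin positive → stroma; otherwise
unassigned. Published workflows rarely state their channel thresholds, so
the default is Otsu's between-class-variance threshold computed per channel
per core, with fixed numeric overrides available. The rule is total: every
pixel receives exactly one label, so tumor ∧ stroma is impossible by
construction.

**Normalization and aggregation.** Each pixel spectrum is divided by its
root mean square (√mean(x²)), making every spectrum RMS 1; all-zero pixels
cannot be normalized and are dropped with a message. Compartment profiles
are plain means over member pixels. A compartment with fewer than
`min_pixels` (default 10) labeled pixels is omitted — an explicit
region-exclusion rule; cohorts routinely keep fewer stroma than tumor
regions for exactly this reason. When a patient contributes multiple cores,
core profiles are averaged with equal weight (a declared simplification;
the generator emits one core per patient).

**Peak annotation.** Observed m/z values are matched against deprotonated
monoisotopic masses ([M−H]⁻ = mass − 1.007276 Da; negative-ion mode) within
`tol_ppm` (default 5 ppm). All matches within tolerance are kept, ordered
by absolute ppm error; the adduct list is configurable.

## Consensus clustering

This is the package's central computation and is implemented in full.

* **Base clusterer:** agglomerative hierarchical clustering with average
  linkage on the distance d(i,j) = 1 − Pearson correlation of the two
  samples' metabolite vectors. Distance and linkage are not dictated by the
  methodology itself, so they are documented defaults (the conventional
  choices for expression-style consensus clustering) and pluggable in
  principle. Constant (zero-variance) samples have undefined correlation;
  their distance to everything is defined as 1 and logged.
* **Resampling:** for each K in `k_range` (default 2..10), `iters`
  iterations (default 1000) of uniform subsampling without replacement at
  `fraction` = 0.8; the consensus matrix entry M(i,j) is the fraction of
  iterations in which i and j co-clustered among those where both were
  drawn. Pairs never co-sampled (vanishingly rare at 1000 × 80%) get
  consensus 0 with a warning; the diagonal is 1.
* **K selection:** A(K) is the exact integral over [0, 1] of the empirical
  CDF of M's upper-triangle values. Δ(2) = A(2) and
  Δ(K) = (A(K) − A(K−1))/A(K−1); K\* is the *largest* K with Δ(K) ≥ τ.
  The original methodology picks K from the delta-area plot by eye
  ("the relative increase becomes noticeably smaller"); automation needs an
  explicit rule, so τ = 0.1 is the default and a manual override
  (`k_override`) reproduces the by-eye workflow. If no K reaches τ the rule
  falls back to K = 2 with a warning.
* **Final labels:** average-linkage clustering of 1 − M cut at K\*,
  renumbered by descending cluster size (ties broken by lowest member
  index), giving the T1…/S1… convention where T1 is the largest tumor
  subtype. Subtype percentages are integerized by the largest-remainder
  method so that they always sum to 100; plain nearest-integer rounding can
  sum to 99 or 101 over four subtypes and does not reproduce standard
  published count arithmetic.
* **Separation:** since ordination plots are out of scope, subtype
  separation is quantified by the mean silhouette width under the same
  1 − Pearson distance (singleton clusters score 0) and by the adjusted
  Rand index against known labels where a ground truth exists.

## Association, survival, networks, transfer

**Subtype–marker correlation.** Each subtype is coded one-vs-rest (member
= 1) and Spearman-correlated with each marker score (mid-rank ties,
two-sided p from the t approximation); p-values are BH-adjusted across the
whole subtype × marker family of a compartment. Indicator coding is the
only reading under which a per-subtype *signed* correlation with a
continuous marker is defined. Both raw and adjusted p are reported, since
published correlation p-values are often reported unadjusted.

**Group tests.** Kruskal–Wallis (tie-corrected, chi-square p) with Dunn's
pairwise z statistics from pooled mid-ranks, BH-adjusted per marker.
Contingency tests use Fisher's exact test whenever any expected cell is
below 5 (the conventional rule), falling back to chi-square with a warning
if exact enumeration is infeasible for a large sparse table.

**Survival.** Kaplan–Meier product-limit curves; log-rank tests overall and
pairwise (pairwise p reported raw, matching the usual pairwise reporting
style, with a BH column alongside); Cox proportional-hazards models with
Efron tie handling. The default Cox mode fits one model per subtype
(indicator + UICC stage) because the published covariate coding of
multi-subtype models is usually ambiguous; a joint model with all
indicators (reference = largest subtype, stage I) is also available. Note a
property of one-vs-rest coding that matters when interpreting "null"
subtypes: if *any* subtype carries a real hazard effect, every other
indicator is non-null too, because its reference group is a mixture.

**Networks.** All metabolite pairs within one subtype's samples are
Spearman-correlated; edges are kept at BH-adjusted p < 0.001 (the stricter
of the two published filter readings; a raw-p mode exists) and isolated
metabolites are dropped. Pathway analysis is over-representation of the
network's node set: hits vs a hypergeometric null, enrichment ratio =
observed/expected hits, BH across pathways, with the cohort's annotated
metabolites as the background. The quantitative-enrichment tool used in the
original workflow is not fully specified; over-representation is our
explicit interpretation, not a claim of equivalence.

**Transfer.** The classifier is a transparent nearest-centroid model:
features z-scored on the training cohort, panel = top `panel_size`
(default 100) metabolites by Kruskal–Wallis H across subtypes, centroids =
per-subtype medians in z-space (robust to log-normal skew). New samples are
z-scored with the *training* means/SDs — never their own — and assigned to
the nearest centroid (ties to the smaller subtype index; below 80% panel
coverage is an error, moderate missingness is imputed at the training
median). The externally published machine-learning chemotherapy-response
classifier that motivates this stage is not reproducible from its
description; the centroid model is a clearly labeled substitute.

## The synthetic-data generator

The generator emulates the study conditions of a discovery cohort of 330
resected patients and a 40-patient NAC-treated cohort, with ground truth.

* **Subtypes.** Each patient gets a tumor subtype (uniform over
  `n_subtypes` = 4) and a stroma subtype coupled to it (tumor k → stroma
  k+1 mod K with probability `stroma_coupling` = 0.7, else uniform), so
  tumor subtype 1 preferentially co-occurs with stroma subtype 2.
* **Intensities.** Log-normal pixel intensities: log-intensity = baseline
  (per-metabolite N(3, 0.5)) + subtype shift + N(0, `noise_sd`). The first
  `frac_informative` (default 0.4) of metabolites split into one defining
  block per subtype; members of a patient's subtype block are shifted by
  `effect_size` × `noise_sd` (a standardized shift) in that compartment's
  pixels. Non-negativity of MS intensities is automatic on the exp scale.
* **Masks and images.** A fixed fraction `tumor_fraction` (default 0.6) of
  pixels is tumor; 5% of the remainder is unassigned. Channel images at
  twice the grid resolution have lightness ~N(0.9, 0.08) on positive and
  ~N(0.1, 0.08) on negative pixels (truncated at 0), so Otsu thresholds
  recover the mask almost perfectly.
* **Markers.** A Gaussian copula on the tumor-subtype indicator: latent =
  signed loading (rows of `marker_assoc`) + N(0, 1), pushed through
  monotone maps to each marker's native scale (log-normal for CD3/CD8,
  probit for PD-L1 % and γH2AX proportion). Monotone maps preserve Spearman
  signs exactly. The default pattern plants an immune-cold subtype 1
  (negative with all four markers), an immune-hot subtype 2, a neutral
  subtype 3 and a PD-L1/γH2AX-high subtype 4.
* **Survival.** Exponential times with baseline median 36 months and
  per-subtype hazard ratios (default 1.4, 1, 0.44, 1.3 — subtype 3
  protective); censoring is independent uniform on (0, c), with c solved
  numerically so the expected censored fraction equals `censor_rate`
  (default 0.3). Clinical covariates (stage, grade, sex, age, resection)
  are drawn from the margins of the emulated cohort's published patient
  table, independent of subtype.
* **NAC cohort.** Samples are drawn around the fitted classifier's
  centroids in z-space (noise `noise_sd`), mapped back to the raw scale. A
  latent resistance label is Bernoulli(`enrich_resistant` = 0.9) in the
  designated subtype and Bernoulli(`base_resistant` = 0.3) elsewhere. The
  *final* response label is the long-/short-term survivor split at the
  median underlying survival time. For that split to track the latent
  label, resistant hazards are multiplied by `response_hr` = 20: for
  exponential times the probability that a resistant patient outlives a
  sensitive one is 1/(1 + response_hr) < 5%. Subtype baseline hazards
  default to 1 inside the NAC generator — a prognostic subtype would
  otherwise leak into the median split and distort the planted response
  enrichment; plant one explicitly via `subtype_hr` when studying outcome
  models.

**What the generator does not emulate:** FT-ICR peak shapes, isotope
patterns and mass-measurement error; spatial autocorrelation within cores
(pixel noise is i.i.d.); multiple cores per patient; missing data;
batch/section effects; any dependence of clinical covariates on subtype.
Passing tests therefore demonstrate correctness of the *computations* under
a clean planted-signal model, not robustness to the messiness of real IMS
cohorts.

## Reproducibility and numerical choices

All randomness flows from one top-level seed through named substreams
(`substream_seed(seed, stage)`, a deterministic hash kept below 2³¹), so
partial reruns reproduce exactly and a fixed configuration is byte-identical
across runs. Other conventions: pixel coordinates are 0-based (row, col),
row-major, with imzML's 1-based (x, y) mapped as row = y − 1, col = x − 1;
the imzml-lite CSV dialect is long-format
`core_id,row,col,mz,intensity`, greppable and diff-friendly; consensus CDF
areas are exact step-function integrals (not sample-point Riemann sums over
observed values only); linkage tie-breaks are deterministic.

## Calibration of the exact tests

The suite checks null calibration of the stochastic components: BH-filtered
correlation networks keep false edges near α × #pairs under a complete
null; null Cox covariates reach ≈95% CI coverage; Spearman null p-values
are uniform. One caveat is intrinsic: Fisher's exact test on small 2×2
tables has a *discrete and conservative* null p-value distribution — its
p-values are stochastically larger than uniform, so "uniform null p" cannot
hold literally for any correct implementation. The meaningful calibration
property, and the one tested, is that the null distribution is never
anti-conservative (its empirical CDF never rises materially above the
uniform CDF, and the empirical type-I error stays at or below nominal).

## Problem sizes used by the test suite

Unit and property tests use compact cohorts (tens of patients, small pixel
grids) chosen so the whole suite runs in a few minutes while every check
retains power: recovery checks use 200–300 patients with 100 metabolites at
effect size 3 (where the delta-area rule and final labels are expected to
be essentially exact), null and coverage checks use 100–200 replicates, and
Cox recovery uses n = 2000 with a ±15% tolerance on planted hazard ratios.
The acceptance script simulates five 300-patient cohorts at 500 consensus
iterations each, which takes a few minutes on one CPU.

## Known limitations

* The delta-area threshold τ = 0.1 is a reasonable automation of a visual
  rule, not a universal constant; near-threshold cohorts warrant inspecting
  the per-K areas (stored in every `consensus_result`).
* One-vs-rest Cox and correlation codings are interpretable per subtype but
  not orthogonal across subtypes.
* The centroid classifier assumes the discovery z-space transfers to the
  new cohort; strong platform shifts would need renormalization upstream.
* imzML support covers continuous-mode, uncompressed float arrays — the
  common export for peak-picked IMS data — not processed-mode or compressed
  files.
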