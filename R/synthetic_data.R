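# Synthetic discovery and NAC-style cohorts with known ground truth.
# Emulates the study conditions of a tissue-microarray spatial-metabolomics
# cohort: planted metabolic subtypes per compartment (log-normal intensity
# model), immunofluorescence channels driving tumor/stroma masks, marker
# scores tied to the planted subtypes through a Gaussian copula, and
# subtype-dependent exponential survival hazards with independent uniform
# censoring.

#' Synthetic cohort configuration
#'
#' Defaults mirror the discovery cohort being emulated: 330 patients, four
#' metabolic subtypes, a 100-metabolite panel, and the marker-association /
#' hazard pattern of the published subtypes (subtype 1 immune-cold, subtype 2
#' immune-hot, subtype 3 protective with hazard ratio ~0.44, subtype 4
#' PD-L1-high).
#'
#' @param n_patients number of patients (one core per patient).
#' @param n_metabolites number of m/z channels / metabolites.
#' @param n_subtypes number of planted subtypes per compartment (>= 2).
#' @param effect_size standardized log-scale mean shift (in units of
#'   \code{noise_sd}) for each subtype-defining metabolite block.
#' @param frac_informative fraction of metabolites carrying subtype signal.
#' @param grid_shape pixels (rows, cols) per core.
#' @param tumor_fraction fraction of pixels that are pan-cytokeratin
#'   positive, in (0, 1).
#' @param noise_sd pixel-level log-intensity noise SD.
#' @param marker_assoc n_subtypes x 4 numeric matrix of signed copula
#'   loadings for CD3, CD8, PDL1, gH2AX (sign = target Spearman sign of the
#'   subtype-indicator association).
#' @param hazard_ratios per-subtype multiplicative hazards (length
#'   n_subtypes).
#' @param censor_rate target fraction of censored patients.
#' @param stroma_coupling probability that a patient's stroma subtype
#'   follows the planted tumor-to-stroma map (tumor k -> stroma k+1 mod K),
#'   so tumor subtype 1 couples to stroma subtype 2.
#' @param seed top-level integer seed; all stage substreams derive from it.
#' @return validated list of class \code{synth_config}.
#' @export
synth_config <- function(n_patients = 330, n_metabolites = 100,
                         n_subtypes = 4, effect_size = 3,
                         frac_informative = 0.4, grid_shape = c(12, 12),
                         tumor_fraction = 0.6, noise_sd = 1,
                         marker_assoc = NULL, hazard_ratios = NULL,
                         censor_rate = 0.3, stroma_coupling = 0.7,
                         seed = 1) {
  cfg <- list(n_patients = n_patients, n_metabolites = n_metabolites,
              n_subtypes = n_subtypes, effect_size = effect_size,
              frac_informative = frac_informative, grid_shape = grid_shape,
              tumor_fraction = tumor_fraction, noise_sd = noise_sd,
              marker_assoc = marker_assoc, hazard_ratios = hazard_ratios,
              censor_rate = censor_rate, stroma_coupling = stroma_coupling,
              seed = seed)
  if (is.null(cfg$marker_assoc)) {
    ma <- matrix(0, n_subtypes, 4, dimnames = list(NULL, MARKER_NAMES))
    ma[1, ] <- c(-1, -1, -1, -1)                 # immune-cold, low DNA damage
    if (n_subtypes >= 2) ma[2, ] <- c(1, 1, 1, 1) # immune-hot
    if (n_subtypes >= 4) ma[4, ] <- c(0, 0, 1, 1) # PD-L1-high
    cfg$marker_assoc <- ma
  }
  if (is.null(cfg$hazard_ratios)) {
    hr <- rep(1, n_subtypes)
    hr[1] <- 1.4
    if (n_subtypes >= 3) hr[3] <- 0.44
    if (n_subtypes >= 4) hr[4] <- 1.3
    cfg$hazard_ratios <- hr
  }
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  fail <- function(field, why) stop("invalid config field '", field, "': ", why)
  if (cfg$n_patients < 2) fail("n_patients", "need at least 2")
  if (cfg$n_metabolites < cfg$n_subtypes)
    fail("n_metabolites", "need at least one metabolite per subtype")
  if (cfg$n_subtypes < 2) fail("n_subtypes", "must be >= 2")
  if (cfg$effect_size < 0) fail("effect_size", "must be >= 0")
  if (cfg$frac_informative <= 0 || cfg$frac_informative > 1)
    fail("frac_informative", "must be in (0, 1]")
  if (length(cfg$grid_shape) != 2 || any(cfg$grid_shape < 2))
    fail("grid_shape", "must be two integers >= 2")
  if (cfg$tumor_fraction <= 0 || cfg$tumor_fraction >= 1)
    fail("tumor_fraction", "must be strictly between 0 and 1")
  if (cfg$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (!is.matrix(cfg$marker_assoc) ||
      nrow(cfg$marker_assoc) != cfg$n_subtypes || ncol(cfg$marker_assoc) != 4)
    fail("marker_assoc", "must be an n_subtypes x 4 matrix")
  if (length(cfg$hazard_ratios) != cfg$n_subtypes || any(cfg$hazard_ratios <= 0))
    fail("hazard_ratios", "must be n_subtypes positive values")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    fail("censor_rate", "must be in [0, 1)")
  if (cfg$stroma_coupling < 0 || cfg$stroma_coupling > 1)
    fail("stroma_coupling", "must be in [0, 1]")
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) fail("seed", "must be one integer")
  structure(cfg, class = "synth_config")
}

# informative metabolites split into one defining block per subtype
subtype_blocks <- function(cfg) {
  n_inf <- max(cfg$n_subtypes, round(cfg$frac_informative * cfg$n_metabolites))
  idx <- seq_len(n_inf)
  split(idx, rep(seq_len(cfg$n_subtypes), length.out = n_inf))
}

BASELINE_MEDIAN_MONTHS <- 36

#' Generate a synthetic discovery cohort
#'
#' One tissue core per patient. Tumor pixels carry the patient's tumor
#' subtype signal, stroma pixels the (coupled) stroma subtype signal, on a
#' log-normal intensity model: intensity = exp(baseline + shift + noise)
#' where shift = effect_size x noise_sd on the subtype's defining metabolite
#' block. Pan-cytokeratin / vimentin channel images at twice the grid
#' resolution drive the downstream annotation. Marker scores follow a
#' Gaussian copula on the tumor-subtype indicator; survival times are
#' exponential with per-subtype hazards and independent uniform censoring.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return \code{list(grids, if_images, patient_ids, markers, clinical,
#'   truth)}; \code{truth} holds the planted labels, informative blocks,
#'   hazard ratios and marker association signs.
#' @export
generate_discovery_cohort <- function(cfg) {
  cfg <- validate_synth_config(cfg)
  set.seed(substream_seed(cfg$seed, "discovery"))
  K <- cfg$n_subtypes; n <- cfg$n_patients; m <- cfg$n_metabolites
  blocks <- subtype_blocks(cfg)

  z_tumor <- sample.int(K, n, replace = TRUE)
  s_map <- c(seq_len(K)[-1], 1)  # tumor k -> stroma k+1 (mod K): 1 couples to 2
  follow <- stats::runif(n) < cfg$stroma_coupling
  z_stroma <- ifelse(follow, s_map[z_tumor], sample.int(K, n, replace = TRUE))

  mz <- sort(100 + 700 * stats::runif(m))  # plausible metabolite m/z range (Da)
  mu <- stats::rnorm(m, mean = 3, sd = 0.5)
  shift <- cfg$effect_size * cfg$noise_sd

  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  npix <- nr * nc
  n_tum <- round(cfg$tumor_fraction * npix)
  pid <- sprintf("P%03d", seq_len(n))

  grids <- vector("list", n); if_images <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- rep("stroma", npix)
    lab[sample.int(npix, n_tum)] <- "tumor"
    non_tum <- which(lab == "stroma")
    lab[sample(non_tum, round(0.05 * length(non_tum)))] <- "unassigned"

    logint <- matrix(stats::rnorm(npix * m, sd = cfg$noise_sd), npix, m)
    logint <- sweep(logint, 2, mu, "+")
    tum_px <- lab == "tumor"; str_px <- lab == "stroma"
    logint[tum_px, blocks[[z_tumor[i]]]] <-
      logint[tum_px, blocks[[z_tumor[i]]]] + shift
    logint[str_px, blocks[[z_stroma[i]]]] <-
      logint[str_px, blocks[[z_stroma[i]]]] + shift
    coords <- cbind(rep(seq_len(nr) - 1L, each = nc),
                    rep(seq_len(nc) - 1L, times = nr))
    grids[[i]] <- pixel_grid(pid[i], coords, mz, exp(logint))

    hi <- function(on) {
      base <- ifelse(on, 0.9, 0.1)
      img <- matrix(0, 2 * nr, 2 * nc)
      for (dr in 0:1) for (dc in 0:1) {
        v <- base + stats::rnorm(npix, sd = 0.08)
        img[cbind(2 * coords[, 1] + 1L + dr, 2 * coords[, 2] + 1L + dc)] <- pmax(v, 0)
      }
      img
    }
    if_images[[i]] <- list(
      panCK = fluor_image(pid[i], "panCK", hi(lab == "tumor")),
      vimentin = fluor_image(pid[i], "vimentin", hi(lab == "stroma")))
  }

  markers <- generate_markers(pid, z_tumor, cfg$marker_assoc)
  clinical <- generate_clinical(pid, z_tumor, cfg)
  truth <- list(z_tumor = z_tumor, z_stroma = z_stroma,
                informative = unlist(blocks, use.names = FALSE),
                blocks = blocks, hazard_ratios = cfg$hazard_ratios,
                marker_assoc = cfg$marker_assoc, mz = mz,
                patient_ids = pid)
  list(grids = grids, if_images = if_images, patient_ids = pid,
       markers = markers, clinical = clinical, truth = truth)
}

generate_markers <- function(pid, z, marker_assoc) {
  n <- length(pid)
  latent <- matrix(stats::rnorm(n * 4), n, 4) + marker_assoc[z, , drop = FALSE]
  # monotone maps from the latent Gaussian to each marker's native scale;
  # Spearman signs are preserved exactly
  validate_markers(data.frame(
    patient_id = pid,
    CD3 = exp(4 + 0.8 * latent[, 1]),
    CD8 = exp(3.5 + 0.8 * latent[, 2]),
    PDL1 = 100 * stats::pnorm(latent[, 3]),
    gH2AX = stats::pnorm(latent[, 4]),
    stringsAsFactors = FALSE))
}

# solve the uniform censoring horizon so that the expected censored fraction
# over the subtype mixture matches the target
censor_horizon <- function(rates, probs, target) {
  if (target <= 0) return(Inf)
  # P(C < T) for T ~ Exp(rate), C ~ U(0, cmax): (1 - exp(-rate*cmax))/(rate*cmax)
  cens_frac <- function(cmax) {
    sum(probs * (1 - exp(-rates * cmax)) / (rates * cmax))
  }
  stats::uniroot(function(cm) cens_frac(cm) - target,
                 lower = 1e-6, upper = 1e6, tol = 1e-8)$root
}

generate_clinical <- function(pid, z, cfg) {
  n <- length(pid)
  lambda0 <- log(2) / BASELINE_MEDIAN_MONTHS
  rates <- lambda0 * cfg$hazard_ratios[z]
  t_event <- stats::rexp(n, rate = rates)
  mix <- as.numeric(table(factor(z, levels = seq_len(cfg$n_subtypes)))) / n
  cmax <- censor_horizon(lambda0 * cfg$hazard_ratios, mix, cfg$censor_rate)
  t_cens <- if (is.finite(cmax)) stats::runif(n, 0, cmax) else rep(Inf, n)
  time <- pmax(pmin(t_event, t_cens), 1e-3)
  event <- as.integer(t_event <= t_cens)
  # covariate margins follow the published cohort table; independent of subtype
  samp <- function(levels, counts) sample(levels, n, replace = TRUE,
                                          prob = counts / sum(counts))
  validate_clinical(data.frame(
    patient_id = pid, time = time, event = event,
    uicc = samp(UICC_LEVELS, c(98, 113, 110, 9)),
    pT = samp(PT_LEVELS, c(72, 157, 75, 26)),
    pN = samp(PN_LEVELS, c(187, 105, 38)),
    M = samp(M_LEVELS, c(321, 9)),
    grade = samp(GRADE_LEVELS, c(6, 163, 161)),
    sex = samp(SEX_LEVELS, c(281, 49)),
    age = pmin(pmax(round(stats::rnorm(n, 69, 8)), 43), 85),
    resection = samp(RESEC_LEVELS, c(287, 40, 3)),
    stringsAsFactors = FALSE))
}

#' Generate a synthetic chemotherapy-treated (NAC-style) cohort
#'
#' Samples are drawn around the fitted classifier's subtype centroids (back
#' on the raw intensity scale via the stored training means/SDs). A latent
#' chemotherapy-resistance label is enriched in the designated subtype;
#' survival times are exponential with a strong resistance hazard multiplier
#' so that the final response label - the long-/short-term survivor split at
#' the median observed survival - tracks the latent label.
#'
#' @param cfg a \code{\link{synth_config}} (n_patients gives the cohort
#'   size; noise_sd the z-space noise around centroids; hazard_ratios the
#'   subtype hazards).
#' @param classifier a fitted \code{centroid_classifier}.
#' @param resistant_subtype subtype label enriched for resistance; must be
#'   one of the classifier's subtypes.
#' @param enrich_resistant latent resistance probability in the designated
#'   subtype (default 0.9).
#' @param base_resistant latent resistance probability elsewhere (default
#'   0.3).
#' @param response_hr hazard multiplier for latent-resistant patients.
#'   The default 20 keeps the median-survival split faithful to the latent
#'   label: for exponential times the probability that a resistant patient
#'   outlives a sensitive one is 1/(1 + response_hr), i.e. under 5%.
#' @param subtype_hr per-subtype baseline hazard multipliers (default all 1,
#'   so that survival — and hence the median-split response label — is
#'   driven by the latent resistance status alone; set explicitly to plant a
#'   prognostic subtype).
#' @return \code{list(cohort, clinical, truth)} where \code{cohort} is a
#'   \code{cohort_matrix} over the classifier panel.
#' @export
generate_nac_cohort <- function(cfg, classifier, resistant_subtype,
                                enrich_resistant = 0.9, base_resistant = 0.3,
                                response_hr = 20, subtype_hr = NULL) {
  cfg <- validate_synth_config(cfg)
  if (!inherits(classifier, "centroid_classifier")) stop("classifier must be fitted")
  if (!resistant_subtype %in% classifier$subtypes)
    stop("unknown resistant_subtype '", resistant_subtype, "'; classifier has: ",
         paste(classifier$subtypes, collapse = ", "))
  set.seed(substream_seed(cfg$seed, "nac"))
  n <- cfg$n_patients
  K <- length(classifier$subtypes)
  z <- sample.int(K, n, replace = TRUE)
  panel <- classifier$panel
  zs <- classifier$centroids[z, , drop = FALSE] +
    matrix(stats::rnorm(n * length(panel), sd = cfg$noise_sd), n)
  raw <- sweep(sweep(zs, 2, classifier$sd[panel], "*"), 2,
               classifier$mean[panel], "+")
  raw <- pmax(raw, 0)
  pid <- sprintf("N%03d", seq_len(n))
  rownames(raw) <- pid
  cohort <- cohort_matrix(raw, classifier$compartment %||% "stroma",
                          pid, metabolite_ids = panel)

  latent_resistant <- stats::rbinom(n, 1,
    ifelse(classifier$subtypes[z] == resistant_subtype,
           enrich_resistant, base_resistant))
  if (is.null(subtype_hr)) subtype_hr <- rep(1, K)
  if (length(subtype_hr) != K || any(subtype_hr <= 0))
    stop("invalid config field 'subtype_hr': must be ", K, " positive values")
  lambda0 <- log(2) / BASELINE_MEDIAN_MONTHS
  rates <- lambda0 * subtype_hr[z] * response_hr^latent_resistant
  t_event <- stats::rexp(n, rate = rates)
  cmax <- censor_horizon(unique(rates), as.numeric(prop.table(table(rates))),
                         cfg$censor_rate)
  t_cens <- if (is.finite(cmax)) stats::runif(n, 0, cmax) else rep(Inf, n)
  time <- pmax(pmin(t_event, t_cens), 1e-3)
  event <- as.integer(t_event <= t_cens)
  # long-/short-term survivor split at the median of the underlying survival
  # time (the generator knows it; censoring only affects the observed columns)
  response <- ifelse(t_event < stats::median(t_event), "resistant", "sensitive")
  mpr <- stats::rbinom(n, 1, ifelse(response == "sensitive", 0.5, 0.1))
  clinical <- generate_clinical(pid, pmin(z, cfg$n_subtypes), cfg)
  clinical$time <- time; clinical$event <- event
  clinical$response <- response; clinical$mpr <- mpr
  clinical <- validate_clinical(clinical)
  truth <- list(z = z, subtype = classifier$subtypes[z],
                latent_resistant = latent_resistant,
                resistant_subtype = resistant_subtype,
                enrich_resistant = enrich_resistant,
                base_resistant = base_resistant)
  list(cohort = cohort, clinical = clinical, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Write ground truth as JSON
#'
#' @param truth truth list from a generator.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
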