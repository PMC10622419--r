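# End-to-end orchestration: synthetic cohort (or pre-built inputs) ->
# annotation -> per-compartment consensus clustering -> associations ->
# survival -> networks/enrichment -> classifier transfer. Every stage writes
# its artifact under outdir; the returned report only re-reads those
# artifacts' numbers.

#' Build a synthetic pathway catalog over a metabolite namespace
#'
#' Random overlapping member sets — a stand-in for a curated
#' pathway-to-metabolite catalog, used so enrichment is runnable without
#' external databases.
#'
#' @param metabolite_ids metabolite namespace.
#' @param n_pathways number of pathways.
#' @param mean_size mean pathway size.
#' @param seed RNG seed.
#' @return named list of \code{list(name, members)}.
#' @export
synth_pathway_catalog <- function(metabolite_ids, n_pathways = 8,
                                  mean_size = 12, seed = 1) {
  set.seed(substream_seed(seed, "catalog"))
  out <- lapply(seq_len(n_pathways), function(i) {
    size <- max(3, stats::rpois(1, mean_size))
    list(name = sprintf("synthetic pathway %02d", i),
         members = sample(metabolite_ids, min(size, length(metabolite_ids))))
  })
  names(out) <- sprintf("PW%02d", seq_len(n_pathways))
  out
}

default_run_config <- function() {
  list(seed = 1, outdir = tempfile("msub_run_"),
       synth = list(), min_pixels = 10,
       k_range = 2:10, fraction = 0.8, iters = 1000, tau = 0.1,
       network_alpha = 0.001, panel_size = 100,
       resistant_subtype = "S2", nac_n = 40)
}

#' Run the full subtyping pipeline on a synthetic cohort
#'
#' Executes: simulate -> annotate/aggregate -> consensus cluster (tumor and
#' stroma separately) -> marker/clinicopathological associations -> survival
#' models -> per-subtype correlation networks and pathway enrichment ->
#' centroid-classifier transfer to a simulated NAC-style cohort. Artifacts
#' (CSV/JSON) are written under \code{config$outdir}.
#'
#' @param config list (or path to a JSON file) overriding the defaults:
#'   \code{seed}, \code{outdir}, \code{synth} (arguments to
#'   \code{\link{synth_config}}), \code{min_pixels}, \code{k_range},
#'   \code{fraction}, \code{iters}, \code{tau}, \code{network_alpha},
#'   \code{panel_size}, \code{resistant_subtype}, \code{nac_n}.
#' @return a \code{run_report} list; see fields in the implementation's
#'   report assembly.
#' @export
run_all <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  scfg <- do.call(synth_config, utils::modifyList(list(seed = cfg$seed),
                                                  as.list(cfg$synth)))
  log_stage("simulate", "generating %d patients, %d metabolites",
            scfg$n_patients, scfg$n_metabolites)
  disc <- generate_discovery_cohort(scfg)
  write_markers(disc$markers, file.path(cfg$outdir, "markers.csv"))
  write_clinical(disc$clinical, file.path(cfg$outdir, "clinical.csv"))
  write_truth(disc$truth[c("z_tumor", "z_stroma", "informative",
                           "hazard_ratios", "patient_ids")],
              file.path(cfg$outdir, "truth.json"))

  log_stage("annotate", "building compartment cohort matrices (min_pixels = %d)",
            cfg$min_pixels)
  cohorts <- build_cohort(disc$grids, disc$if_images, disc$patient_ids,
                          min_pixels = cfg$min_pixels)

  results <- list(); assignments <- list()
  for (comp in names(cohorts)) {
    log_stage("cluster", "%s: %d samples, K in %d..%d, %d iterations", comp,
              nrow(cohorts[[comp]]$x), min(cfg$k_range), max(cfg$k_range),
              cfg$iters)
    res <- run_consensus(cohorts[[comp]], k_range = cfg$k_range,
                         fraction = cfg$fraction, iters = cfg$iters,
                         seed = substream_seed(cfg$seed, comp), tau = cfg$tau)
    results[[comp]] <- res
    assignments[[comp]] <- res$assignment
    utils::write.csv(res$assignment,
                     file.path(cfg$outdir, paste0("subtypes_", comp, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(list(k = res$k, areas = as.list(res$areas),
                              deltas = as.list(res$deltas)),
                         file.path(cfg$outdir, paste0("consensus_", comp, ".json")),
                         digits = NA, auto_unbox = TRUE)
  }
  if (is.null(cohorts$stroma))
    warning("no stroma regions survived aggregation; stroma branch skipped")

  log_stage("associate", "marker correlations and clinicopathological tests")
  assoc <- lapply(assignments, subtype_marker_correlation, markers = disc$markers)
  for (comp in names(assoc))
    utils::write.csv(assoc[[comp]],
                     file.path(cfg$outdir, paste0("marker_assoc_", comp, ".csv")),
                     row.names = FALSE)
  clin_tests <- lapply(assignments, clinicopath_tests, clinical = disc$clinical)
  crosstab <- if (length(assignments) == 2)
    crosstab_subtypes(assignments$tumor, assignments$stroma) else NULL
  if (!is.null(crosstab))
    utils::write.csv(as.data.frame.matrix(crosstab),
                     file.path(cfg$outdir, "crosstab.csv"))

  log_stage("survive", "KM / log-rank / Cox per compartment")
  surv <- lapply(assignments, subtype_survival, clinical = disc$clinical)
  for (comp in names(surv))
    utils::write.csv(surv[[comp]]$cox,
                     file.path(cfg$outdir, paste0("cox_", comp, ".csv")),
                     row.names = FALSE)

  log_stage("network", "per-subtype correlation networks + enrichment")
  catalog <- synth_pathway_catalog(cohorts[[1]]$metabolite_ids, seed = cfg$seed)
  write_gmt(catalog, file.path(cfg$outdir, "catalog.gmt"))
  networks <- list()
  for (comp in names(cohorts)) {
    background <- cohorts[[comp]]$metabolite_ids
    networks[[comp]] <- lapply(levels(assignments[[comp]]$subtype), function(s) {
      rows <- assignments[[comp]]$subtype == s
      if (sum(rows) < 5) return(NULL)
      nw <- subtype_correlation_network(cohorts[[comp]]$x[rows, , drop = FALSE],
                                        alpha = cfg$network_alpha)
      enr <- if (length(nw$nodes))
        quantitative_enrichment(nw$nodes, catalog, background) else NULL
      write_network(nw, file.path(cfg$outdir,
                                  paste0("network_", comp, "_", s, ".csv")))
      list(subtype = s, network = nw, enrichment = enr)
    })
  }

  transfer <- NULL
  if (!is.null(cohorts$stroma)) {
    log_stage("transfer", "centroid classifier -> NAC-style cohort (n = %d)",
              cfg$nac_n)
    clf <- fit_classifier(cohorts$stroma, assignments$stroma,
                          panel_size = min(cfg$panel_size,
                                           ncol(cohorts$stroma$x)))
    write_classifier(clf, file.path(cfg$outdir, "classifier.json"))
    resistant <- if (cfg$resistant_subtype %in% clf$subtypes)
      cfg$resistant_subtype else clf$subtypes[min(2, length(clf$subtypes))]
    nac_cfg <- validate_synth_config(utils::modifyList(
      unclass(scfg), list(n_patients = cfg$nac_n, noise_sd = 0.5)))
    nac <- generate_nac_cohort(nac_cfg, clf, resistant)
    nac_assign <- assign_subtype(clf, nac$cohort)
    resp <- response_association(nac_assign, nac$clinical)
    outcome <- nac_outcome_models(nac_assign, nac$clinical)
    utils::write.csv(resp$proportions,
                     file.path(cfg$outdir, "nac_response.csv"), row.names = FALSE)
    transfer <- list(classifier = clf, assignment = nac_assign,
                     response = resp, outcome = outcome,
                     truth = nac$truth)
  }

  report <- list(
    config = cfg,
    seed_manifest = list(top = cfg$seed,
                         stages = vapply(c("discovery", "tumor", "stroma", "nac"),
                                         function(s) substream_seed(cfg$seed, s),
                                         numeric(1))),
    n_patients = scfg$n_patients,
    regions = vapply(cohorts, function(co) nrow(co$x), integer(1)),
    k = vapply(results, `[[`, integer(1), "k"),
    subtype_sizes = lapply(assignments, assignment_summary),
    marker_associations = assoc,
    clinicopath = clin_tests,
    crosstab = crosstab,
    survival = surv,
    networks = networks,
    transfer = transfer,
    truth = disc$truth)
  class(report) <- "run_report"
  jsonlite::write_json(list(k = as.list(report$k),
                            regions = as.list(report$regions),
                            subtype_sizes = report$subtype_sizes),
                       file.path(cfg$outdir, "report.json"),
                       digits = NA, auto_unbox = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n  patients:", x$n_patients, "\n")
  for (comp in names(x$regions))
    cat(sprintf("  %s: %d regions, K* = %d\n", comp, x$regions[[comp]],
                x$k[[comp]]))
  invisible(x)
}
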