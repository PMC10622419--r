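# Transfer of discovery subtypes to an independent cohort via a transparent
# nearest-centroid classifier over a discriminative metabolite panel, plus
# chemotherapy-response association and outcome models.

#' Fit a nearest-centroid subtype classifier
#'
#' Features are z-scored on the training cohort; the panel is the top
#' \code{panel_size} metabolites ranked by Kruskal-Wallis H across subtypes;
#' centroids are the per-subtype medians in z-space (robust to the skew of
#' log-normal intensities).
#'
#' @param cohort \code{\link{cohort_matrix}} or samples x metabolites matrix.
#' @param assignment data.frame \code{(sample_id, subtype)} aligned to the
#'   cohort rows.
#' @param panel_size number of panel metabolites (default 100; capped at the
#'   number available with a warning).
#' @return object of class \code{centroid_classifier}: panel ids, per-subtype
#'   centroid matrix, training means/SDs for the panel, compartment.
#' @export
fit_classifier <- function(cohort, assignment, panel_size = 100) {
  x <- if (inherits(cohort, "cohort_matrix")) cohort$x else as.matrix(cohort)
  compartment <- if (inherits(cohort, "cohort_matrix")) cohort$compartment else NA
  subtype <- factor(assignment$subtype)
  if (nlevels(subtype) < 2) stop("need at least 2 subtypes")
  if (any(table(subtype) < 3)) stop("every subtype needs at least 3 training samples")
  if (is.null(colnames(x))) colnames(x) <- paste0("met_", seq_len(ncol(x)))
  if (panel_size > ncol(x)) {
    warning("panel_size capped at ", ncol(x), " available metabolites")
    panel_size <- ncol(x)
  }
  H <- apply(x, 2, function(v)
    if (length(unique(v)) == 1) 0
    else unname(stats::kruskal.test(v, subtype)$statistic))
  panel <- colnames(x)[order(-H)[seq_len(panel_size)]]
  mu <- colMeans(x[, panel, drop = FALSE])
  sdv <- apply(x[, panel, drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- scale(x[, panel, drop = FALSE], center = mu, scale = sdv)
  centroids <- do.call(rbind, lapply(levels(subtype), function(s)
    apply(z[subtype == s, , drop = FALSE], 2, stats::median)))
  rownames(centroids) <- levels(subtype)
  if (any(stats::dist(centroids) < 1e-12))
    stop("two subtypes have identical centroids; classifier is degenerate")
  structure(list(panel = panel, centroids = centroids, mean = mu, sd = sdv,
                 compartment = compartment, subtypes = levels(subtype)),
            class = "centroid_classifier")
}

#' Assign a sample (or cohort) to the nearest subtype centroid
#'
#' Samples are z-scored with the *training* means/SDs (no leakage), then
#' assigned to the closest centroid by Euclidean distance. Missing panel
#' features are imputed at the training median (z = centroid-free 0... the
#' training median in z-space) when at least 80% of the panel is covered;
#' below that the sample is rejected. Distance ties go to the
#' smaller subtype index.
#'
#' @param classifier a \code{centroid_classifier}.
#' @param profile named numeric vector for one sample, or a matrix /
#'   \code{cohort_matrix} with metabolite columns.
#' @return data.frame \code{(sample_id, subtype, distance)}.
#' @export
assign_subtype <- function(classifier, profile) {
  x <- if (inherits(profile, "cohort_matrix")) profile$x
       else if (is.matrix(profile) || is.data.frame(profile)) as.matrix(profile)
       else matrix(profile, nrow = 1, dimnames = list("sample1", names(profile)))
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  panel <- classifier$panel
  covered <- intersect(panel, colnames(x))
  coverage <- length(covered) / length(panel)
  if (coverage < 0.8)
    stop(sprintf("sample covers only %.0f%% of the classifier panel (need >= 80%%)",
                 100 * coverage))
  if (coverage < 1)
    message(length(panel) - length(covered),
            " missing panel feature(s) imputed at the training median")
  z <- matrix(0, nrow(x), length(panel), dimnames = list(rownames(x), panel))
  z[, covered] <- sweep(sweep(x[, covered, drop = FALSE], 2,
                              classifier$mean[covered]), 2,
                        classifier$sd[covered], "/")
  # missing features stay at z = 0, the training median in z-space
  ctr <- classifier$centroids
  d2 <- outer(rowSums(z^2), rep(1, nrow(ctr))) - 2 * z %*% t(ctr) +
    outer(rep(1, nrow(z)), rowSums(ctr^2))
  d2 <- pmax(d2, 0)
  best <- apply(d2, 1, which.min)  # which.min takes the first (lowest index) on ties
  data.frame(sample_id = rownames(x),
             subtype = factor(rownames(ctr)[best], levels = rownames(ctr)),
             distance = sqrt(d2[cbind(seq_len(nrow(z)), best)]),
             stringsAsFactors = FALSE)
}

#' Serialize / load a centroid classifier as JSON
#'
#' @param classifier a \code{centroid_classifier}.
#' @param path file path.
#' @return \code{read_classifier} returns the classifier.
#' @export
write_classifier <- function(classifier, path) {
  jsonlite::write_json(list(panel = classifier$panel,
                            centroids = as.data.frame(classifier$centroids),
                            subtypes = classifier$subtypes,
                            mean = classifier$mean, sd = classifier$sd,
                            compartment = classifier$compartment),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctr <- as.matrix(j$centroids)
  rownames(ctr) <- j$subtypes
  colnames(ctr) <- j$panel
  structure(list(panel = j$panel, centroids = ctr,
                 mean = stats::setNames(as.numeric(j$mean), j$panel),
                 sd = stats::setNames(as.numeric(j$sd), j$panel),
                 compartment = j$compartment, subtypes = j$subtypes),
            class = "centroid_classifier")
}

#' Chemotherapy-response association of assigned subtypes
#'
#' Per-subtype resistant proportions and all pairwise two-sided Fisher exact
#' tests on the 2x2 resistant/sensitive tables, with a BH-adjusted column.
#' Subtypes with no assigned patients are excluded with a message.
#'
#' @param assignment data.frame \code{(sample_id, subtype)}.
#' @param response character vector ("sensitive"/"resistant") aligned to the
#'   assignment rows, or a clinical table with \code{patient_id} and
#'   \code{response}.
#' @return \code{list(proportions, pairwise)}.
#' @export
response_association <- function(assignment, response) {
  if (is.data.frame(response))
    response <- response$response[match(assignment$sample_id, response$patient_id)]
  stopifnot(all(response %in% c("sensitive", "resistant")))
  subtype <- factor(assignment$subtype)
  empty <- levels(subtype)[table(subtype) == 0]
  if (length(empty)) {
    message("subtype(s) with no patients excluded: ", paste(empty, collapse = ", "))
    subtype <- droplevels(subtype)
  }
  if (nlevels(subtype) < 2) stop("need at least 2 assigned subtypes with responses")
  tab <- table(subtype, factor(response, levels = c("resistant", "sensitive")))
  prop <- data.frame(subtype = rownames(tab),
                     n = as.integer(rowSums(tab)),
                     resistant = as.integer(tab[, "resistant"]),
                     prop_resistant = as.numeric(tab[, "resistant"] / rowSums(tab)),
                     stringsAsFactors = FALSE)
  pr <- t(utils::combn(rownames(tab), 2))
  p <- apply(pr, 1, function(g)
    stats::fisher.test(tab[g, , drop = FALSE])$p.value)
  pairwise <- data.frame(group1 = pr[, 1], group2 = pr[, 2], p = p,
                         q = stats::p.adjust(p, method = "BH"),
                         stringsAsFactors = FALSE)
  list(proportions = prop, pairwise = pairwise)
}

#' Outcome models for the chemotherapy-treated cohort
#'
#' Pairwise log-rank tests between assigned subtypes and per-subtype
#' multivariate Cox models with subtype indicator + MPR + UICC stage
#' covariates. A missing MPR column is omitted with a warning.
#'
#' @param assignment data.frame \code{(sample_id, subtype)}.
#' @param clinical clinical table with \code{time}, \code{event},
#'   \code{uicc} and optionally \code{mpr}.
#' @return \code{list(logrank, pairwise, cox)}.
#' @export
nac_outcome_models <- function(assignment, clinical) {
  cl <- clinical[match(assignment$sample_id, clinical$patient_id), ]
  subtype <- factor(assignment$subtype)
  lr <- logrank(cl$time, cl$event, subtype)
  pw <- pairwise_logrank(cl$time, cl$event, subtype)
  has_mpr <- "mpr" %in% names(cl)
  if (!has_mpr) warning("clinical table has no 'mpr' column; covariate omitted")
  stage <- factor(as.character(cl$uicc), levels = UICC_LEVELS)
  cox <- do.call(rbind, lapply(levels(subtype), function(s) {
    cov <- data.frame(subtype = as.numeric(subtype == s))
    if (has_mpr) cov$mpr <- cl$mpr
    cov$uicc <- droplevels(stage)
    res <- cox_fit(cov, cl$time, cl$event)
    res$term <- sub("^subtype$", s, res$term)
    res$model <- s
    res
  }))
  list(logrank = lr, pairwise = pw, cox = cox)
}
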