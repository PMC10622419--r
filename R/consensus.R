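# Resampling consensus clustering with CDF delta-area model selection.
# This is the pipeline's central computation and is implemented here in
# full rather than delegated: subsampling, base hierarchical clustering on
# 1 - Pearson distance, co-clustering tallies, consensus CDFs/areas and the
# delta-area K rule.

#' Draw a subsample of sample indices
#'
#' @param n_samples number of samples.
#' @param fraction subsampling fraction in (0, 1]; default 0.8.
#' @param k smallest cluster number the subsample must support.
#' @return integer vector of \code{floor(fraction * n_samples)} distinct
#'   indices, uniform without replacement, drawn from the current RNG stream.
#' @export
subsample <- function(n_samples, fraction = 0.8, k = 2) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  m <- floor(fraction * n_samples)
  if (m < k) stop("subsample of ", m, " samples cannot support K = ", k)
  sort(sample.int(n_samples, m))
}

#' Pearson-correlation distance between sample rows
#'
#' d(i, j) = 1 - Pearson correlation of the two samples' metabolite vectors.
#' A zero-variance (constant) sample has undefined correlation; its distance
#' to every other sample is defined as 1 and a message is emitted.
#'
#' @param x samples x features matrix.
#' @return \code{dist} object.
#' @export
pearson_dist <- function(x) {
  suppressWarnings(r <- stats::cor(t(x)))
  if (anyNA(r)) {
    message(sum(apply(x, 1, stats::sd) == 0),
            " zero-variance sample(s): correlation distance set to 1")
    r[is.na(r)] <- 0
  }
  d <- 1 - r
  diag(d) <- 0
  stats::as.dist(d)
}

#' Base clusterer: average-linkage hierarchical clustering
#'
#' Agglomerative clustering on 1 - Pearson distance, average linkage, tree
#' cut at \code{k} clusters.
#'
#' @param x samples x features matrix (a subsampled cohort).
#' @param k number of clusters.
#' @return integer cluster labels, length \code{nrow(x)}.
#' @export
base_cluster <- function(x, k) {
  if (nrow(x) < k) stop("need at least K = ", k, " samples, got ", nrow(x))
  stats::cutree(stats::hclust(pearson_dist(x), method = "average"), k = k)
}

#' Consensus matrix from logged resampling runs
#'
#' M(i, j) = (number of iterations in which i and j were assigned to the same
#' cluster) / (number of iterations in which both were subsampled). Pairs
#' never co-sampled get consensus 0 with a warning; the diagonal is forced
#' to 1.
#'
#' @param runs list of iterations, each \code{list(subset = indices,
#'   labels = cluster labels over the subset)}.
#' @param n_samples total number of samples.
#' @return symmetric \code{n_samples x n_samples} matrix in [0, 1].
#' @export
consensus_matrix <- function(runs, n_samples) {
  if (length(runs) == 0) stop("need at least one iteration")
  co <- matrix(0, n_samples, n_samples)
  both <- matrix(0, n_samples, n_samples)
  for (r in runs) {
    idx <- r$subset
    both[idx, idx] <- both[idx, idx] + 1
    same <- outer(r$labels, r$labels, "==")
    co[idx, idx] <- co[idx, idx] + same
  }
  never <- both == 0
  diag(never) <- FALSE
  if (any(never))
    warning(sum(never) / 2, " sample pair(s) never co-sampled; consensus set to 0")
  M <- ifelse(both > 0, co / pmax(both, 1), 0)
  diag(M) <- 1
  M
}

#' Empirical CDF of consensus values and its area
#'
#' The CDF is taken over the upper-triangle entries of the consensus matrix.
#' The area is the exact integral of the step CDF over [0, 1], i.e. the
#' left Riemann sum over the sorted unique consensus values.
#'
#' @param M consensus matrix.
#' @return \code{list(cdf = stepfun-like data.frame(value, cdf), area)}.
#' @export
consensus_cdf <- function(M) {
  v <- M[upper.tri(M)]
  vals <- sort(unique(v))
  cdf <- vapply(vals, function(t) mean(v <= t), numeric(1))
  # integrate the right-continuous step CDF over [0, 1]
  breaks <- unique(c(0, vals, 1))
  area <- 0
  for (i in seq_len(length(breaks) - 1)) {
    left <- breaks[i]
    height <- mean(v <= left)
    area <- area + height * (breaks[i + 1] - left)
  }
  list(cdf = data.frame(value = vals, cdf = cdf), area = area)
}

#' Select K by the delta-area rule
#'
#' Relative change in the area under the consensus CDF:
#' delta(2) = A(2); delta(K) = (A(K) - A(K-1)) / A(K-1) for K >= 3. The
#' chosen K* is the largest K whose relative gain still reaches \code{tau};
#' beyond K* the increase in area has become small. If no K reaches
#' \code{tau}, K* = 2 with a warning. A manual override short-circuits the
#' rule (mirrors choosing K from the delta-area plot by eye).
#'
#' @param areas named numeric vector of A(K), names = K values (ascending).
#' @param tau relative-gain threshold (default 0.1).
#' @param override optional integer K to force.
#' @return \code{list(k, deltas)} where \code{deltas} is named by K.
#' @export
select_k <- function(areas, tau = 0.1, override = NULL) {
  ks <- as.integer(names(areas))
  if (is.null(ks) || anyNA(ks)) stop("areas must be named by their K values")
  if (length(ks) < 3) stop("need at least 3 K values to select K")
  stopifnot(!is.unsorted(ks))
  deltas <- c(areas[1], diff(areas) / utils::head(areas, -1))
  names(deltas) <- ks
  if (!is.null(override)) {
    if (!override %in% ks) stop("override K = ", override, " not in K range")
    return(list(k = as.integer(override), deltas = deltas))
  }
  ok <- which(deltas >= tau)
  if (length(ok) == 0) {
    warning("no K reaches the delta-area threshold; falling back to K = 2")
    return(list(k = min(ks), deltas = deltas))
  }
  list(k = ks[max(ok)], deltas = deltas)
}

#' Final subtype labels from the consensus matrix
#'
#' Average-linkage hierarchical clustering on the distance 1 - M, cut at K*.
#' Clusters are renumbered by descending size (ties broken by the lowest
#' member index), matching the convention of naming the largest subtype 1.
#'
#' @param M consensus matrix.
#' @param k number of clusters.
#' @param sample_ids optional identifiers.
#' @param prefix label prefix, e.g. \code{"T"} for tumor or \code{"S"} for
#'   stroma; \code{""} gives bare integers.
#' @return data.frame \code{(sample_id, subtype)}; subtype is a factor with
#'   levels in size order.
#' @export
final_labels <- function(M, k, sample_ids = NULL, prefix = "") {
  n <- nrow(M)
  if (k > n) stop("K exceeds number of samples")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  d <- 1 - M
  diag(d) <- 0
  raw <- stats::cutree(stats::hclust(stats::as.dist(d), method = "average"), k = k)
  sizes <- table(raw)
  first_member <- vapply(names(sizes), function(cl) min(which(raw == as.integer(cl))),
                         numeric(1))
  ord <- order(-as.numeric(sizes), first_member)
  remap <- integer(length(sizes))
  remap[as.integer(names(sizes))[ord]] <- seq_along(ord)
  lv <- paste0(prefix, seq_len(k))
  data.frame(sample_id = as.character(sample_ids),
             subtype = factor(lv[remap[raw]], levels = lv),
             stringsAsFactors = FALSE)
}

#' Run resampling consensus clustering over a K range
#'
#' For each K in \code{k_range}: \code{iters} iterations of 80% subsampling
#' followed by average-linkage hierarchical clustering on 1 - Pearson
#' distance; co-clustering frequencies are tallied into a consensus matrix;
#' the CDF area per K feeds the delta-area rule which picks K*; final labels
#' come from clustering 1 - M at K*.
#'
#' @param cohort a \code{\link{cohort_matrix}} (or plain samples x features
#'   matrix).
#' @param k_range integer vector of candidate cluster numbers (default 2:10).
#' @param fraction subsampling fraction (default 0.8).
#' @param iters resampling iterations per K (default 1000).
#' @param seed integer seed for the run's RNG substream.
#' @param tau delta-area threshold (default 0.1).
#' @param k_override optional manual K.
#' @param keep_runs if TRUE, the per-iteration (subset, labels) logs are
#'   retained (used by the brute-force recount oracle).
#' @return object of class \code{consensus_result}: per-K consensus matrices,
#'   CDFs and areas, deltas, chosen \code{k}, final \code{assignment}.
#' @export
run_consensus <- function(cohort, k_range = 2:10, fraction = 0.8, iters = 1000,
                          seed = 1, tau = 0.1, k_override = NULL,
                          keep_runs = FALSE) {
  x <- if (inherits(cohort, "cohort_matrix")) cohort$x else as.matrix(cohort)
  sample_ids <- if (inherits(cohort, "cohort_matrix")) cohort$sample_ids
                else if (!is.null(rownames(x))) rownames(x)
                else paste0("s", seq_len(nrow(x)))
  compartment <- if (inherits(cohort, "cohort_matrix")) cohort$compartment else NA
  prefix <- if (identical(compartment, "tumor")) "T"
            else if (identical(compartment, "stroma")) "S" else ""
  n <- nrow(x)
  k_range <- sort(as.integer(k_range))
  set.seed(substream_seed(seed, "consensus"))

  # the full-cohort linkage tree is deterministic; precompute per-iteration
  # subsets once per K so different K values explore different resamples
  matrices <- list(); cdfs <- list(); areas <- numeric(length(k_range))
  run_log <- if (keep_runs) list() else NULL
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    runs <- vector("list", iters)
    for (it in seq_len(iters)) {
      idx <- subsample(n, fraction, k)
      lab <- base_cluster(x[idx, , drop = FALSE], k)
      runs[[it]] <- list(subset = idx, labels = lab)
    }
    M <- consensus_matrix(runs, n)
    cc <- consensus_cdf(M)
    matrices[[as.character(k)]] <- M
    cdfs[[as.character(k)]] <- cc$cdf
    areas[ki] <- cc$area
    if (keep_runs) run_log[[as.character(k)]] <- runs
  }
  names(areas) <- k_range
  sel <- select_k(areas, tau = tau, override = k_override)
  assignment <- final_labels(matrices[[as.character(sel$k)]], sel$k,
                             sample_ids, prefix = prefix)
  structure(list(k_range = k_range, matrices = matrices, cdfs = cdfs,
                 areas = areas, deltas = sel$deltas, k = sel$k,
                 assignment = assignment, compartment = compartment,
                 runs = run_log),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %s: K* = %d (K range %d..%d)\n",
              ifelse(is.na(x$compartment), "cohort", x$compartment),
              x$k, min(x$k_range), max(x$k_range)))
  print(assignment_summary(x$assignment))
  invisible(x)
}

#' Per-subtype counts and percentages
#'
#' Integer percentages are computed by the largest-remainder method so that
#' they always sum to 100 (plain nearest-integer rounding can sum to 99 or
#' 101 across four subtypes).
#'
#' @param assignment data.frame with a \code{subtype} column (or a vector of
#'   labels).
#' @return data.frame \code{(subtype, n, percent)}.
#' @export
assignment_summary <- function(assignment) {
  labels <- if (is.data.frame(assignment)) assignment$subtype else assignment
  if (length(labels) == 0) stop("empty assignment")
  n <- table(labels)
  pct <- largest_remainder_percent(as.numeric(n))
  data.frame(subtype = names(n), n = as.integer(n), percent = pct,
             stringsAsFactors = FALSE)
}

largest_remainder_percent <- function(counts) {
  raw <- counts / sum(counts) * 100
  fl <- floor(raw)
  short <- 100 - sum(fl)
  if (short > 0) {
    bump <- order(raw - fl, decreasing = TRUE)[seq_len(short)]
    fl[bump] <- fl[bump] + 1
  }
  as.integer(fl)
}

#' Mean silhouette width under correlation distance
#'
#' Separation score for a subtype assignment: mean silhouette over samples
#' with distance 1 - Pearson. Samples in singleton clusters get silhouette 0.
#'
#' @param cohort \code{\link{cohort_matrix}} or samples x features matrix.
#' @param assignment data.frame with \code{subtype}, ordered as the cohort
#'   rows (or a plain label vector).
#' @return scalar mean silhouette in [-1, 1].
#' @export
separation_score <- function(cohort, assignment) {
  x <- if (inherits(cohort, "cohort_matrix")) cohort$x else as.matrix(cohort)
  labels <- if (is.data.frame(assignment)) assignment$subtype else assignment
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 subtypes")
  d <- as.matrix(pearson_dist(x))
  n <- nrow(x)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { sil[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two clusterings (1 = identical
#' partitions, ~0 = independent). Thin wrapper kept as part of the package
#' surface so recovery checks read naturally.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
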