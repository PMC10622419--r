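# Subtype characterization: immunomarker correlations, marker group
# differences, clinicopathological contingency tests, and tumor-stroma
# subtype cross-tabulation.

#' Spearman correlation with mid-rank ties and t-approximation p-value
#'
#' rho is the Pearson correlation of the mid-ranks; the two-sided p-value
#' uses the t approximation t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees
#' of freedom.
#'
#' @param x,y numeric vectors.
#' @return \code{list(rho, p, n)}; \code{rho}/\code{p} are NA when either
#'   vector is constant.
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), df = n - 2), n = n)
}

#' Subtype-immunomarker Spearman correlations
#'
#' For each subtype a one-vs-rest membership indicator is correlated
#' (Spearman) with each marker score; p-values are Benjamini-Hochberg
#' adjusted across the whole subtype x marker family of the compartment.
#'
#' @param assignment data.frame \code{(sample_id, subtype)}; sample ids must
#'   be patient ids present in the marker table.
#' @param markers marker table (see \code{\link{validate_markers}}).
#' @param marker_cols marker columns to test (default CD3, CD8, PDL1,
#'   gH2AX).
#' @return data.frame \code{(subtype, marker, rho, p, q, n)}.
#' @export
subtype_marker_correlation <- function(assignment, markers,
                                       marker_cols = MARKER_NAMES) {
  markers <- validate_markers(markers)
  m <- markers[match(assignment$sample_id, markers$patient_id), ]
  if (all(is.na(m$patient_id))) stop("no assignment sample ids found in marker table")
  res <- expand.grid(subtype = levels(factor(assignment$subtype)),
                     marker = marker_cols, stringsAsFactors = FALSE)
  stats <- mapply(function(s, mk) {
    ind <- as.numeric(assignment$subtype == s)
    sr <- spearman_rho(ind, m[[mk]])
    c(sr$rho, sr$p, sr$n)
  }, res$subtype, res$marker)
  res$rho <- stats[1, ]; res$p <- stats[2, ]; res$n <- as.integer(stats[3, ])
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with chi-square p-value, then Dunn's
#' pairwise z statistics from pooled mid-ranks, Benjamini-Hochberg adjusted
#' across the pairs.
#'
#' @param values numeric vector.
#' @param groups grouping vector (same length).
#' @return \code{list(H, df, p, pairs)} where \code{pairs} is a data.frame
#'   \code{(group1, group2, z, p, q)}.
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(unique(values)) == 1) {
    gl <- levels(groups)
    pr <- t(utils::combn(gl, 2))
    pairs <- data.frame(group1 = pr[, 1], group2 = pr[, 2],
                        z = 0, p = 1, q = 1, stringsAsFactors = FALSE)
    return(list(H = 0, df = nlevels(groups) - 1, p = 1, pairs = pairs))
  }
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  gl <- levels(groups)
  pr <- t(utils::combn(gl, 2))
  z <- apply(pr, 1, function(g) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ng[g[1]] + 1 / ng[g[2]]))
    (rbar[g[1]] - rbar[g[2]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  pairs <- data.frame(group1 = pr[, 1], group2 = pr[, 2], z = as.numeric(z),
                      p = p, q = stats::p.adjust(p, method = "BH"),
                      stringsAsFactors = FALSE)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairs = pairs)
}

#' Subtype vs clinicopathological contingency tests
#'
#' For each categorical clinical column, tests independence from the subtype
#' assignment: Fisher's exact test when any expected cell count is below 5
#' (falling back to chi-square with a warning if exact enumeration is
#' infeasible for a large sparse table), otherwise the chi-square test.
#' Single-level columns are skipped with a message.
#'
#' @param assignment data.frame \code{(sample_id, subtype)}.
#' @param clinical clinical table; \code{sample_id} matched against
#'   \code{patient_id}.
#' @param columns clinical columns to test.
#' @return data.frame \code{(column, test, p)}.
#' @export
clinicopath_tests <- function(assignment, clinical,
                              columns = c("sex", "age_group", "resection",
                                          "grade", "uicc", "pT", "pN", "M")) {
  cl <- clinical[match(assignment$sample_id, clinical$patient_id), ]
  if (!"age_group" %in% names(cl) && "age" %in% names(cl))
    cl$age_group <- ifelse(cl$age >= stats::median(cl$age), "older", "younger")
  out <- list()
  for (col in intersect(columns, names(cl))) {
    v <- factor(as.character(cl[[col]]))
    if (nlevels(v) < 2) {
      message("column '", col, "' has a single level; skipped")
      next
    }
    tab <- table(assignment$subtype, v)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (any(dim(tab) < 2)) {
      message("column '", col, "' gives a degenerate table; skipped")
      next
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- tryCatch(stats::fisher.test(tab, workspace = 2e6)$p.value,
                    error = function(e) {
                      warning("Fisher enumeration infeasible for '", col,
                              "'; falling back to chi-square")
                      suppressWarnings(stats::chisq.test(tab)$p.value)
                    })
      test <- "fisher"
    } else {
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      test <- "chi-square"
    }
    out[[col]] <- data.frame(column = col, test = test, p = p,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cross-tabulate tumor and stroma subtypes
#'
#' Contingency table of co-membership over patients having both a tumor and
#' a stroma assignment.
#'
#' @param tumor_assign,stroma_assign data.frames \code{(sample_id, subtype)}.
#' @return contingency table (tumor subtypes x stroma subtypes).
#' @export
crosstab_subtypes <- function(tumor_assign, stroma_assign) {
  common <- intersect(tumor_assign$sample_id, stroma_assign$sample_id)
  if (length(common) == 0) stop("no patients with both tumor and stroma subtypes")
  t_lab <- tumor_assign$subtype[match(common, tumor_assign$sample_id)]
  s_lab <- stroma_assign$subtype[match(common, stroma_assign$sample_id)]
  table(tumor = t_lab, stroma = s_lab)
}
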