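# Per-subtype metabolite correlation networks and pathway
# over-representation of the networked metabolites.

#' Metabolite correlation network within one subtype
#'
#' All metabolite pairs are correlated (Spearman, mid-rank ties,
#' t-approximation p-values) across the subtype's samples; p-values are
#' BH-adjusted over all pairs and edges kept at adjusted p < alpha.
#' Metabolites without any significant edge are dropped from the node set.
#'
#' @param cohort \code{\link{cohort_matrix}} or samples x metabolites matrix,
#'   already restricted to one subtype's samples.
#' @param alpha adjusted-p edge threshold (default 0.001).
#' @param adjust \code{"BH"} (default) or \code{"none"} to filter on raw p.
#' @return \code{list(nodes, edges)}; \code{edges} is a data.frame
#'   \code{(metabolite1, metabolite2, rho, sign, p, q)}.
#' @export
subtype_correlation_network <- function(cohort, alpha = 0.001,
                                        adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  x <- if (inherits(cohort, "cohort_matrix")) cohort$x else as.matrix(cohort)
  n <- nrow(x); m <- ncol(x)
  if (n < 5) stop("need at least 5 samples for within-subtype correlation")
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("met_", seq_len(m))
  rk <- apply(x, 2, rank)
  r <- suppressWarnings(stats::cor(rk))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rho <- r[ut]
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[abs(rho) >= 1] <- 0
  p[is.na(rho)] <- NA
  q <- stats::p.adjust(p, method = "BH")
  crit <- if (adjust == "BH") q else p
  keep <- which(!is.na(crit) & crit < alpha)
  edges <- data.frame(metabolite1 = ids[ut[keep, 1]],
                      metabolite2 = ids[ut[keep, 2]],
                      rho = rho[keep],
                      sign = ifelse(rho[keep] >= 0, "positive", "negative"),
                      p = p[keep], q = q[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$q, -abs(edges$rho)), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = sort(unique(c(edges$metabolite1, edges$metabolite2))),
       edges = edges)
}

#' Pathway over-representation of network metabolites
#'
#' For each pathway: hits = number of network metabolites in the pathway's
#' member set; enrichment ratio = hits / expected hits where expected =
#' pathway size x |network| / |background|; p from the hypergeometric upper
#' tail; BH adjustment across pathways. Pathways with no member in the
#' background are skipped.
#'
#' @param network_metabolites character vector of metabolite ids (e.g. the
#'   node set of a \code{\link{subtype_correlation_network}}).
#' @param catalog pathway catalog: named list of
#'   \code{list(name, members)} (see \code{\link{read_gmt}}).
#' @param background character vector of all annotated metabolites in the
#'   cohort (the enrichment universe).
#' @return data.frame \code{(pathway, name, hits, set_size, ratio, p, q)}.
#' @export
quantitative_enrichment <- function(network_metabolites, catalog, background) {
  if (length(catalog) == 0) stop("empty pathway catalog")
  network_metabolites <- intersect(unique(network_metabolites), background)
  if (length(network_metabolites) == 0)
    stop("no annotated network metabolites in the background set")
  N <- length(unique(background))
  n <- length(network_metabolites)
  rows <- lapply(names(catalog), function(id) {
    members <- intersect(catalog[[id]]$members, background)
    K <- length(members)
    if (K == 0) return(NULL)
    hits <- length(intersect(network_metabolites, members))
    expected <- K * n / N
    p <- if (hits == 0) 1 else
      stats::phyper(hits - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = id, name = catalog[[id]]$name, hits = hits,
               set_size = K, ratio = if (hits == 0) 0 else hits / expected,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no pathway overlaps the background set")
  res$q <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), , drop = FALSE]
}

#' Write a correlation network as edge-list CSV and GraphML
#'
#' @param network result of \code{\link{subtype_correlation_network}}.
#' @param csv_path,graphml_path output paths (either may be NULL).
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, csv_path = NULL, graphml_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(network$edges, csv_path, row.names = FALSE)
  if (!is.null(graphml_path)) {
    esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
    nodes <- sprintf('<node id="%s"/>', esc(network$nodes))
    edges <- sprintf('<edge source="%s" target="%s"><data key="rho">%g</data><data key="sign">%s</data></edge>',
                     esc(network$edges$metabolite1), esc(network$edges$metabolite2),
                     network$edges$rho, network$edges$sign)
    xml <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
             '<key id="rho" for="edge" attr.name="rho" attr.type="double"/>',
             '<key id="sign" for="edge" attr.name="sign" attr.type="string"/>',
             '<graph edgedefault="undirected">', nodes, edges,
             '</graph></graphml>')
    writeLines(xml, graphml_path)
  }
  invisible(c(csv_path, graphml_path))
}
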