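#' RMS-normalize pixel spectra
#'
#' Divides each pixel spectrum by its root mean square
#' \eqn{\sqrt{\mathrm{mean}(x^2)}} so that every output spectrum has RMS 1.
#' All-zero pixels cannot be normalized; they are dropped from the grid with
#' a message (downstream they count as unassigned).
#'
#' @param grid a \code{\link{pixel_grid}}.
#' @return The normalized \code{pixel_grid} (possibly with fewer pixels).
#' @export
rms_normalize <- function(grid) {
  validate_pixel_grid(grid)
  rms <- sqrt(rowMeans(grid$intensities^2))
  zero <- rms == 0
  if (any(zero)) {
    message(sum(zero), " all-zero pixel(s) excluded from core '",
            grid$core_id, "' during RMS normalization")
    grid$coords <- grid$coords[!zero, , drop = FALSE]
    grid$intensities <- grid$intensities[!zero, , drop = FALSE]
    rms <- rms[!zero]
  }
  if (nrow(grid$intensities) == 0) stop("no nonzero pixels to normalize")
  grid$intensities <- grid$intensities / rms
  grid
}

#' Co-register a fluorescence image onto the IMS pixel grid
#'
#' Downscales a native-resolution lightness matrix to the MALDI grid by
#' block-mean pooling: each grid pixel's value is the mean of the image
#' block mapped onto it. Non-integer scale factors are handled by
#' proportional-area weighting, so the pooled mean is exact for any
#' resolution ratio >= 1.
#'
#' @param image a \code{\link{fluor_image}} or plain numeric matrix.
#' @param grid_shape integer (rows, cols) of the target IMS grid.
#' @return numeric matrix of dimension \code{grid_shape}.
#' @export
coregister <- function(image, grid_shape) {
  v <- if (inherits(image, "fluor_image")) image$values else as.matrix(image)
  if (length(v) == 0 || any(dim(v) == 0)) stop("zero-size image")
  gr <- as.integer(grid_shape[1]); gc <- as.integer(grid_shape[2])
  if (nrow(v) < gr || ncol(v) < gc)
    stop("image resolution (", nrow(v), "x", ncol(v),
         ") must be >= grid resolution (", gr, "x", gc, ") in both axes")
  pool_1d <- function(n_in, n_out) {
    # weight matrix W (n_out x n_in): proportional overlap of output cell i
    # with input cell j, rows summing to 1
    W <- matrix(0, n_out, n_in)
    step <- n_in / n_out
    for (i in seq_len(n_out)) {
      a <- (i - 1) * step; b <- i * step
      j0 <- floor(a) + 1; j1 <- ceiling(b)
      for (j in j0:min(j1, n_in)) {
        ov <- min(b, j) - max(a, j - 1)
        if (ov > 0) W[i, j] <- ov
      }
    }
    W / rowSums(W)
  }
  Wr <- pool_1d(nrow(v), gr)
  Wc <- pool_1d(ncol(v), gc)
  Wr %*% v %*% t(Wc)
}

#' Otsu threshold for a fluorescence channel
#'
#' Default positivity threshold when none is supplied: Otsu's
#' between-class-variance maximizer on the channel's lightness histogram.
#'
#' @param values numeric matrix or vector of lightness values.
#' @return scalar threshold on the lightness scale.
#' @export
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(EBImage::Image(as.matrix(values)), range = rng)
}

#' Label pixels as tumor, stroma or unassigned
#'
#' Applies the compartment rule: pixels positive for pan-cytokeratin are
#' tumor; pixels negative for pan-cytokeratin but positive for vimentin are
#' stroma; the rest are unassigned. Positivity means lightness >= threshold.
#'
#' @param panck,vimentin numeric matrices at grid resolution (same shape).
#' @param t_panck,t_vim positivity thresholds; default Otsu per channel.
#' @return character matrix of labels in
#'   \code{c("tumor", "stroma", "unassigned")} with class
#'   \code{annotation_mask}.
#' @export
annotate_pixels <- function(panck, vimentin,
                            t_panck = otsu_threshold(panck),
                            t_vim = otsu_threshold(vimentin)) {
  panck <- as.matrix(panck); vimentin <- as.matrix(vimentin)
  if (!identical(dim(panck), dim(vimentin)))
    stop("panCK and vimentin matrices must share shape")
  lab <- matrix("unassigned", nrow(panck), ncol(panck))
  lab[panck < t_panck & vimentin >= t_vim] <- "stroma"
  lab[panck >= t_panck] <- "tumor"
  class(lab) <- c("annotation_mask", class(lab))
  lab
}

#' Aggregate pixel spectra into per-compartment region profiles
#'
#' Means of (normalized) pixel intensities over all pixels of each
#' compartment. Compartments with fewer than \code{min_pixels} member pixels
#' are omitted (this is the explicit region-exclusion rule; cohorts routinely
#' lose some stroma regions this way).
#'
#' @param grid a \code{\link{pixel_grid}} (RMS-normalized upstream).
#' @param mask an \code{annotation_mask} matrix covering the grid coordinates.
#' @param min_pixels minimum member pixels per compartment (default 10).
#' @return list of region profiles, each
#'   \code{list(core_id, compartment, profile, n_pixels)}; empty list (with a
#'   warning) if no pixel is labeled.
#' @export
aggregate_profiles <- function(grid, mask, min_pixels = 10) {
  validate_pixel_grid(grid)
  labels <- mask[cbind(grid$coords[, 1] + 1L, grid$coords[, 2] + 1L)]
  out <- list()
  for (comp in c("tumor", "stroma")) {
    sel <- which(labels == comp)
    if (length(sel) == 0) next
    if (length(sel) < min_pixels) {
      message("core '", grid$core_id, "': ", comp, " region omitted (",
              length(sel), " < ", min_pixels, " pixels)")
      next
    }
    out[[comp]] <- list(core_id = grid$core_id, compartment = comp,
                        profile = colMeans(grid$intensities[sel, , drop = FALSE]),
                        n_pixels = length(sel))
  }
  if (length(out) == 0 && !any(labels %in% c("tumor", "stroma")))
    warning("core '", grid$core_id, "': no labeled pixels at all")
  unname(out)
}

#' Annotate m/z channels by accurate mass matching
#'
#' Matches observed m/z values against deprotonated monoisotopic masses
#' ([M-H]-, negative-ion mode: mass - 1.007276 Da) from a metabolite
#' reference within a ppm tolerance. All matches within tolerance are kept,
#' sorted by absolute ppm error.
#'
#' @param mz_channels numeric vector of observed m/z (Da).
#' @param ref data.frame with columns \code{id}, \code{name}, \code{mass}
#'   (monoisotopic, Da).
#' @param tol_ppm tolerance in parts per million (default 5).
#' @param adducts named numeric vector of adduct mass shifts; default the
#'   negative-mode deprotonated ion.
#' @return list, one element per channel, each a data.frame with columns
#'   \code{id}, \code{name}, \code{adduct}, \code{ppm_error} (possibly
#'   0-row).
#' @export
annotate_peaks <- function(mz_channels, ref, tol_ppm = 5,
                           adducts = c("[M-H]-" = -1.007276)) {
  if (tol_ppm < 0) stop("tol_ppm must be >= 0")
  if (is.null(ref) || nrow(ref) == 0) {
    warning("empty metabolite reference: no annotations")
    return(rep(list(empty_match()), length(mz_channels)))
  }
  theo <- outer(ref$mass, adducts, "+")  # nref x nadduct theoretical m/z
  lapply(mz_channels, function(obs) {
    ppm <- (obs - theo) / theo * 1e6
    hit <- which(abs(ppm) <= tol_ppm, arr.ind = TRUE)
    if (nrow(hit) == 0) return(empty_match())
    d <- data.frame(id = ref$id[hit[, 1]], name = ref$name[hit[, 1]],
                    adduct = names(adducts)[hit[, 2]],
                    ppm_error = ppm[hit], stringsAsFactors = FALSE)
    d[order(abs(d$ppm_error)), , drop = FALSE]
  })
}

empty_match <- function() {
  data.frame(id = character(), name = character(), adduct = character(),
             ppm_error = numeric(), stringsAsFactors = FALSE)
}

#' Build a cohort matrix from per-core region profiles
#'
#' Runs the full per-core annotation path (co-registration, pixel labeling,
#' RMS normalization, aggregation) over a list of cores, then assembles one
#' samples x metabolites matrix per compartment. Multiple cores of the same
#' patient are averaged with equal weight.
#'
#' @param grids list of \code{\link{pixel_grid}}, one or more per patient.
#' @param if_images list with one element per core:
#'   \code{list(panCK = fluor_image, vimentin = fluor_image)}.
#' @param patient_ids character vector, parallel to \code{grids}.
#' @param min_pixels region-exclusion threshold (see
#'   \code{\link{aggregate_profiles}}).
#' @param thresholds optional list \code{list(panCK =, vimentin =)} of fixed
#'   positivity thresholds; default Otsu per channel per core.
#' @return list with elements \code{tumor} and \code{stroma}, each a
#'   \code{cohort_matrix}: \code{list(x = matrix, compartment, sample_ids)}
#'   where rows of \code{x} are patients and columns are m/z channels.
#' @export
build_cohort <- function(grids, if_images, patient_ids, min_pixels = 10,
                         thresholds = NULL) {
  stopifnot(length(grids) == length(if_images),
            length(grids) == length(patient_ids))
  acc <- list(tumor = list(), stroma = list())
  for (i in seq_along(grids)) {
    g <- grids[[i]]
    shape <- c(max(g$coords[, 1]) + 1L, max(g$coords[, 2]) + 1L)
    pk <- coregister(if_images[[i]]$panCK, shape)
    vm <- coregister(if_images[[i]]$vimentin, shape)
    mask <- if (is.null(thresholds)) annotate_pixels(pk, vm)
            else annotate_pixels(pk, vm, thresholds$panCK, thresholds$vimentin)
    gn <- rms_normalize(g)
    for (rp in aggregate_profiles(gn, mask, min_pixels)) {
      acc[[rp$compartment]][[length(acc[[rp$compartment]]) + 1L]] <-
        c(list(patient = patient_ids[i]), rp)
    }
  }
  out <- list()
  for (comp in c("tumor", "stroma")) {
    rps <- acc[[comp]]
    if (length(rps) == 0) { out[[comp]] <- NULL; next }
    pats <- vapply(rps, `[[`, character(1), "patient")
    mat <- do.call(rbind, lapply(rps, `[[`, "profile"))
    agg <- rowsum(mat, pats) / as.vector(table(pats)[sort(unique(pats))])
    out[[comp]] <- cohort_matrix(agg, comp, rownames(agg),
                                 mz = grids[[1]]$mz)
  }
  out
}

#' Construct a cohort matrix
#'
#' @param x numeric matrix, samples x metabolites (no missing values).
#' @param compartment \code{"tumor"} or \code{"stroma"}.
#' @param sample_ids row identifiers (patient or patient-compartment).
#' @param mz optional m/z values for the columns.
#' @param metabolite_ids optional column identifiers; default
#'   \code{colnames(x)} or \code{mz_<k>}.
#' @return object of class \code{cohort_matrix}.
#' @export
cohort_matrix <- function(x, compartment, sample_ids = rownames(x),
                          mz = NULL, metabolite_ids = NULL) {
  compartment <- match.arg(compartment, c("tumor", "stroma"))
  x <- as.matrix(x)
  if (anyNA(x)) stop("cohort matrix must not contain missing values")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(x)))
  if (is.null(metabolite_ids))
    metabolite_ids <- if (!is.null(colnames(x))) colnames(x)
                      else paste0("mz_", seq_len(ncol(x)))
  rownames(x) <- sample_ids
  colnames(x) <- metabolite_ids
  structure(list(x = x, compartment = compartment,
                 sample_ids = as.character(sample_ids),
                 metabolite_ids = as.character(metabolite_ids),
                 mz = mz),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %s: %d samples x %d metabolites\n",
              x$compartment, nrow(x$x), ncol(x$x)))
  invisible(x)
}
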