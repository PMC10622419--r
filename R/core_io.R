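#' Construct a pixel spectrum grid
#'
#' The central container for one tissue core measured by imaging mass
#' spectrometry: a set of pixels, each carrying an intensity spectrum over a
#' shared list of m/z channels.
#'
#' @param core_id character scalar identifying the core.
#' @param coords integer matrix with two columns (row, col), 0-based,
#'   one row per pixel. Pixel order is row-major by convention but any
#'   order is accepted; coordinates must be unique.
#' @param mz numeric vector of m/z values (Da), strictly increasing.
#' @param intensities numeric matrix, pixels x channels, non-negative.
#'
#' @return An object of class \code{pixel_grid} with fields \code{core_id},
#'   \code{coords}, \code{mz}, \code{intensities}.
#' @export
pixel_grid <- function(core_id, coords, mz, intensities) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  intensities <- as.matrix(intensities)
  g <- structure(
    list(core_id = as.character(core_id), coords = coords,
         mz = as.numeric(mz), intensities = intensities),
    class = "pixel_grid")
  validate_pixel_grid(g)
  g
}

validate_pixel_grid <- function(g) {
  stopifnot(inherits(g, "pixel_grid"))
  if (ncol(g$coords) != 2L)
    stop("coords must have two columns (row, col)")
  if (any(g$coords < 0L))
    stop("pixel coordinates must be 0-based non-negative")
  key <- paste(g$coords[, 1], g$coords[, 2])
  if (anyDuplicated(key))
    stop("duplicate pixel coordinates: (",
         paste(g$coords[which(duplicated(key))[1], ], collapse = ","), ")")
  if (nrow(g$intensities) != nrow(g$coords))
    stop("intensity rows (", nrow(g$intensities),
         ") do not match number of pixels (", nrow(g$coords), ")")
  if (ncol(g$intensities) != length(g$mz))
    stop("intensity columns (", ncol(g$intensities),
         ") do not match number of m/z channels (", length(g$mz), ")")
  if (any(g$intensities < 0))
    stop("intensities must be non-negative")
  if (length(g$mz) > 1 && any(diff(g$mz) <= 0))
    stop("m/z channels must be strictly increasing")
  invisible(g)
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid> core '%s': %d pixels x %d m/z channels (%.4f..%.4f Da)\n",
              x$core_id, nrow(x$coords), length(x$mz),
              min(x$mz), max(x$mz)))
  invisible(x)
}

#' Construct a fluorescence channel image
#'
#' @param core_id core identifier.
#' @param channel one of \code{"panCK"} (pan-cytokeratin) or
#'   \code{"vimentin"}.
#' @param values numeric matrix of lightness values (arbitrary units, >= 0)
#'   at the microscope's native resolution.
#' @return Object of class \code{fluor_image}.
#' @export
fluor_image <- function(core_id, channel, values) {
  channel <- match.arg(channel, c("panCK", "vimentin"))
  values <- as.matrix(values)
  if (any(values < 0)) stop("lightness values must be non-negative")
  structure(list(core_id = as.character(core_id), channel = channel,
                 values = values),
            class = "fluor_image")
}

# ---- table schemas ---------------------------------------------------------

UICC_LEVELS  <- c("I", "II", "III", "IV")
PT_LEVELS    <- c("T1", "T2", "T3", "T4")
PN_LEVELS    <- c("N0", "N1", "N2")
M_LEVELS     <- c("M0", "M1")
GRADE_LEVELS <- c("G1", "G2", "G3")
SEX_LEVELS   <- c("male", "female")
RESEC_LEVELS <- c("R0", "R1", "R2")
MARKER_NAMES <- c("CD3", "CD8", "PDL1", "gH2AX")

#' Validate an immunomarker table
#'
#' Required columns: \code{patient_id}, \code{CD3}, \code{CD8} (cell
#' densities, >= 0), \code{PDL1} (percent positive tumor cells, 0-100),
#' \code{gH2AX} (proportion of positive cells, 0-1).
#'
#' @param markers data.frame.
#' @return The validated data.frame, invisibly usable downstream.
#' @export
validate_markers <- function(markers) {
  need <- c("patient_id", MARKER_NAMES)
  miss <- setdiff(need, names(markers))
  if (length(miss)) stop("marker table missing column: ", miss[1])
  if (anyDuplicated(markers$patient_id)) stop("duplicate patient_id in marker table")
  if (any(markers$CD3 < 0, na.rm = TRUE) || any(markers$CD8 < 0, na.rm = TRUE))
    stop("CD3/CD8 scores must be >= 0")
  if (any(markers$PDL1 < 0 | markers$PDL1 > 100, na.rm = TRUE))
    stop("PDL1 must be a percentage in [0, 100]")
  if (any(markers$gH2AX < 0 | markers$gH2AX > 1, na.rm = TRUE))
    stop("gH2AX must be a proportion in [0, 1]")
  markers
}

#' Validate a clinical table
#'
#' Required columns: \code{patient_id}, \code{time} (months, > 0),
#' \code{event} (0/1, disease-specific death), \code{uicc} (I-IV),
#' \code{pT}, \code{pN}, \code{M}, \code{grade}, \code{sex}, \code{age},
#' \code{resection}. Optional: \code{mpr} (0/1), \code{response}
#' ("sensitive"/"resistant").
#'
#' @param clinical data.frame.
#' @return The validated data.frame.
#' @export
validate_clinical <- function(clinical) {
  need <- c("patient_id", "time", "event", "uicc", "pT", "pN", "M",
            "grade", "sex", "age", "resection")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop("clinical table missing column: ", miss[1])
  if (anyDuplicated(clinical$patient_id)) stop("duplicate patient_id in clinical table")
  if (any(clinical$time <= 0)) stop("survival time must be > 0")
  if (!all(clinical$event %in% c(0, 1))) stop("event must be 0 or 1")
  chk <- function(col, levels) {
    bad <- setdiff(unique(as.character(clinical[[col]])), levels)
    if (length(bad))
      stop("column '", col, "' has value outside its closed vocabulary: ", bad[1])
  }
  chk("uicc", UICC_LEVELS); chk("pT", PT_LEVELS); chk("pN", PN_LEVELS)
  chk("M", M_LEVELS); chk("grade", GRADE_LEVELS); chk("sex", SEX_LEVELS)
  chk("resection", RESEC_LEVELS)
  if ("mpr" %in% names(clinical) && !all(clinical$mpr %in% c(0, 1)))
    stop("mpr must be 0 or 1")
  if ("response" %in% names(clinical)) {
    bad <- setdiff(unique(clinical$response), c("sensitive", "resistant"))
    if (length(bad)) stop("response must be 'sensitive' or 'resistant', got: ", bad[1])
  }
  clinical
}

# ---- grid file formats -----------------------------------------------------

#' Read a pixel spectrum grid from file
#'
#' Two dialects are supported: \code{"imzml"}, the open mass-spectrometry
#' imaging standard (continuous mode; XML plus binary .ibd companion), and
#' \code{"imzml_lite_csv"}, a long-format plain-text dialect with columns
#' \code{core_id,row,col,mz,intensity} intended for greppable, diff-friendly
#' fixtures.
#'
#' @param path file path (for imzML, the .imzML XML file; the .ibd file is
#'   found by replacing the extension).
#' @param dialect \code{"imzml"} or \code{"imzml_lite_csv"}.
#' @return A \code{\link{pixel_grid}}.
#' @export
read_grid <- function(path, dialect = c("imzml_lite_csv", "imzml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         imzml_lite_csv = read_grid_csv(path),
         imzml = read_imzml(path))
}

read_grid_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("core_id", "row", "col", "mz", "intensity")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("imzml-lite CSV missing column: ", miss[1])
  if (length(unique(d$core_id)) != 1)
    stop("imzml-lite CSV must contain exactly one core, found: ",
         paste(unique(d$core_id), collapse = ", "))
  mz <- sort(unique(d$mz))
  key <- paste(d$row, d$col)
  px <- unique(key)
  # each pixel must report each channel exactly once
  cnt <- table(key)
  if (any(cnt != length(mz)))
    stop("malformed imzml-lite CSV: pixel (",
         gsub(" ", ",", names(cnt)[which(cnt != length(mz))[1]]),
         ") does not have exactly one record per m/z channel")
  d <- d[order(match(key, px), match(d$mz, mz)), ]
  coords <- do.call(rbind, strsplit(px, " "))
  coords <- matrix(as.integer(coords), ncol = 2)
  inten <- matrix(d$intensity, nrow = length(px), ncol = length(mz), byrow = TRUE)
  pixel_grid(d$core_id[1], coords, mz, inten)
}

#' Write a pixel spectrum grid as imzml-lite CSV
#'
#' @param grid a \code{\link{pixel_grid}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  validate_pixel_grid(grid)
  n <- nrow(grid$coords); m <- length(grid$mz)
  d <- data.frame(core_id = grid$core_id,
                  row = rep(grid$coords[, 1], each = m),
                  col = rep(grid$coords[, 2], each = m),
                  mz = rep(grid$mz, times = n),
                  intensity = as.vector(t(grid$intensities)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write / read marker and clinical tables and pathway catalogs
#'
#' Plain-CSV round trip with schema validation on read. The pathway catalog
#' uses GMT-style text: one pathway per line,
#' \code{id<TAB>name<TAB>member<TAB>member...}.
#'
#' @param markers,clinical data.frames passing \code{\link{validate_markers}}
#'   / \code{\link{validate_clinical}}.
#' @param path file path.
#' @return readers return validated data.frames / named catalog list.
#' @name tables_io
NULL

#' @rdname tables_io
#' @export
write_markers <- function(markers, path) {
  utils::write.csv(validate_markers(markers), path, row.names = FALSE)
  invisible(path)
}

#' @rdname tables_io
#' @export
read_markers <- function(path) {
  validate_markers(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname tables_io
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(validate_clinical(clinical), path, row.names = FALSE)
  invisible(path)
}

#' @rdname tables_io
#' @export
read_clinical <- function(path) {
  validate_clinical(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname tables_io
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(is.list(catalog), length(names(catalog)) == length(catalog))
  lines <- vapply(names(catalog), function(id) {
    p <- catalog[[id]]
    if (length(p$members) == 0) stop("pathway '", id, "' has an empty member set")
    paste(c(id, p$name, p$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname tables_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line (needs id, name, >=1 member): ", l)
    list(name = f[2], members = f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
                       character(1))
  out
}

# ---- RNG substreams --------------------------------------------------------

#' Derive a named RNG substream seed
#'
#' All randomness in the pipeline flows from one top-level seed; each stage
#' draws from its own substream so partial reruns reproduce exactly. The
#' substream seed is a deterministic hash of the top-level seed and the
#' stage name, kept below 2^31.
#'
#' @param seed top-level integer seed.
#' @param stage character stage name.
#' @return integer seed for the stage's substream.
#' @export
substream_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 12345) %% 2147483647)
}
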