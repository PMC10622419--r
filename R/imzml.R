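# Minimal imzML support: continuous-mode read/write of the open
# mass-spectrometry-imaging standard (XML index + binary .ibd companion).
# Only what the pipeline needs: one shared m/z axis, float32/float64 arrays,
# no compression. Positions are 1-based in imzML; the pixel_grid convention
# is 0-based (row = y - 1, col = x - 1).

ACC <- list(
  continuous  = "IMS:1000030",
  processed   = "IMS:1000031",
  uuid        = "IMS:1000080",
  pos_x       = "IMS:1000050",
  pos_y       = "IMS:1000051",
  offset      = "IMS:1000102",
  arr_len     = "IMS:1000103",
  enc_len     = "IMS:1000104",
  mz_array    = "MS:1000514",
  int_array   = "MS:1000515",
  f32         = "MS:1000521",
  f64         = "MS:1000523"
)

ibd_path <- function(path) {
  p <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(p, path)) p <- paste0(path, ".ibd")
  p
}

read_imzml <- function(path) {
  doc <- xml2::read_xml(path)
  # namespace-agnostic xpath; imzML files in the wild vary in ns declaration
  q <- function(node, xp) xml2::xml_find_all(node, xp)
  acc_set <- function(node) {
    unique(xml2::xml_attr(q(node, ".//*[local-name()='cvParam']"), "accession"))
  }
  fc <- q(doc, ".//*[local-name()='fileContent']")
  if (length(fc) && ACC$processed %in% acc_set(fc[[1]]) &&
      !(ACC$continuous %in% acc_set(fc[[1]])))
    stop("processed-mode imzML is not supported; expected continuous mode")

  # referenceable param groups let binaryDataArray carry its cvParams indirectly
  groups <- q(doc, ".//*[local-name()='referenceableParamGroup']")
  group_acc <- lapply(groups, acc_set)
  names(group_acc) <- xml2::xml_attr(groups, "id")

  ibd <- ibd_path(path)
  if (!file.exists(ibd)) stop("binary companion file not found: ", ibd)
  con <- file(ibd, "rb")
  on.exit(close(con))

  spectra <- q(doc, ".//*[local-name()='spectrum']")
  if (!length(spectra)) stop("malformed imzML: no spectrum elements in ", path)

  read_array_meta <- function(bda) {
    accs <- acc_set(bda)
    ref <- q(bda, ".//*[local-name()='referenceableParamGroupRef']")
    if (length(ref)) {
      rid <- xml2::xml_attr(ref[[1]], "ref")
      accs <- union(accs, group_acc[[rid]])
    }
    cv <- q(bda, ".//*[local-name()='cvParam']")
    cva <- xml2::xml_attr(cv, "accession")
    val <- function(a) as.numeric(xml2::xml_attr(cv[cva == a][1], "value"))
    list(is_mz = ACC$mz_array %in% accs,
         bytes = if (ACC$f64 %in% accs) 8L else if (ACC$f32 %in% accs) 4L else
           stop("malformed imzML: binary array without a float32/float64 cvParam"),
         offset = val(ACC$offset), n = val(ACC$arr_len))
  }

  read_ibd <- function(meta) {
    seek(con, meta$offset)
    readBin(con, "double", n = meta$n, size = meta$bytes)
  }

  mz <- NULL
  coords <- matrix(0L, length(spectra), 2)
  inten <- NULL
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    cv <- q(sp, ".//*[local-name()='scan']//*[local-name()='cvParam']")
    cva <- xml2::xml_attr(cv, "accession")
    x <- as.integer(xml2::xml_attr(cv[cva == ACC$pos_x][1], "value"))
    y <- as.integer(xml2::xml_attr(cv[cva == ACC$pos_y][1], "value"))
    if (is.na(x) || is.na(y))
      stop("malformed imzML: spectrum ", i, " lacks pixel position cvParams")
    coords[i, ] <- c(y - 1L, x - 1L)
    for (bda in q(sp, ".//*[local-name()='binaryDataArray']")) {
      meta <- read_array_meta(bda)
      if (meta$is_mz) {
        if (is.null(mz)) mz <- read_ibd(meta)
      } else {
        v <- read_ibd(meta)
        if (is.null(inten)) inten <- matrix(0, length(spectra), length(v))
        inten[i, ] <- v
      }
    }
  }
  if (is.null(mz)) stop("malformed imzML: no m/z array found")
  core <- sub("\\.imzml$", "", basename(path), ignore.case = TRUE)
  pixel_grid(core, coords, mz, inten)
}

#' Write a pixel spectrum grid as continuous-mode imzML
#'
#' Emits the standard XML index plus the binary \code{.ibd} companion
#' (shared float64 m/z axis written once, float32 intensities per pixel,
#' no compression).
#'
#' @param grid a \code{\link{pixel_grid}}.
#' @param path output path for the \code{.imzML} file; the \code{.ibd} file
#'   is written alongside.
#' @return \code{path}, invisibly.
#' @export
write_imzml <- function(grid, path) {
  validate_pixel_grid(grid)
  n_px <- nrow(grid$coords); n_mz <- length(grid$mz)

  # deterministic pseudo-UUID derived from content dimensions and core id
  h <- substream_seed(n_px * 7 + n_mz, grid$core_id)
  uuid_bytes <- as.raw((seq_len(16) * 37 + h) %% 256)
  uuid_str <- paste0(
    "{", paste(format_hex(uuid_bytes[1:4]), collapse = ""), "-",
    paste(format_hex(uuid_bytes[5:6]), collapse = ""), "-",
    paste(format_hex(uuid_bytes[7:8]), collapse = ""), "-",
    paste(format_hex(uuid_bytes[9:10]), collapse = ""), "-",
    paste(format_hex(uuid_bytes[11:16]), collapse = ""), "}")

  ibd <- ibd_path(path)
  con <- file(ibd, "wb")
  writeBin(uuid_bytes, con)
  writeBin(as.numeric(grid$mz), con, size = 8)
  mz_offset <- 16
  int_offsets <- numeric(n_px)
  pos <- 16 + 8 * n_mz
  for (i in seq_len(n_px)) {
    int_offsets[i] <- pos
    writeBin(as.numeric(grid$intensities[i, ]), con, size = 4)
    pos <- pos + 4 * n_mz
  }
  close(con)

  cvp <- function(cv, acc, name, value = NULL, unit = NULL) {
    v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s/>', cv, acc, name, v)
  }
  spec_xml <- vapply(seq_len(n_px), function(i) {
    x <- grid$coords[i, 2] + 1L; y <- grid$coords[i, 1] + 1L
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, n_mz),
      '<scanList count="1">',
      cvp("MS", "MS:1000795", "no combination"),
      '<scan>',
      cvp("IMS", ACC$pos_x, "position x", x),
      cvp("IMS", ACC$pos_y, "position y", y),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      sprintf('<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="mzArray"/>%s%s%s<binary/></binaryDataArray>',
              cvp("IMS", ACC$offset, "external offset", mz_offset),
              cvp("IMS", ACC$arr_len, "external array length", n_mz),
              cvp("IMS", ACC$enc_len, "external encoded length", 8 * n_mz)),
      sprintf('<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="intensityArray"/>%s%s%s<binary/></binaryDataArray>',
              cvp("IMS", ACC$offset, "external offset", int_offsets[i]),
              cvp("IMS", ACC$arr_len, "external array length", n_mz),
              cvp("IMS", ACC$enc_len, "external encoded length", 4 * n_mz)),
      '</binaryDataArrayList></spectrum>')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    cvp("MS", "MS:1000294", "mass spectrum"),
    cvp("IMS", ACC$continuous, "continuous"),
    cvp("IMS", ACC$uuid, "universally unique identifier", uuid_str),
    cvp("IMS", "IMS:1000091", "ibd SHA-1", "0000000000000000000000000000000000000000"),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cvp("MS", ACC$mz_array, "m/z array"),
    cvp("MS", ACC$f64, "64-bit float"),
    cvp("MS", "MS:1000576", "no compression"),
    cvp("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    cvp("MS", ACC$int_array, "intensity array"),
    cvp("MS", ACC$f32, "32-bit float"),
    cvp("MS", "MS:1000576", "no compression"),
    cvp("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<softwareList count="1"><software id="metaboSubtypes" version="0.1.0"/></softwareList>',
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    cvp("IMS", "IMS:1000042", "max count of pixels x", max(grid$coords[, 2]) + 1L),
    cvp("IMS", "IMS:1000043", "max count of pixels y", max(grid$coords[, 1]) + 1L),
    '</scanSettings></scanSettingsList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="export"><processingMethod order="1" softwareRef="metaboSubtypes">',
    cvp("MS", "MS:1000544", "Conversion to mzML"),
    '</processingMethod></dataProcessing></dataProcessingList>',
    sprintf('<run id="%s" defaultInstrumentConfigurationRef="IC1">', grid$core_id),
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="export">', n_px),
    paste(spec_xml, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, path)
  invisible(path)
}

format_hex <- function(raw_vec) sprintf("%02x", as.integer(raw_vec))
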