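## Dataset container I/O. One lossless container carries every stage's data
## with its acquisition metadata, so that units (f0, prfc, pixel pitch)
## always travel with the arrays. On disk the container is R-native
## serialization of a validated plain-list representation of the group
## schema /iq, /pa, /maps, /truth, /meta; round-trips are bit-identical.

.REQUIRED_IQ_META <- c("f0", "prf_c", "pixel_pitch", "c")

# S4 -> plain list (the serialized form is class-version independent).
.containerToList <- function(cont) {
  iq <- if (is.null(cont@iq)) NULL else list(
    data = cont@iq@data,
    f0 = cont@iq@f0, prf_c = cont@iq@prfc,
    pixel_pitch = cont@iq@pixelPitch, c = cont@iq@c,
    axes = c("depth", "lateral", "time"),
    units = c(data = "a.u.", f0 = "Hz", prf_c = "Hz", pixel_pitch = "mm",
              c = "m/s"))
  pa <- if (is.null(cont@pa)) NULL else list(
    images = cont@pa@images, wavelengths = cont@pa@wavelengths,
    pulse_energies = cont@pa@pulseEnergies,
    pixel_pitch = cont@pa@pixelPitch,
    axes = c("depth", "lateral", "wavelength", "set"),
    units = c(images = "a.u.", wavelengths = "nm", pulse_energies = "mJ"))
  list(iq = iq, pa = pa, maps = cont@maps, truth = cont@truth,
       meta = cont@meta)
}

.containerFromList <- function(lst, path = "<container>") {
  schemaError <- function(field, group)
    stop("container schema error in ", path, ": /", group,
         " is missing required field '", field, "'", call. = FALSE)
  iq <- NULL
  if (!is.null(lst$iq)) {
    for (f in .REQUIRED_IQ_META)
      if (is.null(lst$iq[[f]])) schemaError(f, "iq")
    if (is.null(lst$iq$data)) schemaError("data", "iq")
    iq <- IQMovie(lst$iq$data, pixelPitch = lst$iq$pixel_pitch,
                  f0 = lst$iq$f0, c = lst$iq$c, prfc = lst$iq$prf_c)
  }
  pa <- NULL
  if (!is.null(lst$pa)) {
    for (f in c("images", "wavelengths", "pulse_energies"))
      if (is.null(lst$pa[[f]])) schemaError(f, "pa")
    pa <- PAStack(lst$pa$images, lst$pa$wavelengths, lst$pa$pulse_energies,
                  pixelPitch = lst$pa$pixel_pitch %||% 0.1)
  }
  new("DatasetContainer", iq = iq, pa = pa,
      maps = lst$maps %||% list(), truth = lst$truth %||% list(),
      meta = lst$meta %||% list())
}

#' Write a dataset container to disk
#'
#' Stamps the package version into /meta before writing; the write/read
#' pair is a lossless identity for all arrays and attributes.
#'
#' @param container a \code{\link{datasetContainer}}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeContainer <- function(container, path) {
  validObject(container)
  container@meta$version <- as.character(utils::packageVersion("hemofus"))
  saveRDS(.containerToList(container), path)
  invisible(path)
}

#' Read a dataset container from disk
#'
#' Validates the schema: missing required acquisition metadata (f0, prf_c,
#' pixel_pitch, sound speed) raises an error naming the field.
#'
#' @param path container file path.
#' @return A \code{\link{DatasetContainer}}.
#' @export
readContainer <- function(path) {
  if (!file.exists(path)) stop("container not found: ", path)
  .containerFromList(readRDS(path), path)
}

#' Export a 2-D map to a standard image or table format
#'
#' \code{tiff32} writes a 32-bit float TIFF of value / scale with the
#' positive scale factor \code{max(|value|)} recorded in a plain-text
#' \code{<path>.scale} sidecar (the TIFF container stores floats in
#' [0, 1]); \code{\link{importMap}} reapplies it. \code{pngdb} writes an
#' 8-bit log-compressed view referenced to the map maximum. \code{csv}
#' writes exact values with pixel coordinates.
#'
#' @param map numeric matrix.
#' @param path output path.
#' @param format one of "tiff32", "pngdb", "csv".
#' @param floorDb dB floor of the compressed view.
#' @return The path, invisibly.
#' @export
exportMap <- function(map, path, format = c("tiff32", "pngdb", "csv"),
                      floorDb = -60) {
  format <- match.arg(format)
  if (all(is.na(map))) stop("map contains only NA values")
  m <- map
  m[is.na(m)] <- 0
  if (format == "tiff32") {
    scale <- max(abs(m))
    if (scale == 0) scale <- 1
    tiff::writeTIFF((m / scale + 1) / 2, path, bits.per.sample = 32L,
                    reduce = FALSE)
    writeLines(format(scale, digits = 17), paste0(path, ".scale"))
  } else if (format == "pngdb") {
    mx <- max(abs(m))
    if (mx <= 0) mx <- 1
    db <- 20 * log10(pmax(abs(m) / mx, 10^(floorDb / 20)))
    png::writePNG((db - floorDb) / (-floorDb), path)
  } else {
    d <- dim(map)
    df <- data.frame(depth = rep(seq_len(d[1]), d[2]),
                     lateral = rep(seq_len(d[2]), each = d[1]),
                     value = as.vector(map))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Re-import a float TIFF map written by \code{\link{exportMap}}
#'
#' @param path TIFF path with its \code{.scale} sidecar.
#' @return numeric matrix.
#' @export
importMap <- function(path) {
  img <- tiff::readTIFF(path)
  scaleFile <- paste0(path, ".scale")
  scale <- if (file.exists(scaleFile))
    as.numeric(readLines(scaleFile)[1]) else 1
  (img * 2 - 1) * scale
}
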