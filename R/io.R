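## Localization, ROI and mask I/O; segment extraction.
## Canonical unit is nm throughout; pixel-based dialects convert at load.

.detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a localization table from delimited text
#'
#' Reads a comma- or tab-separated localization file (auto-detected) with a
#' header row. A dialect maps file columns to the canonical fields and
#' declares units: coordinates given in camera pixels are converted to nm at
#' load using \code{pixelSize}.
#'
#' @param path file path.
#' @param dialect named list mapping canonical fields (\code{x}, \code{y},
#'   optionally \code{z}, \code{channel}, \code{frame}, \code{photons}) to
#'   file column names, plus \code{units} ("nm", the default, or "px") and
#'   \code{pixelSize} (nm per pixel, required for "px").
#' @return A \linkS4class{Localizations}; row order preserved.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLocalizations(Localizations(x = c(0, 100), y = c(5, 6)), f)
#' readLocalizations(f)
#' @export
readLocalizations <- function(path, dialect = list()) {
  def <- list(x = "x_nm", y = "y_nm", z = "z_nm", channel = "channel",
              frame = "frame", photons = "photons", units = "nm",
              pixelSize = NULL)
  dia <- utils::modifyList(def, dialect)
  d <- utils::read.table(path, header = TRUE, sep = .detectSep(path),
                         stringsAsFactors = FALSE, check.names = FALSE)
  for (fld in c("x", "y")) {
    if (!dia[[fld]] %in% names(d))
      stop(sprintf("format error: mapped column '%s' (for %s) not found",
                   dia[[fld]], fld), call. = FALSE)
  }
  getNum <- function(col, fld) {
    v <- d[[col]]
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vn) & !is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric %s value at row %d", fld, bad[1]), call. = FALSE)
    vn
  }
  scale <- 1
  if (identical(dia$units, "px")) {
    if (is.null(dia$pixelSize))
      stop("format error: dialect with units 'px' requires pixelSize", call. = FALSE)
    scale <- dia$pixelSize
  }
  x <- getNum(dia$x, "x") * scale
  y <- getNum(dia$y, "y") * scale
  z <- if (dia$z %in% names(d)) getNum(dia$z, "z") * scale else NULL
  channel <- if (dia$channel %in% names(d)) as.integer(d[[dia$channel]]) else 1L
  frame <- if (dia$frame %in% names(d)) as.integer(d[[dia$frame]]) else 0L
  photons <- if (dia$photons %in% names(d)) getNum(dia$photons, "photons") else NULL
  if (nrow(d) == 0L)
    return(Localizations(numeric(0), numeric(0),
                         z = if (dia$z %in% names(d)) numeric(0) else NULL))
  Localizations(x, y, z = z, channel = channel, frame = frame, photons = photons)
}

#' Write a localization table as delimited text
#'
#' Writes the canonical comma-separated schema
#' \code{x_nm,y_nm[,z_nm],channel,frame[,photons]}; optional columns absent
#' from the table are omitted.
#'
#' @param locs a \linkS4class{Localizations}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeLocalizations <- function(locs, path) {
  stopifnot(is(locs, "Localizations"))
  d <- locs@data
  out <- data.frame(x_nm = d$x, y_nm = d$y)
  if ("z" %in% names(d)) out$z_nm <- d$z
  out$channel <- d$channel
  out$frame <- d$frame
  if ("photons" %in% names(d)) out$photons <- d$photons
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read segment ROIs from delimited text
#'
#' One segment per line with header \code{ax,ay,bx,by,half_width,label}.
#'
#' @param path file path.
#' @return A list of \linkS4class{SegmentROI}.
#' @export
readSegmentROIs <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = .detectSep(path),
                         stringsAsFactors = FALSE)
  need <- c("ax", "ay", "bx", "by", "half_width")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("format error: missing ROI column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  lab <- if ("label" %in% names(d)) as.character(d$label) else as.character(seq_len(nrow(d)))
  lapply(seq_len(nrow(d)), function(i)
    SegmentROI(c(d$ax[i], d$ay[i]), c(d$bx[i], d$by[i]), d$half_width[i], lab[i]))
}

#' Write segment ROIs as delimited text
#'
#' @param rois list of \linkS4class{SegmentROI}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeSegmentROIs <- function(rois, path) {
  d <- do.call(rbind, lapply(rois, function(r)
    data.frame(ax = r@a[1], ay = r@a[2], bx = r@b[1], by = r@b[2],
               half_width = r@halfWidth, label = r@label)))
  utils::write.table(d, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the localizations belonging to a segment ROI
#'
#' Keeps localizations whose perpendicular distance to the ROI axis is at most
#' the half-width (inclusive) and whose axial coordinate lies in
#' \code{[0, |b - a|]} (closed), and expresses them in the segment-local frame:
#' x along the axis with origin at endpoint a, y perpendicular.
#'
#' @param locs a \linkS4class{Localizations} in global coordinates.
#' @param roi a \linkS4class{SegmentROI}.
#' @return A \linkS4class{Localizations} in segment-local coordinates (possibly
#'   empty).
#' @export
extractSegment <- function(locs, roi) {
  stopifnot(is(locs, "Localizations"), is(roi, "SegmentROI"))
  d <- locs@data
  if (!nrow(d)) return(locs)
  v <- roi@b - roi@a
  L <- sqrt(sum(v^2))
  u <- v / L
  dx <- d$x - roi@a[1]
  dy <- d$y - roi@a[2]
  ax <- dx * u[1] + dy * u[2]        # axial
  py <- -dx * u[2] + dy * u[1]       # perpendicular (right-handed)
  keep <- ax >= 0 & ax <= L & abs(py) <= roi@halfWidth
  out <- d[keep, , drop = FALSE]
  out$x <- ax[keep]
  out$y <- py[keep]
  rownames(out) <- NULL
  new("Localizations", data = out)
}

#' Write a mask or grayscale image as a TIFF-like raster with pixel-size sidecar
#'
#' Writes a single-channel float TIFF via the \pkg{tiff} package and a sidecar
#' text file \code{<path>.pixelsize} holding the pixel size in nm.
#'
#' @param mask a \linkS4class{MaskImage}.
#' @param path output TIFF path.
#' @return Invisibly, \code{path}.
#' @export
writeMaskImage <- function(mask, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF rasters", call. = FALSE)
  tiff::writeTIFF(mask@mask * 1.0, path)
  writeLines(format(mask@pixelSize, digits = 12), paste0(path, ".pixelsize"))
  invisible(path)
}

#' Read a mask image written by \code{writeMaskImage}
#'
#' @param path TIFF path (with sidecar \code{<path>.pixelsize}).
#' @param pixelSize pixel size in nm; if missing, read from the sidecar.
#' @return A \linkS4class{MaskImage} (pixels > 0.5 are foreground).
#' @export
readMaskImage <- function(path, pixelSize = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF rasters", call. = FALSE)
  m <- tiff::readTIFF(path)
  if (is.null(pixelSize)) {
    side <- paste0(path, ".pixelsize")
    if (!file.exists(side))
      stop("pixel size not given and sidecar file not found", call. = FALSE)
    pixelSize <- as.numeric(readLines(side, n = 1L))
  }
  MaskImage(m > 0.5, pixelSize)
}

#' Read a puncta table (x_nm, y_nm[, channel]) from delimited text
#'
#' @param path file path.
#' @param channel channel label for the returned set.
#' @return A \linkS4class{PunctaSet}.
#' @export
readPuncta <- function(path, channel = "pre") {
  d <- utils::read.table(path, header = TRUE, sep = .detectSep(path))
  if (!all(c("x_nm", "y_nm") %in% names(d)))
    stop("format error: puncta file needs x_nm and y_nm columns", call. = FALSE)
  PunctaSet(cbind(d$x_nm, d$y_nm), channel)
}

#' Write a puncta table as delimited text
#'
#' @param puncta a \linkS4class{PunctaSet}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writePuncta <- function(puncta, path) {
  d <- data.frame(x_nm = puncta@coords[, 1], y_nm = puncta@coords[, 2],
                  channel = puncta@channel)
  utils::write.table(d, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
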