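# Raw spectral-domain OCT exports carry linear interferometric intensities
# whose dynamic range spans several orders of magnitude; the classical
# greyscale visualization compresses them with a fourth root before 8-bit
# binning. Coordinates throughout the package are 0-based (row, col) with
# row 0 at the inner retina (top of image); rows increase with depth.

#' Per-scan pixel calibration
#'
#' Lateral (pixel width) and axial (pixel depth) pixel dimensions in
#' micrometres. These are taken as given — reported by the OCT device
#' during raw export, or computed externally from corneal radius and scan
#' focus — and are never derived from nominal scan depth.
#'
#' @param pixel_width_um Micrometres per column (lateral), > 0.
#' @param pixel_depth_um Micrometres per row (axial), > 0. The Spectralis
#'   default of 3.87 is typical.
#' @return Object of class `scan_calibration`.
#' @export
#' @examples
#' scan_calibration(11.27, 3.87)
scan_calibration <- function(pixel_width_um, pixel_depth_um = 3.87) {
  if (!is.numeric(pixel_width_um) || length(pixel_width_um) != 1L ||
      !is.finite(pixel_width_um) || pixel_width_um <= 0) {
    stop("pixel_width_um must be a single positive number")
  }
  if (!is.numeric(pixel_depth_um) || length(pixel_depth_um) != 1L ||
      !is.finite(pixel_depth_um) || pixel_depth_um <= 0) {
    stop("pixel_depth_um must be a single positive number")
  }
  structure(list(pixel_width_um = pixel_width_um,
                 pixel_depth_um = pixel_depth_um),
            class = "scan_calibration")
}

#' @export
print.scan_calibration <- function(x, ...) {
  cat(sprintf("<scan_calibration> %.4g x %.4g um (width x depth), %.4f um^2/px\n",
              x$pixel_width_um, x$pixel_depth_um, pixel_area(x)))
  invisible(x)
}

#' True area of one pixel in square micrometres
#'
#' @param calib A [scan_calibration()].
#' @return `pixel_width_um * pixel_depth_um`.
#' @export
#' @examples
#' pixel_area(scan_calibration(11.27, 3.87)) # 43.6149
pixel_area <- function(calib) {
  stopifnot(inherits(calib, "scan_calibration"))
  calib$pixel_width_um * calib$pixel_depth_um
}

# round half away from zero (inputs are non-negative here), unlike the
# banker's rounding of base round()
.round_half_up <- function(x) floor(x + 0.5)

#' Fourth-root rescaling of a raw B-scan to 8-bit greyscale
#'
#' Converts a raw intensity array to the classical greyscale visualization:
#' each intensity v maps to `round(255 * (v / reference_max)^(1/4))` with
#' half-up rounding. The fourth root compresses the raw dynamic range so
#' that weakly reflective bands (ELM, IZ, BM) remain visible next to the
#' bright EZ/RPE complex.
#'
#' @param raw Numeric matrix of non-negative finite intensities (rows =
#'   depth, columns = lateral position).
#' @param reference_max Normalisation constant: `"scan"` (default) uses the
#'   per-scan maximum, or supply a fixed positive number (e.g. the device's
#'   full-scale value) that must be >= `max(raw)`. An all-zero scan with
#'   per-scan normalisation maps to the all-zero image.
#' @return Integer matrix of the same shape with values in 0..255.
#' @export
#' @examples
#' raw <- matrix(c(0, 1, 8, 16), 2, 2)
#' fourth_root_rescale(raw, reference_max = 16)
fourth_root_rescale <- function(raw, reference_max = "scan") {
  if (!is.matrix(raw) || !is.numeric(raw) || length(raw) == 0L) {
    stop("raw must be a non-empty numeric matrix")
  }
  if (any(!is.finite(raw))) stop("raw intensities must be finite")
  if (any(raw < 0)) stop("raw intensities must be non-negative")

  if (identical(reference_max, "scan")) {
    ref <- max(raw)
    if (ref == 0) {
      return(matrix(0L, nrow(raw), ncol(raw)))
    }
  } else {
    if (!is.numeric(reference_max) || length(reference_max) != 1L ||
        !is.finite(reference_max) || reference_max <= 0) {
      stop("reference_max must be \"scan\" or a single positive number")
    }
    ref <- reference_max
    if (max(raw) > ref) stop("reference_max must be >= max(raw)")
  }

  g <- .round_half_up(255 * (raw / ref)^0.25)
  storage.mode(g) <- "integer"
  g
}

#' Read a raw or greyscale B-scan from TIFF/PNG
#'
#' TIFF input is read at native bit depth (`as.is`), PNG as 8/16-bit
#' levels; either way a numeric matrix of non-negative intensities is
#' returned, collapsing any channel dimension by its first plane.
#'
#' @param path Image path (.tif/.tiff/.png).
#' @return Numeric matrix, rows = depth.
#' @export
read_bscan_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    png = {
      x <- png::readPNG(path, info = TRUE)
      bd <- attr(x, "info")$bit.depth
      if (is.null(bd)) bd <- 8L
      x * (2^bd - 1)
    },
    stop("unsupported image extension: ", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  storage.mode(img) <- "double"
  img
}

#' Write an 8-bit greyscale B-scan to PNG or TIFF
#'
#' @param grey Integer/numeric matrix with values in 0..255.
#' @param path Output path (.png or .tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_grey_image <- function(grey, path) {
  stopifnot(is.matrix(grey), all(grey >= 0), all(grey <= 255))
  x <- grey / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image extension: ", ext)
  )
  invisible(path)
}

#' Read/write a calibration sidecar (YAML or JSON)
#'
#' The sidecar holds `pixel_width_um` and `pixel_depth_um` for one scan.
#'
#' @param path Sidecar path (.yaml/.yml/.json).
#' @param calib A [scan_calibration()] (for writing).
#' @return [scan_calibration()] for reading; `path` invisibly for writing.
#' @name calibration_io
NULL

#' @rdname calibration_io
#' @export
read_calibration <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    stop("unsupported sidecar extension: ", ext)
  )
  scan_calibration(x$pixel_width_um, x$pixel_depth_um)
}

#' @rdname calibration_io
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "scan_calibration"))
  x <- list(pixel_width_um = calib$pixel_width_um,
            pixel_depth_um = calib$pixel_depth_um)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported sidecar extension: ", ext)
  )
  invisible(path)
}
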