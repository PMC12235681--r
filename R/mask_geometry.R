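# Lesion masks are drawn in colour over the greyscale B-scan; a pixel
# belongs to a mask iff its RGB channels are not all equal (anything that
# is not a grey tone), and each distinct colour is one lesion. Pixel
# coordinates are 0-based (row, col).

#' Create a lesion mask
#'
#' A mask is the set of pixels one grader painted for one lesion, carrying
#' the colour that identifies the lesion on its scan. The instrument's
#' rules — at least 2 pixels, 8-connected — are checked by
#' [validate_mask()], not by the constructor.
#'
#' @param pixels Integer matrix with two columns (row, col), 0-based.
#' @param colour RGB triple (0..255) identifying the lesion.
#' @param scan_id Scan identifier.
#' @param lesion_id Lesion identifier; defaults to the colour's hex code.
#' @return Object of class `lesion_mask`.
#' @export
lesion_mask <- function(pixels, colour, scan_id = "scan", lesion_id = NULL) {
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 2L || nrow(pixels) == 0L) {
    stop("pixels must be a non-empty matrix with columns (row, col)")
  }
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L)) stop("pixel coordinates are 0-based and non-negative")
  pixels <- unique(pixels)
  pixels <- pixels[order(pixels[, 1L], pixels[, 2L]), , drop = FALSE]
  colnames(pixels) <- c("row", "col")
  colour <- as.integer(colour)
  if (length(colour) != 3L || any(colour < 0L) || any(colour > 255L)) {
    stop("colour must be an RGB triple in 0..255")
  }
  if (colour[1L] == colour[2L] && colour[2L] == colour[3L]) {
    stop("mask colour must not be a grey tone (R = G = B)")
  }
  if (is.null(lesion_id)) lesion_id <- colour_hex(colour)
  structure(list(pixels = pixels, colour = colour,
                 scan_id = as.character(scan_id),
                 lesion_id = as.character(lesion_id)),
            class = "lesion_mask")
}

#' Hex code of an RGB triple
#' @param colour Integer RGB triple in 0..255.
#' @return String like "#FF0000".
#' @export
colour_hex <- function(colour) {
  sprintf("#%02X%02X%02X", colour[1L], colour[2L], colour[3L])
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s / %s, colour %s, %d px\n",
              x$scan_id, x$lesion_id, colour_hex(x$colour), nrow(x$pixels)))
  invisible(x)
}

# 8-connectivity test by component growth over the bounding box
.is_connected8 <- function(pixels) {
  n <- nrow(pixels)
  if (n == 1L) return(TRUE)
  r0 <- min(pixels[, 1L]); c0 <- min(pixels[, 2L])
  nr <- max(pixels[, 1L]) - r0 + 1L
  nc <- max(pixels[, 2L]) - c0 + 1L
  inmask <- matrix(FALSE, nr, nc)
  inmask[cbind(pixels[, 1L] - r0 + 1L, pixels[, 2L] - c0 + 1L)] <- TRUE
  seen <- matrix(FALSE, nr, nc)
  start <- which(inmask)[1L]
  seen[start] <- TRUE
  frontier <- matrix(c((start - 1L) %% nr + 1L, (start - 1L) %/% nr + 1L), 1L)
  offs <- cbind(rep(-1:1, 3L), rep(-1:1, each = 3L))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  while (nrow(frontier)) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
      cbind(frontier[, 1L] + offs[k, 1L], frontier[, 2L] + offs[k, 2L])
    }))
    keep <- cand[, 1L] >= 1L & cand[, 1L] <= nr &
      cand[, 2L] >= 1L & cand[, 2L] <= nc
    cand <- unique(cand[keep, , drop = FALSE])
    if (!nrow(cand)) break
    new <- inmask[cand] & !seen[cand]
    cand <- cand[new, , drop = FALSE]
    if (!nrow(cand)) break
    seen[cand] <- TRUE
    frontier <- cand
  }
  sum(seen) == n
}

#' Validate a lesion mask
#'
#' Checks the instrument's masking rules: the mask must comprise at least
#' two pixels and form a single connected area, where horizontal, vertical
#' and diagonal pixel connections all count (8-connectivity). Violations
#' are returned as data so a whole scan's masks can be reported at once.
#'
#' @param mask A [lesion_mask()].
#' @return Character vector of violations; `character(0)` if valid.
#' @export
#' @examples
#' validate_mask(lesion_mask(rbind(c(0, 0), c(1, 1)), c(255, 0, 0)))  # valid
#' validate_mask(lesion_mask(rbind(c(0, 0), c(0, 2)), c(255, 0, 0)))  # gap
validate_mask <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  v <- character(0)
  if (nrow(mask$pixels) < 2L) {
    v <- c(v, sprintf("mask %s: below minimal size of 2 pixels (has %d)",
                      colour_hex(mask$colour), nrow(mask$pixels)))
  }
  if (!.is_connected8(mask$pixels)) {
    v <- c(v, sprintf("mask %s: pixel set is not 8-connected",
                      colour_hex(mask$colour)))
  }
  v
}

# normalise an RGB overlay array to integer 0..255 channels
.overlay_channels <- function(overlay) {
  if (length(dim(overlay)) != 3L || dim(overlay)[3L] < 3L) {
    stop("overlay must be an RGB array (rows x cols x 3)")
  }
  ov <- overlay[, , 1:3, drop = FALSE]
  if (max(ov) <= 1) ov <- ov * 255
  storage.mode(ov) <- "integer"
  ov
}

#' Extract colour lesion masks from an annotated overlay
#'
#' A pixel belongs to some mask iff its R, G, B values are not all equal;
#' pixels are grouped by exact colour (zero per-channel tolerance, so two
#' touching confluent lesions delineated in different colours are never
#' merged) and each colour yields one mask. Every extracted mask must pass
#' [validate_mask()]; a colour whose pixels are disconnected or fewer than
#' two is an error naming that colour. Masks are returned sorted by
#' (min col, min row, colour bytes) for determinism.
#'
#' @param overlay RGB array (rows x cols x 3), values in 0..1 or 0..255.
#' @param base Optional greyscale base image; when supplied, its shape must
#'   match the overlay's.
#' @param scan_id Scan identifier attached to the masks.
#' @return List of [lesion_mask()] objects (possibly empty).
#' @export
extract_masks <- function(overlay, base = NULL, scan_id = "scan") {
  ov <- .overlay_channels(overlay)
  if (!is.null(base)) {
    if (!all(dim(base)[1:2] == dim(ov)[1:2])) {
      stop("overlay and base image shapes differ")
    }
  }
  r <- ov[, , 1L]; g <- ov[, , 2L]; b <- ov[, , 3L]
  coloured <- which(r != g | g != b)
  if (!length(coloured)) return(list())
  nr <- nrow(r)
  rows <- (coloured - 1L) %% nr          # 0-based
  cols <- (coloured - 1L) %/% nr
  key <- r[coloured] * 65536L + g[coloured] * 256L + b[coloured]
  masks <- lapply(split(seq_along(key), key), function(idx) {
    col3 <- c(r[coloured[idx[1L]]], g[coloured[idx[1L]]], b[coloured[idx[1L]]])
    m <- lesion_mask(cbind(rows[idx], cols[idx]), col3, scan_id = scan_id)
    viol <- validate_mask(m)
    if (length(viol)) {
      stop(sprintf("invalid mask for colour %s: %s",
                   colour_hex(col3), paste(viol, collapse = "; ")))
    }
    m
  })
  ord <- order(
    vapply(masks, function(m) min(m$pixels[, 2L]), 0L),
    vapply(masks, function(m) min(m$pixels[, 1L]), 0L),
    vapply(masks, function(m) sum(m$colour * c(65536, 256, 1)), 0)
  )
  unname(masks[ord])
}

#' Render lesion masks onto a greyscale B-scan
#'
#' Produces the annotated overlay image: the base image replicated into
#' RGB with each mask's pixels painted in its (hard-edged, un-blended)
#' colour. Masks on one scan must be pairwise disjoint.
#'
#' @param grey Greyscale matrix, values 0..255.
#' @param masks List of [lesion_mask()] objects.
#' @return RGB array (rows x cols x 3) of integers 0..255.
#' @export
render_masks <- function(grey, masks) {
  stopifnot(is.matrix(grey))
  ov <- array(as.integer(grey), dim = c(nrow(grey), ncol(grey), 3L))
  painted <- matrix(FALSE, nrow(grey), ncol(grey))
  for (m in masks) {
    idx <- cbind(m$pixels[, 1L] + 1L, m$pixels[, 2L] + 1L)
    if (any(idx[, 1L] > nrow(grey)) || any(idx[, 2L] > ncol(grey))) {
      stop("mask ", m$lesion_id, " extends beyond the image")
    }
    if (any(painted[idx])) {
      stop("masks overlap at scan ", m$scan_id, "; lesion masks must be disjoint")
    }
    painted[idx] <- TRUE
    for (ch in 1:3) {
      plane <- ov[, , ch]
      plane[idx] <- m$colour[ch]
      ov[, , ch] <- plane
    }
  }
  ov
}

#' Measure lesion morphometrics from a mask
#'
#' Derives the geometrical properties of a lesion: cutting area (pixel
#' count), projected diameter (lateral extent in columns, max - min + 1,
#' matching the fundus-projection convention) and the real-valued centroid.
#' Micrometre values use the scan calibration exactly:
#' `area_um2 = area_px * pixel_width * pixel_depth` and
#' `diameter_um = diameter_px * pixel_width`.
#'
#' @param mask A valid [lesion_mask()].
#' @param calib A [scan_calibration()].
#' @return Object of class `lesion_geometry` with fields `area_px`,
#'   `area_um2`, `diameter_px`, `diameter_um`, `centroid_row`,
#'   `centroid_col`, plus the mask's identifiers.
#' @export
#' @examples
#' m <- lesion_mask(as.matrix(expand.grid(row = 0:2, col = 10:12)),
#'                  c(255, 0, 0))
#' measure_geometry(m, scan_calibration(11.27, 3.87))
measure_geometry <- function(mask, calib) {
  viol <- validate_mask(mask)
  if (length(viol)) {
    stop("invalid mask: ", paste(viol, collapse = "; "))
  }
  stopifnot(inherits(calib, "scan_calibration"))
  px <- mask$pixels
  area_px <- nrow(px)
  diameter_px <- max(px[, 2L]) - min(px[, 2L]) + 1L
  structure(list(
    scan_id = mask$scan_id,
    lesion_id = mask$lesion_id,
    colour = colour_hex(mask$colour),
    area_px = area_px,
    area_um2 = area_px * calib$pixel_width_um * calib$pixel_depth_um,
    diameter_px = diameter_px,
    diameter_um = diameter_px * calib$pixel_width_um,
    centroid_row = mean(px[, 1L]),
    centroid_col = mean(px[, 2L])
  ), class = "lesion_geometry")
}

#' @export
print.lesion_geometry <- function(x, ...) {
  cat(sprintf(
    "<lesion_geometry> %s / %s: area %d px (%.1f um^2), diameter %d px (%.1f um), centroid (%.2f, %.2f)\n",
    x$scan_id, x$lesion_id, x$area_px, x$area_um2,
    x$diameter_px, x$diameter_um, x$centroid_row, x$centroid_col))
  invisible(x)
}

#' Tabulate geometries of several masks
#'
#' @param masks List of valid [lesion_mask()] objects.
#' @param calib A [scan_calibration()] shared by the scan.
#' @return Data.frame with one row per mask: scan_id, lesion_id, colour,
#'   area_px, area_um2, diameter_px, diameter_um, centroid_row,
#'   centroid_col (centroids reported to 2 decimals).
#' @export
geometry_table <- function(masks, calib) {
  rows <- lapply(masks, function(m) {
    gtr <- measure_geometry(m, calib)
    data.frame(scan_id = gtr$scan_id, lesion_id = gtr$lesion_id,
               colour = gtr$colour, area_px = gtr$area_px,
               area_um2 = gtr$area_um2, diameter_px = gtr$diameter_px,
               diameter_um = gtr$diameter_um,
               centroid_row = round(gtr$centroid_row, 2),
               centroid_col = round(gtr$centroid_col, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Export masks as per-lesion run-length JSON
#'
#' Each mask is stored as its colour plus row-wise runs
#' `[row, col_start, length]` (0-based), a compact loss-free encoding.
#'
#' @param masks List of [lesion_mask()] objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_masks_json <- function(masks, path) {
  enc <- lapply(masks, function(m) {
    px <- m$pixels
    by_row <- split(px[, 2L], px[, 1L])
    runs <- do.call(rbind, lapply(names(by_row), function(rw) {
      cc <- sort(by_row[[rw]])
      brk <- c(0L, which(diff(cc) > 1L), length(cc))
      do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
        seg <- cc[(brk[i] + 1L):brk[i + 1L]]
        c(as.integer(rw), seg[1L], length(seg))
      }))
    }))
    colnames(runs) <- c("row", "col_start", "length")
    list(scan_id = m$scan_id, lesion_id = m$lesion_id,
         colour = as.integer(m$colour),
         runs = as.data.frame(runs))
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read masks back from run-length JSON
#'
#' @param path JSON path written by [write_masks_json()].
#' @return List of [lesion_mask()] objects.
#' @export
read_masks_json <- function(path) {
  enc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(enc, function(e) {
    runs <- do.call(rbind, lapply(e$runs, function(rn) {
      c(rn$row, rn$col_start, rn$length)
    }))
    px <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
      cbind(runs[i, 1L], runs[i, 2L] + seq_len(runs[i, 3L]) - 1L)
    }))
    lesion_mask(px, unlist(e$colour), scan_id = e$scan_id,
                lesion_id = e$lesion_id)
  })
}
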