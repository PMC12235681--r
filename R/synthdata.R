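# Seeded generator of synthetic OCT B-scans with ground truth, so that
# masking, measurement, classification and the cohort statistics can be
# exercised end-to-end without any real scans. The phantom is a five-band
# outer-retina model (ELM, EZ, IZ, RPE, BM as horizontal reflectivity
# bands) into which lesions are injected as hard-edged shapes: drusen as
# dome-shaped deposits between Bruch's membrane and an upward-deformed
# RPE, SDDs as mounds on top of an undisturbed RPE, hyper-reflective foci
# as bright blobs. Speckle is emulated as multiplicative log-normal noise
# on reflectivity before fourth-root rescaling -- a pragmatic stand-in,
# not a physical OCT speckle model.

#' Synthetic outer-retina model
#'
#' Band positions are 0-based top rows; rows increase with depth, so the
#' bands must appear in anatomical order ELM < EZ < IZ < RPE < BM. The
#' defaults place the outer-retinal complex in the lower part of a
#' 496 x 512 B-scan with reflectivities echoing the familiar appearance
#' (bright EZ and RPE, faint ELM/IZ/BM).
#'
#' @param n_rows,n_cols Image size; the common Spectralis B-scan format is
#'   496 x 512.
#' @param band_rows Named integer vector of top rows for elm, ez, iz, rpe,
#'   bm (strictly increasing).
#' @param band_thickness Named integer vector of band thicknesses in rows.
#' @param band_reflectivity Named numeric vector of reflectivities in
#'   (0, 1].
#' @param background_reflectivity Background reflectivity in (0, 1).
#' @param speckle_sdlog Standard deviation of the log-normal multiplicative
#'   speckle (0 disables noise).
#' @return Object of class `retina_model`.
#' @export
retina_model <- function(n_rows = 496L, n_cols = 512L,
                         band_rows = c(elm = 330L, ez = 340L, iz = 350L,
                                       rpe = 356L, bm = 361L),
                         band_thickness = c(elm = 2L, ez = 4L, iz = 3L,
                                            rpe = 5L, bm = 2L),
                         band_reflectivity = c(elm = 0.35, ez = 0.85,
                                               iz = 0.40, rpe = 0.95,
                                               bm = 0.30),
                         background_reflectivity = 0.03,
                         speckle_sdlog = 0.25) {
  bands <- c("elm", "ez", "iz", "rpe", "bm")
  stopifnot(all(bands %in% names(band_rows)),
            all(bands %in% names(band_thickness)),
            all(bands %in% names(band_reflectivity)))
  if (any(diff(band_rows[bands]) <= 0)) {
    stop("band rows must be strictly increasing in depth (elm < ez < iz < rpe < bm)")
  }
  stopifnot(all(band_reflectivity > 0), all(band_reflectivity <= 1),
            background_reflectivity > 0, background_reflectivity < 1,
            speckle_sdlog >= 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 band_rows = band_rows[bands],
                 band_thickness = band_thickness[bands],
                 band_reflectivity = band_reflectivity[bands],
                 background_reflectivity = background_reflectivity,
                 speckle_sdlog = speckle_sdlog),
            class = "retina_model")
}

.BRIGHTNESS_REFLECTIVITY <- c(LOW = 0.30, MODERATE = 0.55, HIGH = 0.90)

#' Specify one synthetic lesion
#'
#' @param type One of `"DRUSEN"`, `"SDD"`, `"HYPERREFLECTIVE_ONLY"`.
#' @param centre_col Central column of the lesion footprint (0-based).
#' @param diameter_um Projected diameter in micrometres; converted to a
#'   pixel footprint with the scan's pixel width (at least 2 columns).
#' @param height_aspect Peak height as a fraction of the pixel footprint
#'   width; defaults to 0.4 for drusen, 0.3 for SDDs, 0.5 for foci.
#' @param brightness Brightness class driving the deposit reflectivity.
#' @param confluent Mark the lesion confluent (SP-01); overlapping
#'   footprints are only permitted between lesions that are both
#'   confluent.
#' @param rpe_state Layer state recorded for the outer RPE; defaults to
#'   `BENT_UP` for drusen, `UNCHANGED` for SDDs, `BENT_UP` for foci. Must
#'   stay consistent with the type (`BENT_UP`/`DISRUPTED` for drusen,
#'   `BENT_DOWN`/`UNCHANGED` for SDDs).
#' @return Object of class `lesion_spec`.
#' @export
lesion_spec <- function(type, centre_col, diameter_um,
                        height_aspect = NULL,
                        brightness = "MODERATE",
                        confluent = FALSE,
                        rpe_state = NULL) {
  type <- match.arg(type, c("DRUSEN", "SDD", "HYPERREFLECTIVE_ONLY"))
  stopifnot(diameter_um > 0)
  if (is.null(height_aspect)) {
    height_aspect <- switch(type, DRUSEN = 0.4, SDD = 0.3,
                            HYPERREFLECTIVE_ONLY = 0.5)
  }
  if (is.null(rpe_state)) {
    rpe_state <- switch(type, DRUSEN = "BENT_UP", SDD = "UNCHANGED",
                        HYPERREFLECTIVE_ONLY = "BENT_UP")
  }
  allowed <- switch(type,
    DRUSEN = c("BENT_UP", "DISRUPTED"),
    SDD = c("BENT_DOWN", "UNCHANGED"),
    HYPERREFLECTIVE_ONLY = LAYER_STATES
  )
  if (!(rpe_state %in% allowed)) {
    stop("rpe_state ", rpe_state, " inconsistent with lesion type ", type)
  }
  stopifnot(brightness %in% names(.BRIGHTNESS_REFLECTIVITY))
  structure(list(type = type, centre_col = as.integer(centre_col),
                 diameter_um = diameter_um, height_aspect = height_aspect,
                 brightness = brightness, confluent = confluent,
                 rpe_state = rpe_state),
            class = "lesion_spec")
}

# pixel footprint of a spec under a calibration: columns (0-based) and
# per-column elevation in rows (half-ellipse profile, >= 1 everywhere so
# the mask spans exactly the nominal footprint width)
.lesion_footprint <- function(spec, calib, n_cols) {
  w <- max(2L, as.integer(round(spec$diameter_um / calib$pixel_width_um)))
  h <- max(1L, as.integer(round(w * spec$height_aspect)))
  first <- spec$centre_col - (w - 1L) %/% 2L
  cols <- first + 0:(w - 1L)
  if (first < 0L || cols[w] >= n_cols) {
    stop("lesion footprint at columns ", first, "..", cols[w],
         " does not fit the ", n_cols, "-column field")
  }
  t <- (cols - mean(cols)) / (w / 2)
  elev <- pmax(1L, as.integer(round(h * sqrt(pmax(0, 1 - t^2)))))
  list(cols = cols, elev = elev, width = w, height = h)
}

.truth_record <- function(spec, scan_id, lesion_id) {
  states <- switch(spec$type,
    DRUSEN = list(elm = "BENT_UP", ez = "BENT_UP", iz = "BENT_UP",
                  rpe = spec$rpe_state, bm = "UNCHANGED"),
    SDD = list(elm = "BENT_UP", ez = "BENT_UP", iz = "BENT_UP",
               rpe = spec$rpe_state, bm = "UNCHANGED"),
    HYPERREFLECTIVE_ONLY = list(elm = "BENT_UP", ez = "BENT_UP",
                                iz = "BENT_UP", rpe = spec$rpe_state,
                                bm = "UNCHANGED")
  )
  grading_record(
    scan_id = scan_id, lesion_id = lesion_id,
    scan_gradable = TRUE,
    elm = states$elm, ez = states$ez, iz = states$iz,
    rpe = states$rpe, bm = states$bm,
    iz_rpe_separable = spec$type != "DRUSEN",
    brightness = if (spec$type == "HYPERREFLECTIVE_ONLY") "HIGH"
    else spec$brightness,
    confluent = isTRUE(spec$confluent),
    hyperreflective_only = spec$type == "HYPERREFLECTIVE_ONLY"
  )
}

#' Colour palette for lesion masks
#'
#' Distinct saturated (never grey) RGB colours for up to `n` lesions on one
#' scan, deterministic in `n`.
#'
#' @param n Number of colours.
#' @return n x 3 integer matrix of RGB values in 0..255.
#' @export
mask_palette <- function(n) {
  hex <- grDevices::rainbow(n, s = 1, v = 1)
  t(grDevices::col2rgb(hex))
}

#' Generate one synthetic B-scan with ground truth
#'
#' Renders the band model, injects the specified lesions, applies
#' multiplicative speckle and fourth-root greyscale conversion, and emits
#' exact ground truth: the pixel set and colour of every lesion mask, a
#' consistent auto-filled grading record per lesion (whose LAY-04 state
#' reproduces the injected type under [classify_lesion()]), and the truth
#' geometry. Deterministic for a fixed seed.
#'
#' Footprints of two lesions may overlap in column range only when both
#' are marked confluent; the overlap is then delineated by assigning each
#' contested column to the nearer lesion centre, so masks stay disjoint
#' and connected. Anything else is rejected.
#'
#' @param model A [retina_model()].
#' @param lesions List of [lesion_spec()] objects.
#' @param calib A [scan_calibration()].
#' @param seed Integer seed; `NULL` continues from the current RNG state.
#' @param scan_id Identifier stamped on masks and records.
#' @param render Render the grey image (set `FALSE` for truth-only output).
#' @return Object of class `synthetic_scan`: `grey` (8-bit matrix),
#'   `masks` (list of [lesion_mask()]), `records` (list of
#'   [grading_record()]), `geometry` (truth data.frame), `calib`,
#'   `scan_id`, `seed`.
#' @export
#' @examples
#' sc <- generate_bscan(retina_model(), list(
#'   lesion_spec("DRUSEN", centre_col = 200, diameter_um = 180)
#' ), scan_calibration(11.27, 3.87), seed = 7)
#' length(sc$masks)
generate_bscan <- function(model, lesions, calib, seed = NULL,
                           scan_id = "synthetic", render = TRUE) {
  stopifnot(inherits(model, "retina_model"),
            inherits(calib, "scan_calibration"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(lesions)
  fps <- lapply(lesions, .lesion_footprint, calib = calib,
                n_cols = model$n_cols)

  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (max(min(fps[[i]]$cols), min(fps[[j]]$cols)) <=
          min(max(fps[[i]]$cols), max(fps[[j]]$cols))) {
        if (!(isTRUE(lesions[[i]]$confluent) && isTRUE(lesions[[j]]$confluent))) {
          stop(sprintf(
            "footprints of lesions %d and %d overlap but both are not marked confluent",
            i, j))
        }
      }
    }
  }

  # column ownership within each type group: contested columns go to the
  # nearer lesion centre
  owner_cols <- vector("list", n)
  for (i in seq_len(n)) owner_cols[[i]] <- fps[[i]]$cols
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (lesions[[i]]$type != lesions[[j]]$type) next
      shared <- intersect(owner_cols[[i]], owner_cols[[j]])
      if (!length(shared)) next
      di <- abs(shared - lesions[[i]]$centre_col)
      dj <- abs(shared - lesions[[j]]$centre_col)
      to_j <- shared[dj < di]
      to_i <- setdiff(shared, to_j)
      owner_cols[[i]] <- setdiff(owner_cols[[i]], to_j)
      owner_cols[[j]] <- setdiff(owner_cols[[j]], to_i)
    }
  }

  br <- model$band_rows; bt <- model$band_thickness
  # per-column elevations (columns indexed 1..n_cols for row vectors)
  e_dru <- integer(model$n_cols)
  e_sdd <- integer(model$n_cols)
  for (i in seq_len(n)) {
    fp <- fps[[i]]
    idx <- fp$cols + 1L
    if (lesions[[i]]$type == "DRUSEN") {
      e_dru[idx] <- pmax(e_dru[idx], fp$elev)
    } else if (lesions[[i]]$type == "SDD") {
      e_sdd[idx] <- pmax(e_sdd[idx], fp$elev)
    }
  }

  # truth mask pixel sets
  colours <- mask_palette(max(n, 1L))
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- lesions[[i]]
    cols0 <- owner_cols[[i]]
    fp <- fps[[i]]
    elev <- fp$elev[match(cols0, fp$cols)]
    if (sp$type == "DRUSEN") {
      # deposit fills the wedge opened between lifted RPE bottom and BM top
      px <- do.call(rbind, lapply(seq_along(cols0), function(k) {
        rows <- (br[["bm"]] - elev[k]):(br[["bm"]] - 1L)
        cbind(rows, cols0[k])
      }))
    } else if (sp$type == "SDD") {
      # mound on top of the (undisturbed) RPE
      px <- do.call(rbind, lapply(seq_along(cols0), function(k) {
        rows <- (br[["rpe"]] - elev[k]):(br[["rpe"]] - 1L)
        cbind(rows, cols0[k])
      }))
    } else {
      # solid half-height ellipse blob straddling the EZ/IZ region
      cr <- br[["ez"]] - 4L
      h2 <- max(1L, fp$height %/% 2L)
      px <- do.call(rbind, lapply(seq_along(cols0), function(k) {
        dh <- max(1L, as.integer(round(h2 * elev[k] / max(fp$elev))))
        cbind((cr - dh):(cr + dh), cols0[k])
      }))
    }
    masks[[i]] <- lesion_mask(px, colours[i, ], scan_id = scan_id,
                              lesion_id = paste0("L", i))
  }

  # pairwise disjointness (cross-type collisions would be a model error)
  if (n > 1L) {
    keys <- lapply(masks, function(m) m$pixels[, 1L] * model$n_cols + m$pixels[, 2L])
    all_keys <- unlist(keys)
    if (anyDuplicated(all_keys)) stop("internal error: generated masks overlap")
  }

  records <- lapply(seq_len(n), function(i) {
    .truth_record(lesions[[i]], scan_id, paste0("L", i))
  })

  geometry <- if (n) do.call(rbind, lapply(seq_len(n), function(i) {
    px <- masks[[i]]$pixels
    dpx <- max(px[, 2L]) - min(px[, 2L]) + 1L
    data.frame(scan_id = scan_id, lesion_id = paste0("L", i),
               lesion_type = lesions[[i]]$type,
               area_px = nrow(px),
               area_um2 = nrow(px) * calib$pixel_width_um * calib$pixel_depth_um,
               diameter_px = dpx,
               diameter_um = dpx * calib$pixel_width_um,
               centroid_row = mean(px[, 1L]),
               centroid_col = mean(px[, 2L]),
               stringsAsFactors = FALSE)
  })) else data.frame()

  grey <- NULL
  if (render) {
    refl <- matrix(model$background_reflectivity, model$n_rows, model$n_cols)
    shift_upper <- e_dru + e_sdd     # ELM, EZ, IZ ride on both deposits
    shift_rpe <- e_dru
    for (x in seq_len(model$n_cols)) {
      for (b in c("elm", "ez", "iz", "rpe", "bm")) {
        sh <- switch(b, elm = , ez = , iz = shift_upper[x],
                     rpe = shift_rpe[x], bm = 0L)
        top <- br[[b]] - sh
        rows <- (top:(top + bt[[b]] - 1L)) + 1L
        rows <- rows[rows >= 1L & rows <= model$n_rows]
        refl[rows, x] <- model$band_reflectivity[[b]]
      }
    }
    for (i in seq_len(n)) {
      dep_refl <- if (lesions[[i]]$type == "HYPERREFLECTIVE_ONLY") 0.98
      else .BRIGHTNESS_REFLECTIVITY[[
        if (lesions[[i]]$type == "HYPERREFLECTIVE_ONLY") "HIGH"
        else lesions[[i]]$brightness]]
      idx <- cbind(masks[[i]]$pixels[, 1L] + 1L, masks[[i]]$pixels[, 2L] + 1L)
      refl[idx] <- dep_refl
    }
    if (model$speckle_sdlog > 0) {
      refl <- refl * exp(stats::rnorm(length(refl), 0, model$speckle_sdlog))
    }
    raw <- refl^4
    grey <- fourth_root_rescale(raw, reference_max = "scan")
  }

  structure(list(grey = grey, masks = masks, records = records,
                 geometry = geometry, calib = calib, scan_id = scan_id,
                 seed = seed),
            class = "synthetic_scan")
}

#' @export
print.synthetic_scan <- function(x, ...) {
  cat(sprintf("<synthetic_scan> %s: %d lesion(s)%s\n", x$scan_id,
              length(x$masks), if (is.null(x$grey)) " (not rendered)" else ""))
  invisible(x)
}

#' Draw lesion diameters from the cohort size distribution
#'
#' Log-normal diameters in micrometres. The defaults emulate the observed
#' early-AMD size scale: median about 155 um (meanlog `log(154.8)`) with
#' sdlog 0.6.
#'
#' @param n Number of draws.
#' @param meanlog,sdlog Log-scale parameters; `sdlog >= 0`.
#' @return Numeric vector of diameters (um).
#' @export
sample_lesion_diameters <- function(n, meanlog = log(154.8), sdlog = 0.6) {
  if (sdlog < 0) stop("sdlog must be non-negative")
  stats::rlnorm(n, meanlog, sdlog)
}

#' Generate a synthetic grading cohort
#'
#' Emulates a consecutive sample of early-AMD patients, one leading B-scan
#' per patient: per-scan lesion counts with a mean just under two lesions
#' per scan, lesion types drawn from the operational drusen : SDD :
#' hyper-reflective-focus mix, log-normal diameters, per-scan pixel widths
#' scattered around 11.27 um at fixed 3.87 um depth, and occasional
#' confluent pairs rendered in touching but distinct colours. Full ground
#' truth (masks, records, geometry) is emitted; everything is reproducible
#' from the single seed.
#'
#' @param n_patients Number of patients (one scan each), >= 1.
#' @param size_distribution Numeric `c(meanlog, sdlog)` of the diameter
#'   distribution in um.
#' @param type_mix Named proportions over DRUSEN, SDD,
#'   HYPERREFLECTIVE_ONLY (need not be normalised; must be non-negative
#'   and sum to a positive value).
#' @param mean_lesions_per_scan Expected lesions per scan; counts are
#'   `1 + Poisson(mean - 1)`.
#' @param pixel_width_mean,pixel_width_sd Per-scan lateral calibration
#'   distribution (um); depth is fixed.
#' @param pixel_depth_um Axial calibration (um).
#' @param confluent_prob Probability that a scan with >= 2 lesions carries
#'   a confluent (touching) pair; the default makes about a fifth of all
#'   lesions confluent.
#' @param seed Integer seed.
#' @param render Render grey images (set `FALSE` to generate only masks,
#'   records and geometry, which is much faster).
#' @return Object of class `synthetic_cohort`: `scans` (list of
#'   [generate_bscan()] results), `records` (flat list), `geometry`
#'   (data.frame of truth values incl. `lesion_type`), `manifest`.
#' @export
generate_cohort <- function(n_patients = 100L,
                            size_distribution = c(meanlog = log(154.8),
                                                  sdlog = 0.6),
                            type_mix = c(DRUSEN = 142, SDD = 54,
                                         HYPERREFLECTIVE_ONLY = 1),
                            mean_lesions_per_scan = 1.98,
                            pixel_width_mean = 11.27,
                            pixel_width_sd = 0.3,
                            pixel_depth_um = 3.87,
                            confluent_prob = 0.35,
                            seed = 1L,
                            render = TRUE) {
  stopifnot(n_patients >= 1L, mean_lesions_per_scan >= 1)
  meanlog <- size_distribution[[1]]
  sdlog <- size_distribution[[2]]
  if (sdlog < 0) stop("sdlog must be non-negative")
  stopifnot(all(type_mix >= 0), sum(type_mix) > 0,
            all(names(type_mix) %in%
                  c("DRUSEN", "SDD", "HYPERREFLECTIVE_ONLY")))
  set.seed(seed)
  scan_seeds <- sample.int(.Machine$integer.max - 1L, n_patients)

  model <- retina_model()
  max_w_px <- 120L   # footprint cap so every lesion fits the field

  scans <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    set.seed(scan_seeds[p])
    scan_id <- sprintf("P%03d", p)
    n_les <- 1L + stats::rpois(1L, mean_lesions_per_scan - 1)
    width_um <- max(5, stats::rnorm(1L, pixel_width_mean, pixel_width_sd))
    calib <- scan_calibration(width_um, pixel_depth_um)
    types <- sample(names(type_mix), n_les, replace = TRUE,
                    prob = type_mix / sum(type_mix))
    diam <- sample_lesion_diameters(n_les, meanlog, sdlog)
    w_px <- pmin(max_w_px, pmax(2L, as.integer(round(diam / width_um))))

    confl <- rep(FALSE, n_les)
    pair_gap0 <- rep(FALSE, n_les)   # TRUE: this lesion touches its predecessor
    if (n_les >= 2L && stats::runif(1) < confluent_prob) {
      k <- if (n_les == 2L) 2L else sample(2:n_les, 1L)
      confl[c(k - 1L, k)] <- TRUE
      pair_gap0[k] <- TRUE
    }

    # sequential placement left to right with random gaps
    min_gap <- ifelse(pair_gap0, 0L, 2L)
    slack <- model$n_cols - 2L - sum(w_px) - sum(min_gap[-1L])
    if (slack < 0) stop("lesions do not fit the scan field; reduce sizes or count")
    cuts <- sort(stats::runif(n_les, 0, 1))
    starts <- integer(n_les)
    pos <- 1L + as.integer(floor(cuts[1L] * slack / n_les))
    for (i in seq_len(n_les)) {
      if (i > 1L) {
        extra <- as.integer(floor(stats::runif(1) * slack / (2 * n_les)))
        pos <- pos + min_gap[i] + if (pair_gap0[i]) 0L else extra
      }
      starts[i] <- pos
      pos <- pos + w_px[i]
    }

    specs <- lapply(seq_len(n_les), function(i) {
      bri <- sample(c("LOW", "MODERATE", "HIGH"), 1L,
                    prob = c(0.25, 0.6, 0.15))
      rpe_state <- switch(types[i],
        DRUSEN = sample(c("BENT_UP", "DISRUPTED"), 1L, prob = c(0.8, 0.2)),
        SDD = sample(c("UNCHANGED", "BENT_DOWN"), 1L, prob = c(0.8, 0.2)),
        HYPERREFLECTIVE_ONLY = "BENT_UP")
      lesion_spec(types[i],
                  centre_col = starts[i] + (w_px[i] - 1L) %/% 2L,
                  diameter_um = w_px[i] * width_um,
                  brightness = bri, confluent = confl[i],
                  rpe_state = rpe_state)
    })
    scans[[p]] <- generate_bscan(model, specs, calib, seed = NULL,
                                 scan_id = scan_id, render = render)
  }

  geometry <- do.call(rbind, lapply(scans, function(s) s$geometry))
  records <- unlist(lapply(scans, function(s) s$records), recursive = FALSE)
  structure(list(
    scans = scans,
    records = records,
    geometry = geometry,
    manifest = list(seed = seed, n_patients = n_patients,
                    size_distribution = c(meanlog = meanlog, sdlog = sdlog),
                    type_mix = type_mix,
                    mean_lesions_per_scan = mean_lesions_per_scan,
                    pixel_width_mean = pixel_width_mean,
                    pixel_width_sd = pixel_width_sd,
                    pixel_depth_um = pixel_depth_um,
                    confluent_prob = confluent_prob)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d lesions (seed %s)\n",
              x$manifest$n_patients, nrow(x$geometry),
              format(x$manifest$seed)))
  print(table(x$geometry$lesion_type))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Exports grey PNGs, overlay PNGs with truth masks drawn in, the records
#' CSV, the truth geometry CSV and a manifest JSON (seed and parameters).
#'
#' @param cohort A [generate_cohort()] result (rendered).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$scans) {
    if (is.null(s$grey)) stop("cohort was generated with render = FALSE")
    write_grey_image(s$grey, file.path(dir, paste0(s$scan_id, "_grey.png")))
    ov <- render_masks(s$grey, s$masks)
    png::writePNG(ov / 255, file.path(dir, paste0(s$scan_id, "_overlay.png")))
    write_calibration(s$calib, file.path(dir, paste0(s$scan_id, "_calib.json")))
  }
  write_records_csv(cohort$records, file.path(dir, "records.csv"))
  utils::write.csv(cohort$geometry, file.path(dir, "geometry_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
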