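# Operational lesion typing: drusen and subretinal drusenoid deposits
# (SDDs) are distinguished by the state of the outer RPE layer around the
# lesion (a druse sits below the RPE and pushes it up or breaks through;
# an SDD sits on top and leaves it unaffected or bent down). A lesion
# consisting of hyper-reflective material only (SP-03) is its own type and
# takes precedence over the RPE rule.

#' Lesion types
#' @format Character vector of the four operational types.
#' @export
LESION_TYPES <- c("DRUSEN", "SDD", "HYPERREFLECTIVE_ONLY", "UNGRADABLE")

#' Classify a lesion from its grading record
#'
#' Applies the operational definitions: if SP-03 is ticked the lesion is
#' `HYPERREFLECTIVE_ONLY` (precedence over the layer rule); otherwise an
#' RPE state of `BENT_DOWN` or `UNCHANGED` (LAY-04A/B) defines an `SDD`,
#' `BENT_UP` or `DISRUPTED` (LAY-04C/D) a `DRUSEN`, and `NOT_GRADABLE`
#' (LAY-04E) leaves the lesion `UNGRADABLE`.
#'
#' @param record A valid [grading_record()].
#' @return One of [LESION_TYPES].
#' @export
#' @examples
#' classify_lesion(grading_record("s", "L1", rpe = "BENT_UP"))   # DRUSEN
#' classify_lesion(grading_record("s", "L2", rpe = "UNCHANGED")) # SDD
classify_lesion <- function(record) {
  viol <- validate_record(record)
  if (length(viol)) {
    stop("invalid record: ", paste(viol, collapse = "; "))
  }
  if (isTRUE(record$hyperreflective_only)) return("HYPERREFLECTIVE_ONLY")
  switch(record$rpe,
    BENT_DOWN = ,
    UNCHANGED = "SDD",
    BENT_UP = ,
    DISRUPTED = "DRUSEN",
    NOT_GRADABLE = "UNGRADABLE"
  )
}

#' Select the leading drusen and leading scan of a volume
#'
#' The leading drusen is the lesion with the maximal cutting area visible
#' in any B-scan throughout the volume; the leading scan is the B-scan
#' showing it. Ties are broken by lowest scan index, then lowest lesion id.
#'
#' @param volume Data.frame with columns `scan_index`, `lesion_id`,
#'   `area_um2` — one row per (scan, lesion) pair in the volume.
#' @return Object of class `leading_selection` with `scan_index`,
#'   `lesion_id`, `area_um2`.
#' @export
#' @examples
#' vol <- data.frame(scan_index = 48, lesion_id = as.character(1:5),
#'                   area_um2 = c(2740, 1566, 2001, 7307, 3262))
#' select_leading(vol)  # lesion 4, 7307 um^2
select_leading <- function(volume) {
  stopifnot(is.data.frame(volume),
            all(c("scan_index", "lesion_id", "area_um2") %in% names(volume)))
  if (nrow(volume) == 0L) stop("volume contains no lesions")
  ord <- order(-volume$area_um2, volume$scan_index, volume$lesion_id)
  top <- volume[ord[1L], ]
  structure(list(scan_index = top$scan_index,
                 lesion_id = as.character(top$lesion_id),
                 area_um2 = top$area_um2),
            class = "leading_selection")
}

#' @export
print.leading_selection <- function(x, ...) {
  cat(sprintf("<leading_selection> scan %s, lesion %s, cutting area %.1f um^2\n",
              format(x$scan_index), x$lesion_id, x$area_um2))
  invisible(x)
}

.geom_df <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("lesion_id", "area_um2") %in% names(x)))
    data.frame(lesion_id = as.character(x$lesion_id), area_um2 = x$area_um2,
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(x, function(g) {
      data.frame(lesion_id = g$lesion_id, area_um2 = g$area_um2,
                 stringsAsFactors = FALSE)
    }))
  }
}

#' Track lesions from a baseline scan to its follow-up
#'
#' Correspondence between the two visits is given by annotation identity:
#' the grader masks a persisting lesion with the same colour (hence the
#' same `lesion_id`) at both visits. For every follow-up lesion one tracked
#' pair is produced with the area change
#' `delta_area_um2 = followup - baseline`; a follow-up lesion with no
#' baseline partner gets baseline area 0 and is expected to be graded
#' `NEW`. Baseline lesions absent at follow-up are reported with follow-up
#' area 0 (candidate remission). A follow-up record claiming growth,
#' stationarity or remission without a baseline partner is an error, since
#' those progression states require an unambiguous identification with a
#' baseline lesion.
#'
#' @param baseline,followup Lesion geometries of the two scans: either a
#'   data.frame with columns `lesion_id`, `area_um2`, or a list of
#'   [measure_geometry()] results.
#' @param followup_records Optional list of valid [grading_record()]s for
#'   the follow-up scan (matched by `lesion_id`) supplying the recorded
#'   progression state.
#' @return Data.frame of class `tracked_pairs`: `lesion_id`,
#'   `baseline_area_um2`, `followup_area_um2`, `delta_area_um2`,
#'   `matched` and `recorded_progression`.
#' @export
track_lesions <- function(baseline, followup, followup_records = NULL) {
  b <- .geom_df(baseline)
  f <- .geom_df(followup)
  if (anyDuplicated(b$lesion_id)) stop("duplicate lesion_id in baseline")
  if (anyDuplicated(f$lesion_id)) stop("duplicate lesion_id in followup")

  prog <- stats::setNames(rep("NOT_ASSESSED", nrow(f)), f$lesion_id)
  if (!is.null(followup_records)) {
    for (r in followup_records) {
      viol <- validate_record(r)
      if (length(viol)) {
        stop("invalid follow-up record ", r$lesion_id, ": ",
             paste(viol, collapse = "; "))
      }
      if (r$lesion_id %in% names(prog)) prog[r$lesion_id] <- r$progression
    }
  }

  ids <- union(f$lesion_id, b$lesion_id)
  ba <- stats::setNames(rep(0, length(ids)), ids)
  fa <- ba
  ba[b$lesion_id] <- b$area_um2
  fa[f$lesion_id] <- f$area_um2
  matched <- ids %in% b$lesion_id & ids %in% f$lesion_id

  needs_baseline <- c("GROWTH", "STATIONARY",
                      "REMISSION_LAYERS_PRESERVED",
                      "REMISSION_LAYERS_DESTROYED")
  for (id in f$lesion_id) {
    if (!(id %in% b$lesion_id) && prog[id] %in% needs_baseline) {
      stop(sprintf(
        "follow-up lesion %s graded %s but has no baseline partner", id, prog[id]))
    }
  }

  rp <- stats::setNames(rep(NA_character_, length(ids)), ids)
  rp[f$lesion_id] <- prog[f$lesion_id]
  out <- data.frame(
    lesion_id = ids,
    baseline_area_um2 = as.numeric(ba),
    followup_area_um2 = as.numeric(fa),
    delta_area_um2 = as.numeric(fa - ba),
    matched = matched,
    recorded_progression = as.character(rp),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("tracked_pairs", "data.frame")
  out
}

#' Advisory consistency check between measured change and graded progression
#'
#' Compares the relative area change of one tracked pair with the grader's
#' progression tick. With relative change `delta / baseline` and threshold
#' t, the expectation is `GROWTH` above t, `REMISSION` below -t and
#' `STATIONARY` in between; a lesion without a baseline partner is
#' expected `NEW`. The check is advisory only — a mismatch flags the pair
#' for grader review, the tick remains authoritative. `UNCLEAR` and
#' `NOT_ASSESSED` ticks are never flagged.
#'
#' @param pair One row of a [track_lesions()] result (or an equivalent
#'   list with `baseline_area_um2`, `delta_area_um2`,
#'   `recorded_progression`).
#' @param growth_threshold_fraction Relative area change regarded as
#'   noticeable; default 0.10.
#' @return List with `consistent` (logical), `expected` (progression
#'   expectation) and `message`.
#' @export
check_progression_consistency <- function(pair,
                                          growth_threshold_fraction = 0.10) {
  stopifnot(growth_threshold_fraction >= 0)
  b <- pair$baseline_area_um2
  d <- pair$delta_area_um2
  rec <- pair$recorded_progression
  if (is.null(rec) || is.na(rec)) rec <- "NOT_ASSESSED"

  if (b == 0) {
    expected <- "NEW"
  } else {
    rel <- d / b
    expected <- if (rel > growth_threshold_fraction) "GROWTH"
    else if (rel < -growth_threshold_fraction) "REMISSION"
    else "STATIONARY"
  }

  consistent <- if (rec %in% c("UNCLEAR", "NOT_ASSESSED")) {
    TRUE
  } else if (expected == "REMISSION") {
    rec %in% c("REMISSION_LAYERS_PRESERVED", "REMISSION_LAYERS_DESTROYED")
  } else {
    rec == expected
  }

  list(
    consistent = consistent,
    expected = expected,
    message = if (consistent) "recorded progression matches measured change"
    else sprintf("recorded %s but measured change suggests %s: flag for grader review",
                 rec, expected)
  )
}

#' Tabulate lesion types with their geometry for export
#'
#' @param records List of valid [grading_record()] objects.
#' @param geometries Optional data.frame from [geometry_table()] matched by
#'   `scan_id`/`lesion_id`.
#' @return Data.frame with scan_id, lesion_id, lesion_type and, when
#'   geometries are given, area_um2 and diameter_um.
#' @export
phenotype_table <- function(records, geometries = NULL) {
  out <- do.call(rbind, lapply(records, function(r) {
    data.frame(scan_id = r$scan_id, lesion_id = r$lesion_id,
               lesion_type = classify_lesion(r), stringsAsFactors = FALSE)
  }))
  if (!is.null(geometries)) {
    out <- merge(out, geometries[, c("scan_id", "lesion_id", "area_um2",
                                     "diameter_um")],
                 by = c("scan_id", "lesion_id"), all.x = TRUE, sort = FALSE)
  }
  out
}
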