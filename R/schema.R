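# ---- Controlled vocabularies --------------------------------------------

#' Layer states of the grading questionnaire
#'
#' Each of the five outer-retinal layers (ELM, EZ, IZ, RPE, BM) is graded
#' with exactly one of five states, encoded on the questionnaire as the
#' field-code suffixes A-E: bent or bulged downwards but still connected
#' (A), unchanged and intact (B), bent or bulged upwards but still
#' connected (C), disrupted or destroyed (D), or not clearly assessable (E).
#'
#' @format Named character vector mapping suffix letters to state names.
#' @export
LAYER_STATES <- c(
  A = "BENT_DOWN",
  B = "UNCHANGED",
  C = "BENT_UP",
  D = "DISRUPTED",
  E = "NOT_GRADABLE"
)

#' Brightness classes (fields BRI-01 to BRI-05)
#' @format Named character vector mapping field numbers to class names.
#' @export
BRIGHTNESS_LEVELS <- c(
  "01" = "LOW",
  "02" = "MODERATE",
  "03" = "HIGH",
  "04" = "OTHER",
  "05" = "NOT_GRADABLE"
)

#' Progression states (fields PRO-01 to PRO-06)
#'
#' Assessed only on follow-up scans graded together with their baseline.
#' A record from a scan where progression was not assessed carries
#' `NOT_ASSESSED` (no PRO field ticked).
#'
#' @format Named character vector mapping field numbers to state names.
#' @export
PROGRESSION_STATES <- c(
  "01" = "NEW",
  "02" = "GROWTH",
  "03" = "STATIONARY",
  "04" = "REMISSION_LAYERS_PRESERVED",
  "05" = "REMISSION_LAYERS_DESTROYED",
  "06" = "UNCLEAR"
)

# layer slot name -> LAY field number
.LAYER_CODES <- c(elm = "01", ez = "02", iz = "03", rpe = "04", bm = "05")

#' All questionnaire field codes, in form order
#'
#' @return Character vector of the literal field codes: GEN-01..GEN-04, the
#'   25 LAY codes, INSEP, BRI-01..BRI-05, SP-01..SP-03 and PRO-01..PRO-06.
#' @export
questionnaire_field_codes <- function() {
  c(
    paste0("GEN-0", 1:4),
    as.vector(t(outer(paste0("LAY-", .LAYER_CODES), names(LAYER_STATES), paste0))),
    "INSEP",
    paste0("BRI-", names(BRIGHTNESS_LEVELS)),
    paste0("SP-0", 1:3),
    paste0("PRO-", names(PROGRESSION_STATES))
  )
}

# ---- GradingRecord -------------------------------------------------------

#' Create a grading record for one lesion
#'
#' One completed questionnaire describes a single lesion on a single B-scan:
#' general scan properties, the state of the five surrounding outer-retinal
#' layers, whether IZ and RPE are separable around the lesion, the lesion's
#' brightness, three special flags and (for follow-up scans) a progression
#' state.
#'
#' The constructor does not reject inconsistent content: layer-state and
#' brightness slots may deliberately hold zero or several values so that a
#' mis-ticked form can be represented and reported by
#' [validate_record()]. Validation is data, not an exception.
#'
#' @param scan_id,lesion_id Identifiers; `lesion_id` links the record to a
#'   mask colour on the scan.
#' @param scan_gradable Logical, field GEN-01: scan is gradable at all.
#' @param dry_late_amd,wet_late_amd Logical, GEN-02/GEN-03: visible signs of
#'   dry/wet late AMD anywhere in the scan.
#' @param is_followup Logical, GEN-04: scan is a follow-up image assessed
#'   together with its baseline.
#' @param elm,ez,iz,rpe,bm Layer states, values of [LAYER_STATES]
#'   (LAY-01 to LAY-05).
#' @param iz_rpe_separable Field INSEP (tri-state): `TRUE` when IZ and the
#'   outer RPE layer can be clearly separated around the lesion, `FALSE`
#'   when they cannot (the INSEP box is ticked), `NA` when unassessed.
#' @param brightness One of [BRIGHTNESS_LEVELS] (BRI-01 to BRI-05).
#' @param confluent,drusen_ooze,hyperreflective_only Logical special flags
#'   SP-01 to SP-03: lesion is confluent; hyper-reflective material trails
#'   into the inner retina ("drusen ooze"); the lesion consists of
#'   hyper-reflective material only.
#' @param progression One of [PROGRESSION_STATES] or `"NOT_ASSESSED"`
#'   (no PRO field ticked). Anything other than `NOT_ASSESSED` requires
#'   `is_followup = TRUE`.
#' @return An object of class `grading_record`.
#' @seealso [validate_record()], [tabulate_occupancies()],
#'   [classify_lesion()]
#' @export
#' @examples
#' r <- grading_record(
#'   scan_id = "s1", lesion_id = "L1",
#'   elm = "UNCHANGED", ez = "BENT_UP", iz = "BENT_UP",
#'   rpe = "BENT_UP", bm = "UNCHANGED", brightness = "MODERATE"
#' )
#' validate_record(r)
grading_record <- function(scan_id, lesion_id,
                           scan_gradable = TRUE,
                           dry_late_amd = FALSE,
                           wet_late_amd = FALSE,
                           is_followup = FALSE,
                           elm = "UNCHANGED", ez = "UNCHANGED",
                           iz = "UNCHANGED", rpe = "UNCHANGED",
                           bm = "UNCHANGED",
                           iz_rpe_separable = NA,
                           brightness = "MODERATE",
                           confluent = FALSE,
                           drusen_ooze = FALSE,
                           hyperreflective_only = FALSE,
                           progression = "NOT_ASSESSED") {
  structure(
    list(
      scan_id = as.character(scan_id),
      lesion_id = as.character(lesion_id),
      scan_gradable = scan_gradable,
      dry_late_amd = dry_late_amd,
      wet_late_amd = wet_late_amd,
      is_followup = is_followup,
      elm = unname(elm), ez = unname(ez), iz = unname(iz),
      rpe = unname(rpe), bm = unname(bm),
      iz_rpe_separable = unname(iz_rpe_separable),
      brightness = unname(brightness),
      confluent = confluent,
      drusen_ooze = drusen_ooze,
      hyperreflective_only = hyperreflective_only,
      progression = unname(progression)
    ),
    class = "grading_record"
  )
}

#' @export
print.grading_record <- function(x, ...) {
  cat("<grading_record>", x$scan_id, "/", x$lesion_id, "\n")
  cat("  ticked:", paste(ticked_codes(x), collapse = " "), "\n")
  invisible(x)
}

.is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

#' Validate a grading record
#'
#' Checks a record against the questionnaire's consistency rules and
#' returns the violations as data rather than raising, so that a batch of
#' gradings can be checked and all problems reported at once. The enforced
#' rules are:
#' \itemize{
#'   \item exactly one state per layer (LAY-01 to LAY-05), drawn from
#'     [LAYER_STATES];
#'   \item exactly one brightness class (BRI-01 to BRI-05);
#'   \item exactly one progression state, which may be `NOT_ASSESSED` (no
#'     box ticked) only unconditionally; any assessed progression requires
#'     GEN-04 (follow-up) to be ticked;
#'   \item the general and special flags are single non-missing logicals,
#'     INSEP is `TRUE`/`FALSE`/`NA`;
#'   \item if the scan is not gradable (GEN-01 unticked), every
#'     lesion-level field must be unset or `NOT_GRADABLE`.
#' }
#'
#' @param record A [grading_record()].
#' @return Character vector of violation messages, each prefixed with the
#'   offending field code(s); `character(0)` when the record is valid.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "grading_record"))
  v <- character(0)

  for (slot in names(.LAYER_CODES)) {
    code <- paste0("LAY-", .LAYER_CODES[[slot]])
    val <- record[[slot]]
    if (length(val) != 1L || is.na(val) || !(val %in% LAYER_STATES)) {
      v <- c(v, sprintf(
        "%sA-%sE: exactly one state must be ticked for %s (got: %s)",
        code, code, toupper(slot),
        if (length(val)) paste(val, collapse = ", ") else "none"
      ))
    }
  }

  b <- record$brightness
  if (length(b) != 1L || is.na(b) || !(b %in% BRIGHTNESS_LEVELS)) {
    v <- c(v, sprintf(
      "BRI-01-BRI-05: exactly one brightness class must be ticked (got: %s)",
      if (length(b)) paste(b, collapse = ", ") else "none"
    ))
  }

  p <- record$progression
  if (length(p) != 1L || is.na(p) ||
      !(p %in% c(PROGRESSION_STATES, "NOT_ASSESSED"))) {
    v <- c(v, sprintf(
      "PRO-01-PRO-06: at most one progression state may be ticked (got: %s)",
      if (length(p)) paste(p, collapse = ", ") else "none"
    ))
  } else if (p != "NOT_ASSESSED" && !isTRUE(record$is_followup)) {
    v <- c(v, sprintf(
      "GEN-04/PRO-%s: progression may only be assessed on a follow-up scan",
      names(PROGRESSION_STATES)[match(p, PROGRESSION_STATES)]
    ))
  }

  flags <- c(scan_gradable = "GEN-01", dry_late_amd = "GEN-02",
             wet_late_amd = "GEN-03", is_followup = "GEN-04",
             confluent = "SP-01", drusen_ooze = "SP-02",
             hyperreflective_only = "SP-03")
  for (slot in names(flags)) {
    if (!.is_flag(record[[slot]])) {
      v <- c(v, sprintf("%s: must be a single TRUE/FALSE", flags[[slot]]))
    }
  }
  sep <- record$iz_rpe_separable
  if (!(is.logical(sep) && length(sep) == 1L)) {
    v <- c(v, "INSEP: must be TRUE, FALSE or NA (unassessed)")
  }

  if (identical(record$scan_gradable, FALSE)) {
    lesion_ok <-
      all(vapply(names(.LAYER_CODES),
                 function(s) identical(record[[s]], "NOT_GRADABLE"), TRUE)) &&
      identical(record$brightness, "NOT_GRADABLE") &&
      identical(record$confluent, FALSE) &&
      identical(record$drusen_ooze, FALSE) &&
      identical(record$hyperreflective_only, FALSE) &&
      (length(record$iz_rpe_separable) == 1L && is.na(record$iz_rpe_separable)) &&
      (identical(record$progression, "NOT_ASSESSED") ||
         identical(record$progression, "NOT_GRADABLE"))
    if (!lesion_ok) {
      v <- c(v, paste(
        "GEN-01: scan not gradable, so all lesion-level fields",
        "(LAY, INSEP, BRI, SP, PRO) must be unset or NOT_GRADABLE"
      ))
    }
  }

  v
}

#' Field codes ticked by a record
#'
#' Maps a (valid) record back to the set of literal questionnaire field
#' codes that would be marked on the printed form.
#'
#' @param record A valid [grading_record()].
#' @return Character vector of ticked field codes.
#' @export
ticked_codes <- function(record) {
  codes <- character(0)
  gen <- c("GEN-01", "GEN-02", "GEN-03", "GEN-04")
  gen_on <- c(record$scan_gradable, record$dry_late_amd,
              record$wet_late_amd, record$is_followup)
  codes <- c(codes, gen[which(vapply(gen_on, isTRUE, TRUE))])
  for (slot in names(.LAYER_CODES)) {
    val <- record[[slot]]
    if (length(val) == 1L && !is.na(val) && val %in% LAYER_STATES) {
      suffix <- names(LAYER_STATES)[match(val, LAYER_STATES)]
      codes <- c(codes, paste0("LAY-", .LAYER_CODES[[slot]], suffix))
    }
  }
  if (isFALSE(record$iz_rpe_separable)) codes <- c(codes, "INSEP")
  b <- record$brightness
  if (length(b) == 1L && b %in% BRIGHTNESS_LEVELS) {
    codes <- c(codes, paste0("BRI-", names(BRIGHTNESS_LEVELS)[match(b, BRIGHTNESS_LEVELS)]))
  }
  sp <- c("SP-01", "SP-02", "SP-03")
  sp_on <- c(record$confluent, record$drusen_ooze, record$hyperreflective_only)
  codes <- c(codes, sp[which(vapply(sp_on, isTRUE, TRUE))])
  p <- record$progression
  if (length(p) == 1L && p %in% PROGRESSION_STATES) {
    codes <- c(codes, paste0("PRO-", names(PROGRESSION_STATES)[match(p, PROGRESSION_STATES)]))
  }
  codes
}

# ---- Occupancy tabulation ------------------------------------------------

#' Tabulate field occupancies over a cohort of grading records
#'
#' Counts, for every questionnaire field code, the number of records in
#' which that field is ticked — the cohort summary a grading study reports.
#' For every layer the A-E counts sum to the number of records, as do the
#' brightness counts and (because `NOT_ASSESSED` is representable as "no
#' PRO box ticked") the progression counts plus the unassessed remainder.
#'
#' @param records List of valid [grading_record()] objects.
#' @return An object of class `occupancy_table`: a list with `counts`
#'   (named integer vector over all field codes, in form order) and
#'   `n_records`.
#' @export
#' @examples
#' recs <- list(
#'   grading_record("s1", "L1", brightness = "MODERATE"),
#'   grading_record("s1", "L2", brightness = "LOW")
#' )
#' tabulate_occupancies(recs)
tabulate_occupancies <- function(records) {
  stopifnot(is.list(records))
  for (i in seq_along(records)) {
    viol <- validate_record(records[[i]])
    if (length(viol)) {
      stop(sprintf("record %d is invalid: %s", i, paste(viol, collapse = "; ")))
    }
  }
  codes <- questionnaire_field_codes()
  counts <- stats::setNames(integer(length(codes)), codes)
  for (r in records) {
    tc <- ticked_codes(r)
    counts[tc] <- counts[tc] + 1L
  }
  structure(list(counts = counts, n_records = length(records)),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat("Occupancy table over", x$n_records, "grading records\n")
  nz <- x$counts[x$counts > 0]
  if (length(nz)) print(nz) else cat("  (no ticked fields)\n")
  invisible(x)
}

#' @export
as.data.frame.occupancy_table <- function(x, ...) {
  data.frame(field = names(x$counts), count = as.integer(x$counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- Serialization -------------------------------------------------------

#' Convert grading records to a flat table of field-code columns
#'
#' One row per lesion; columns are the literal field codes (booleans as
#' 0/1) plus `scan_id` and `lesion_id`. INSEP is 1 when IZ/RPE are
#' inseparable, 0 when separable and empty (`NA`) when unassessed.
#'
#' @param records List of valid [grading_record()] objects.
#' @return A data.frame.
#' @export
records_to_df <- function(records) {
  codes <- questionnaire_field_codes()
  n <- length(records)
  m <- matrix(0L, nrow = n, ncol = length(codes), dimnames = list(NULL, codes))
  scan_id <- character(n)
  lesion_id <- character(n)
  insep <- rep(NA_integer_, n)
  for (i in seq_along(records)) {
    r <- records[[i]]
    viol <- validate_record(r)
    if (length(viol)) {
      stop(sprintf("record %d is invalid: %s", i, paste(viol, collapse = "; ")))
    }
    m[i, ticked_codes(r)] <- 1L
    if (!is.na(r$iz_rpe_separable)) insep[i] <- as.integer(!r$iz_rpe_separable)
    scan_id[i] <- r$scan_id
    lesion_id[i] <- r$lesion_id
  }
  df <- as.data.frame(m)
  names(df) <- codes        # keep literal codes (data.frame mangles "-")
  df$INSEP <- insep
  cbind(data.frame(scan_id = scan_id, lesion_id = lesion_id,
                   stringsAsFactors = FALSE), df)
}

.parse_cell <- function(x, row, col) {
  if (is.na(x) || x == "") return(NA_integer_)
  if (!(x %in% c("0", "1", "FALSE", "TRUE"))) {
    stop(sprintf("row %d, column %s: non-boolean cell value '%s'", row, col, x))
  }
  as.integer(x %in% c("1", "TRUE"))
}

#' Parse a flat field-code table back into grading records
#'
#' Strict inverse of [records_to_df()]: malformed rows are errors naming
#' the row and column (unknown column, duplicated field code, non-boolean
#' cell, no state or several states ticked for a layer).
#'
#' @param df Data.frame with columns `scan_id`, `lesion_id` and the literal
#'   field codes.
#' @return List of [grading_record()] objects.
#' @export
df_to_records <- function(df) {
  codes <- questionnaire_field_codes()
  expected <- c("scan_id", "lesion_id", codes)
  if (anyDuplicated(names(df))) {
    stop("duplicate column(s): ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  }
  unknown <- setdiff(names(df), expected)
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(expected, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }

  lapply(seq_len(nrow(df)), function(i) {
    cell <- function(code) .parse_cell(as.character(df[[code]][i]), i, code)
    tick <- function(code) {
      x <- cell(code)
      !is.na(x) && x == 1L
    }
    pick_one <- function(prefix, suffixes, labels, what, allow_none = FALSE) {
      cols <- paste0(prefix, suffixes)
      on <- vapply(cols, tick, TRUE)
      if (sum(on) == 0L) {
        if (allow_none) return(NULL)
        stop(sprintf("row %d, columns %s-%s: no %s ticked",
                     i, cols[1], cols[length(cols)], what))
      }
      if (sum(on) > 1L) {
        stop(sprintf("row %d: several %s fields ticked (%s)",
                     i, what, paste(cols[on], collapse = ", ")))
      }
      labels[[which(on)]]
    }

    layer_vals <- lapply(names(.LAYER_CODES), function(slot) {
      pick_one(paste0("LAY-", .LAYER_CODES[[slot]]), names(LAYER_STATES),
               LAYER_STATES, paste0("layer state (", toupper(slot), ")"))
    })
    names(layer_vals) <- names(.LAYER_CODES)

    insep_raw <- cell("INSEP")
    prog <- pick_one("PRO-", names(PROGRESSION_STATES), PROGRESSION_STATES,
                     "progression", allow_none = TRUE)

    grading_record(
      scan_id = as.character(df$scan_id[i]),
      lesion_id = as.character(df$lesion_id[i]),
      scan_gradable = tick("GEN-01"),
      dry_late_amd = tick("GEN-02"),
      wet_late_amd = tick("GEN-03"),
      is_followup = tick("GEN-04"),
      elm = layer_vals$elm, ez = layer_vals$ez, iz = layer_vals$iz,
      rpe = layer_vals$rpe, bm = layer_vals$bm,
      iz_rpe_separable = if (is.na(insep_raw)) NA else insep_raw == 0L,
      brightness = pick_one("BRI-", names(BRIGHTNESS_LEVELS),
                            BRIGHTNESS_LEVELS, "brightness"),
      confluent = tick("SP-01"),
      drusen_ooze = tick("SP-02"),
      hyperreflective_only = tick("SP-03"),
      progression = if (is.null(prog)) "NOT_ASSESSED" else prog
    )
  })
}

#' Read and write grading records as CSV or JSON
#'
#' CSV: one row per lesion, header holds the literal field codes plus
#' `scan_id`/`lesion_id`, booleans as 0/1, UTF-8, RFC 4180 quoting.
#' JSON: an array of objects with the same keys. Round-trips are the
#' identity on valid records.
#'
#' @param records List of valid [grading_record()] objects.
#' @param path File path.
#' @return `read_*` return a list of records; `write_*` return `path`
#'   invisibly.
#' @name record_io
NULL

#' @rdname record_io
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records_to_df(records), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname record_io
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = character(0))
  df_to_records(df)
}

#' @rdname record_io
#' @export
write_records_json <- function(records, path) {
  df <- records_to_df(records)
  jsonlite::write_json(df, path, dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname record_io
#' @export
read_records_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  for (nm in names(df)) df[[nm]] <- as.character(df[[nm]])
  df_to_records(df)
}
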