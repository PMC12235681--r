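# Cohort-level metric phenotypes: size summaries in pixel and metric
# units, log-normal distribution fitting with Shapiro-Wilk testing on the
# log scale, and the pixel-vs-micrometre unit correlation.

#' Sample statistics of lesion sizes
#'
#' Standard order statistics and moments (minimum, median, mean, standard
#' deviation, maximum) of projected diameter and cutting area, each in
#' pixel and metric units — one row per entity, matching the layout such
#' size tables are reported in. Lesions of excluded types (by default the
#' hyper-reflective-only lesions, which have no meaningful deposit size)
#' are dropped first.
#'
#' @param geometries Data.frame with columns `diameter_px`, `diameter_um`,
#'   `area_px`, `area_um2` (e.g. from [geometry_table()]).
#' @param types Optional character vector of lesion types, parallel to the
#'   rows of `geometries`.
#' @param exclude_types Types to drop; default `"HYPERREFLECTIVE_ONLY"`.
#' @return Object of class `size_summary`: a data.frame with columns
#'   `entity`, `minimum`, `median`, `mean`, `st_dev`, `maximum`, and
#'   attribute `n` (lesions retained).
#' @export
summarize_sizes <- function(geometries, types = NULL,
                            exclude_types = "HYPERREFLECTIVE_ONLY") {
  need <- c("diameter_px", "area_px", "diameter_um", "area_um2")
  stopifnot(is.data.frame(geometries), all(need %in% names(geometries)))
  keep <- rep(TRUE, nrow(geometries))
  if (!is.null(types)) {
    stopifnot(length(types) == nrow(geometries))
    keep <- !(types %in% exclude_types)
  }
  g <- geometries[keep, , drop = FALSE]
  if (nrow(g) == 0L) stop("no lesions left after exclusion")

  entities <- c("Projected diameter (pixels)" = "diameter_px",
                "Cutting area (pixels)" = "area_px",
                "Projected diameter (um)" = "diameter_um",
                "Cutting area (um^2)" = "area_um2")
  out <- do.call(rbind, lapply(names(entities), function(nm) {
    v <- g[[entities[[nm]]]]
    data.frame(entity = nm, minimum = min(v), median = stats::median(v),
               mean = mean(v), st_dev = stats::sd(v), maximum = max(v),
               stringsAsFactors = FALSE)
  }))
  attr(out, "n") <- nrow(g)
  class(out) <- c("size_summary", "data.frame")
  out
}

#' @export
print.size_summary <- function(x, ...) {
  cat("Sample statistics for N =", attr(x, "n"), "lesions\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) round(v, 1))
  print(df, row.names = FALSE)
  invisible(x)
}

.check_positive <- function(values) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    stop("values must be positive and finite; offending index(es): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
}

#' Fit a log-normal distribution to lesion sizes
#'
#' The maximum-likelihood / method-of-moments fit on the log scale:
#' `meanlog` and `sdlog` are the sample mean and sample standard deviation
#' of `log(values)`. Goodness of fit is assessed by the Shapiro-Wilk test
#' applied to the log-transformed values (normality of logs is equivalent
#' to log-normality of the raw values, whatever the logarithm base).
#'
#' @param values Positive sizes (diameters in um, areas in um^2, ...),
#'   n >= 2. The Shapiro-Wilk fields are `NA` outside the test's supported
#'   sample range of 3..5000.
#' @return Object of class `lognormal_fit` with `meanlog`, `sdlog`, `n`,
#'   `shapiro_w`, `shapiro_p`.
#' @export
#' @examples
#' fit_lognormal(exp(c(1, 3)))  # meanlog 2, sdlog sqrt(2)
fit_lognormal <- function(values) {
  .check_positive(values)
  if (length(values) < 2L) stop("need at least 2 values")
  lv <- log(values)
  sw <- if (length(lv) >= 3L && length(lv) <= 5000L) stats::shapiro.test(lv)
  else list(statistic = NA_real_, p.value = NA_real_)
  structure(list(
    meanlog = mean(lv),
    sdlog = stats::sd(lv),
    n = length(values),
    shapiro_w = unname(sw$statistic),
    shapiro_p = sw$p.value
  ), class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, digits = 4, ...) {
  cat("Log-normal fit (n =", x$n, ")\n")
  cat(sprintf("  meanlog %.*f  sdlog %.*f  (median %.*g)\n",
              digits, x$meanlog, digits, x$sdlog, digits, exp(x$meanlog)))
  if (!is.na(x$shapiro_w)) {
    cat(sprintf("  Shapiro-Wilk on logs: W = %.*f, p = %.*g\n",
                digits, x$shapiro_w, digits, x$shapiro_p))
  }
  invisible(x)
}

#' Test a sample for log-normality
#'
#' Shapiro-Wilk test of normality applied to the natural logs of the
#' values; non-rejection at level `alpha` is read as "consistent with a
#' log-normal distribution".
#'
#' @param values Positive values, 3 <= n <= 5000 (the test's supported
#'   range).
#' @param alpha Significance level, default 0.05.
#' @return List with `decision` (`"consistent with log-normal"` or
#'   `"log-normality rejected"`), `W`, `p` and `alpha`.
#' @export
test_lognormality <- function(values, alpha = 0.05) {
  .check_positive(values)
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("sample size must be between 3 and 5000 (got ", n, ")")
  }
  sw <- stats::shapiro.test(log(values))
  list(
    decision = if (sw$p.value > alpha) "consistent with log-normal"
    else "log-normality rejected",
    W = unname(sw$statistic),
    p = sw$p.value,
    alpha = alpha
  )
}

#' Correlation between pixel and metric measurements
#'
#' Pearson product-moment correlation (with two-sided p-value) between
#' lesion sizes measured in pixels and the same sizes converted to metric
#' units. With per-scan calibration varying across a cohort the two are
#' not exactly proportional; near-perfect correlation justifies carrying
#' on the analysis in metric units only.
#'
#' @param values_px,values_um Paired numeric vectors of equal length >= 3.
#' @return List with `r`, `p`, `n`.
#' @export
unit_correlation <- function(values_px, values_um) {
  stopifnot(length(values_px) == length(values_um))
  if (length(values_px) < 3L) stop("need at least 3 pairs")
  if (stats::sd(values_px) == 0 || stats::sd(values_um) == 0) {
    stop("zero variance in one of the margins")
  }
  ct <- stats::cor.test(values_px, values_um, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(values_px))
}
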