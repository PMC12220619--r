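#' Default measurement tolerance for f
#'
#' The smallest meaningful difference in cohort outlier fraction, estimated
#' in the study from two scanning trials of aspirin tablets (a standardized
#' control) as 0.0008. Used as the default gate for pre/post comparisons;
#' [measurement_tolerance()] recomputes a tolerance from user-supplied
#' standard trials.
#'
#' @return The numeric constant 0.0008.
#' @export
default_tolerance <- function() 0.0008

#' Per-wavelength Tukey fences for a cohort matrix
#'
#' At each wavelength (column) computes the first and third quartiles over
#' the cohort's SNV-corrected scans, the interquartile range, and the Tukey
#' fences `q1 - k * iqr` and `q3 + k * iqr` (k = 1.5 by default).
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7, the spreadsheet default) unless
#' `method = "hinges"` selects Tukey hinges (`stats::fivenum`). At small
#' cohort sizes the two differ, so the choice is exposed.
#'
#' @param mat Numeric cohort matrix, scans in rows, wavelengths in columns.
#' @param k Fence multiplier (default 1.5).
#' @param method Quartile estimator: `"linear"` or `"hinges"`.
#' @param min_scans Minimum rows required for quartile estimation.
#' @return data.frame with one row per wavelength and columns
#'   `q1, q3, iqr, lower, upper`.
#' @export
compute_fences <- function(mat, k = 1.5, method = c("linear", "hinges"),
                           min_scans = 4L) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  if (nrow(mat) < min_scans) {
    stop("cohort has ", nrow(mat), " scans; at least ", min_scans,
         " are required for quartile estimation", call. = FALSE)
  }
  if (method == "linear") {
    q <- apply(mat, 2, stats::quantile, probs = c(0.25, 0.75), type = 7, names = FALSE)
  } else {
    q <- apply(mat, 2, function(col) stats::fivenum(col)[c(2, 4)])
  }
  q1 <- q[1, ]
  q3 <- q[2, ]
  iqr <- q3 - q1
  data.frame(q1 = q1, q3 = q3, iqr = iqr,
             lower = q1 - k * iqr, upper = q3 + k * iqr)
}

#' Count outlier points in a cohort matrix
#'
#' A point is an outlier iff it lies strictly beyond its wavelength's fences
#' (`value < lower` or `value > upper`); values exactly on a fence are not
#' outliers. Excursions below `1e-10` are treated as ties so that cohorts
#' that are identical up to floating-point round-off (e.g. pure-scatter scans
#' after SNV) report zero outliers.
#'
#' @param mat Cohort matrix (scans x wavelengths).
#' @param fences A fence table from [compute_fences()] with one row per
#'   wavelength of `mat`.
#' @return Integer total count of outlier points.
#' @export
count_outlier_points <- function(mat, fences) {
  mat <- as.matrix(mat)
  if (nrow(fences) != ncol(mat)) {
    stop("fence table has ", nrow(fences), " rows but the matrix has ",
         ncol(mat), " wavelengths", call. = FALSE)
  }
  eps <- 1e-10
  lower <- matrix(fences$lower, nrow = nrow(mat), ncol = ncol(mat), byrow = TRUE)
  upper <- matrix(fences$upper, nrow = nrow(mat), ncol = ncol(mat), byrow = TRUE)
  sum(mat < lower - eps | mat > upper + eps)
}

#' Cohort spectra outlier fraction f
#'
#' The study's summary statistic for a cohort of scans: each spectrum is
#' SNV-corrected, the cohort's scans are pooled into one matrix, per-wavelength
#' Tukey fences are computed over the pool, and
#' `f = (total outlier points) / (total spectra points)` with
#' `total spectra points = n_scans * n_points`. A higher f indicates a
#' younger / more heterogeneous cohort by weighted average age.
#'
#' Each scan replicate enters the pool as its own row (no per-specimen
#' averaging); `average_replicates = TRUE` averages a specimen's replicates
#' first. Aggregated cohorts must be pooled before calling this function:
#' fences are recomputed on the pool, so a pooled f is generally not the
#' scan-weighted mean of sub-cohort f values.
#'
#' @param scans A [scan_set()] of raw spectra, or a numeric matrix of raw
#'   spectra (rows = scans) when `snv = TRUE`, or of already-corrected
#'   spectra when `snv = FALSE`.
#' @param k Fence multiplier (default 1.5).
#' @param method Quartile estimator, see [compute_fences()].
#' @param min_scans Minimum scans required.
#' @param snv Apply SNV correction internally (default TRUE).
#' @param denominator SNV denominator, see [snv()].
#' @param average_replicates Average scan replicates per specimen before
#'   pooling (default FALSE: every replicate is a row).
#' @return An object of class `cohort_result`: list with `outlier_points`,
#'   `total_points`, `n_scans`, `n_points`, `k`, and `f` (full precision;
#'   report with `round(f, 4)`).
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(50 * 10), 50, 10)
#' cohort_outlier_fraction(m)$f
#' @export
cohort_outlier_fraction <- function(scans, k = 1.5,
                                    method = c("linear", "hinges"),
                                    min_scans = 4L, snv = TRUE,
                                    denominator = c("sample", "population"),
                                    average_replicates = FALSE) {
  method <- match.arg(method)
  denominator <- match.arg(denominator)
  if (inherits(scans, "scan_set")) {
    mat <- scans$absorbance
    if (average_replicates) {
      key <- paste(scans$meta$species, scans$meta$specimen_id, sep = "\r")
      mat <- rowsum(mat, key)
      mat <- mat / as.vector(table(key)[rownames(mat)])
    }
  } else {
    mat <- as.matrix(scans)
  }
  if (snv) mat <- snv_matrix(mat, denominator = denominator)
  fences <- compute_fences(mat, k = k, method = method, min_scans = min_scans)
  outliers <- count_outlier_points(mat, fences)
  total <- nrow(mat) * ncol(mat)
  structure(
    list(outlier_points = as.integer(outliers), total_points = as.integer(total),
         n_scans = nrow(mat), n_points = ncol(mat), k = k,
         f = outliers / total),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> f = %.4f (%d / %d points; %d scans x %d wavelengths, k = %g)\n",
              x$f, x$outlier_points, x$total_points, x$n_scans, x$n_points, x$k))
  invisible(x)
}

#' Measurement tolerance from repeated standard scans
#'
#' Reduces the f values of repeated scanning trials of a physical standard
#' (aspirin tablets in the study) to a single tolerance: the maximum pairwise
#' absolute difference between trial f values, rounded to 4 decimal places.
#' The published study value is 0.0008 (see [default_tolerance()]).
#'
#' @param trial_fs Numeric vector of per-trial f values (>= 2 trials).
#' @return An object of class `f_tolerance`: list with `value` (rounded) and
#'   `trials`.
#' @examples
#' measurement_tolerance(c(0.0105, 0.0113))$value  # 0.0008
#' @export
measurement_tolerance <- function(trial_fs) {
  trial_fs <- as.numeric(trial_fs)
  if (length(trial_fs) < 2L) {
    stop("at least 2 standard trials are needed to estimate a tolerance", call. = FALSE)
  }
  if (anyNA(trial_fs)) stop("trial f values must not be missing", call. = FALSE)
  value <- round(max(stats::dist(trial_fs)), 4)
  structure(list(value = value, trials = trial_fs), class = "f_tolerance")
}

#' @export
print.f_tolerance <- function(x, ...) {
  cat(sprintf("<f_tolerance> %.4f from %d trials\n", x$value, length(x$trials)))
  invisible(x)
}
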