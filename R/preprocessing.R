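#' Standard Normal Variate (SNV) scatter correction
#'
#' Standardizes a single absorbance spectrum to mean 0 and unit spread by
#' subtracting its mean and dividing by its standard deviation. SNV removes
#' per-scan multiplicative and additive scatter: `snv(a * x + b)` equals
#' `snv(x)` for any scale `a > 0` and offset `b`.
#'
#' The denominator defaults to the sample (n-1) standard deviation, the
#' common spreadsheet convention; the population (n) form is available. The
#' cohort outlier fraction is invariant to this choice because the
#' per-wavelength fences scale with the data, but intermediate values differ.
#'
#' @param x Numeric absorbance vector, length >= 2, non-constant.
#' @param denominator `"sample"` (n-1, default) or `"population"` (n).
#' @return Standardized numeric vector of the same length.
#' @examples
#' snv(c(1, 2, 3))                 # -1 0 1
#' snv(2 * c(1, 2, 3) + 10)        # identical: scatter removed
#' @export
snv <- function(x, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  x <- as.numeric(x)
  if (length(x) < 2L) stop("SNV needs at least 2 points", call. = FALSE)
  if (anyNA(x) || !all(is.finite(x))) stop("SNV input must be finite", call. = FALSE)
  s <- stats::sd(x)
  if (denominator == "population") s <- s * sqrt((length(x) - 1) / length(x))
  if (s == 0) stop("degenerate spectrum: zero variance", call. = FALSE)
  (x - mean(x)) / s
}

#' SNV-correct every scan of a cohort
#'
#' Applies [snv()] independently to each row of a [scan_set()]'s absorbance
#' matrix and returns the matrix of corrected spectra. Rows follow the scan
#' set's canonical order (species, specimen_id, scan_replicate), so any
#' permutation of the input scans yields the identical matrix.
#'
#' @param scans A [scan_set()], or a numeric matrix with one raw spectrum per
#'   row.
#' @param denominator Passed to [snv()].
#' @return Numeric matrix of SNV-corrected spectra, one row per scan.
#' @export
snv_matrix <- function(scans, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  if (inherits(scans, "scan_set")) {
    mat <- scans$absorbance
    ids <- rownames(mat)
  } else {
    mat <- as.matrix(scans)
    ids <- rownames(mat)
    if (is.null(ids)) ids <- paste0("scan", seq_len(nrow(mat)))
  }
  out <- matrix(NA_real_, nrow = nrow(mat), ncol = ncol(mat),
                dimnames = dimnames(mat))
  for (i in seq_len(nrow(mat))) {
    out[i, ] <- tryCatch(
      snv(mat[i, ], denominator = denominator),
      error = function(e) {
        stop("scan ", ids[i], ": ", conditionMessage(e), call. = FALSE)
      }
    )
  }
  out
}
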