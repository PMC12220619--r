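#' Wavelength grid for SWIR scans
#'
#' Defines the common wavelength axis every scan in an analysis must share.
#' The spectrometer used in the study resolves 3.5 nm and produces 228
#' absorbance points per scan; the instrument's exact endpoints are not fixed
#' by the resolution and point count alone, so the start wavelength is
#' configurable and defaults to 900 nm (the grid then spans 900-1694.5 nm,
#' inside the SWIR window and covering the 1210/1450 nm water bands).
#'
#' @param start_nm First wavelength in nm.
#' @param step_nm Spacing between points in nm.
#' @param n_points Number of absorbance points per scan.
#' @return An object of class `wavelength_grid`.
#' @examples
#' g <- wavelength_grid()
#' range(wavelengths(g))
#' @export
wavelength_grid <- function(start_nm = 900, step_nm = 3.5, n_points = 228L) {
  stopifnot(is.numeric(start_nm), length(start_nm) == 1L, is.finite(start_nm))
  stopifnot(is.numeric(step_nm), length(step_nm) == 1L, is.finite(step_nm))
  if (step_nm <= 0) stop("wavelength grid step must be strictly positive", call. = FALSE)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1L) {
    stop("wavelength grid needs at least one point", call. = FALSE)
  }
  structure(
    list(start_nm = start_nm, step_nm = step_nm, n_points = n_points),
    class = "wavelength_grid"
  )
}

#' @return Numeric vector of the grid's wavelengths in nm.
#' @rdname wavelength_grid
#' @param grid A `wavelength_grid`.
#' @export
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  grid$start_nm + grid$step_nm * (seq_len(grid$n_points) - 1)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  w <- wavelengths(x)
  cat(sprintf(
    "<wavelength_grid> %d points, %.6g-%.6g nm, step %.6g nm\n",
    x$n_points, w[1], w[length(w)], x$step_nm
  ))
  invisible(x)
}

#' Infer a wavelength grid from observed wavelength values
#'
#' Checks the values are strictly increasing and (approximately) uniformly
#' spaced, then returns the matching [wavelength_grid()].
#'
#' @param w Numeric vector of wavelengths in nm.
#' @return A `wavelength_grid`.
#' @export
infer_grid <- function(w) {
  w <- as.numeric(w)
  if (anyNA(w) || length(w) < 1L) stop("cannot infer grid from missing wavelengths", call. = FALSE)
  if (length(w) == 1L) return(wavelength_grid(w, 3.5, 1L))
  d <- diff(w)
  if (any(d <= 0)) stop("wavelengths must be strictly increasing", call. = FALSE)
  if (max(d) - min(d) > 1e-6 * mean(d) + 1e-9) {
    stop("wavelengths are not uniformly spaced; cannot infer a grid", call. = FALSE)
  }
  wavelength_grid(w[1], mean(d), length(w))
}

#' Collection-day classes
#'
#' `PRE` is one day before ULV adulticide application, `POST_D1` and `POST_D2`
#' are one and two days after application.
#' @return Character vector of the three valid collection-day codes.
#' @export
collection_days <- function() c("PRE", "POST_D1", "POST_D2")

#' Container for a set of SWIR scans
#'
#' A `scan_set` couples per-scan metadata with the absorbance matrix (one row
#' per scan, one column per wavelength) and the shared [wavelength_grid()].
#' Rows are kept in the canonical order (species, specimen_id, scan_replicate)
#' so that all downstream computations are order-independent.
#'
#' @param meta data.frame with columns `specimen_id`, `species`,
#'   `treatment_cycle`, `collection_day`, `scan_replicate`.
#' @param absorbance Numeric matrix, `nrow(meta)` rows by `grid$n_points`
#'   columns, all values finite.
#' @param grid A [wavelength_grid()].
#' @return An object of class `scan_set`.
#' @export
scan_set <- function(meta, absorbance, grid = wavelength_grid()) {
  stopifnot(is.data.frame(meta), inherits(grid, "wavelength_grid"))
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  req <- c("specimen_id", "species", "treatment_cycle", "collection_day", "scan_replicate")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols)) {
    stop("scan metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meta <- as.data.frame(meta)[req]
  meta$specimen_id <- as.character(meta$specimen_id)
  meta$species <- as.character(meta$species)
  meta$treatment_cycle <- as.integer(meta$treatment_cycle)
  meta$collection_day <- as.character(meta$collection_day)
  meta$scan_replicate <- as.integer(meta$scan_replicate)
  bad_day <- setdiff(unique(meta$collection_day), collection_days())
  if (length(bad_day)) {
    stop("unknown collection_day token(s): ", paste(bad_day, collapse = ", "), call. = FALSE)
  }
  if (nrow(meta) != nrow(absorbance)) {
    stop("metadata rows (", nrow(meta), ") and absorbance rows (", nrow(absorbance),
         ") disagree", call. = FALSE)
  }
  if (ncol(absorbance) != grid$n_points) {
    stop("absorbance has ", ncol(absorbance), " columns but the grid expects ",
         grid$n_points, " points", call. = FALSE)
  }
  if (nrow(absorbance) && !all(is.finite(absorbance))) {
    stop("absorbance values must all be finite", call. = FALSE)
  }
  if (any(meta$scan_replicate < 1L, na.rm = TRUE)) {
    stop("scan_replicate must be >= 1", call. = FALSE)
  }
  ord <- order(meta$species, meta$specimen_id, meta$scan_replicate)
  meta <- meta[ord, , drop = FALSE]
  absorbance <- absorbance[ord, , drop = FALSE]
  rownames(meta) <- NULL
  rownames(absorbance) <- paste(meta$specimen_id, meta$scan_replicate, sep = ":")
  structure(list(meta = meta, absorbance = absorbance, grid = grid), class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf(
    "<scan_set> %d scans x %d wavelengths; %d species; days: %s\n",
    nrow(x$meta), x$grid$n_points, length(unique(x$meta$species)),
    paste(sort(unique(x$meta$collection_day)), collapse = ", ")
  ))
  invisible(x)
}

#' Number of scans in a scan set
#' @param x A `scan_set`.
#' @export
n_scans <- function(x) {
  stopifnot(inherits(x, "scan_set"))
  nrow(x$meta)
}

#' Subset a scan set by a metadata predicate
#'
#' @param x A `scan_set`.
#' @param keep Logical vector over scans (rows of `x$meta`).
#' @return A `scan_set` with the selected scans.
#' @export
subset_scans <- function(x, keep) {
  stopifnot(inherits(x, "scan_set"), is.logical(keep), length(keep) == nrow(x$meta))
  keep[is.na(keep)] <- FALSE
  scan_set(x$meta[keep, , drop = FALSE], x$absorbance[keep, , drop = FALSE], x$grid)
}
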