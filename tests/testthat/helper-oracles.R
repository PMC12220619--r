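# Independent brute-force oracles and small fixture builders used across the
# test files. Everything here is deliberately written from first principles
# (explicit loops, hand quantile formula) so it shares no code path with the
# package implementation it checks.

# type-7 quantile by the textbook interpolation formula
hand_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# double-loop Tukey outlier count over a plain matrix (no SNV)
oracle_outlier_count <- function(mat, k = 1.5) {
  count <- 0L
  for (j in seq_len(ncol(mat))) {
    q1 <- hand_quantile(mat[, j], 0.25)
    q3 <- hand_quantile(mat[, j], 0.75)
    lo <- q1 - k * (q3 - q1)
    hi <- q3 + k * (q3 - q1)
    for (i in seq_len(nrow(mat))) {
      v <- mat[i, j]
      if (v < lo || v > hi) count <- count + 1L
    }
  }
  count
}

# closed-form simple OLS from the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  sse <- sum((y - intercept - slope * x)^2)
  se <- sqrt(sse / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, intercept = intercept, se = se,
       p = 2 * stats::pt(-abs(t), n - 2))
}

# a small well-formed scan set with random spectra
random_scan_set <- function(n_specimens = 3, reps = 2, n_points = 5,
                            species = c("SYN01", "SYN02"),
                            days = c("PRE", "POST_D1")) {
  grid <- wavelength_grid(1000, 2, n_points)
  rows <- expand.grid(specimen = seq_len(n_specimens), rep = seq_len(reps),
                      species = species, day = days,
                      stringsAsFactors = FALSE)
  meta <- data.frame(
    specimen_id = sprintf("%s_%s_%02d", rows$species, rows$day, rows$specimen),
    species = rows$species,
    treatment_cycle = 1L,
    collection_day = rows$day,
    scan_replicate = rows$rep
  )
  mat <- matrix(rnorm(nrow(meta) * n_points, mean = 1), nrow(meta), n_points)
  scan_set(meta, mat, grid)
}

# write a long-dialect CSV by hand (independent of write_spectra_table)
write_long_by_hand <- function(lines, path = tempfile(fileext = ".csv")) {
  header <- "specimen_id,species,treatment_cycle,collection_day,scan_replicate,wavelength_nm,absorbance"
  writeLines(c(header, lines), path)
  path
}
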