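#' Simple ordinary-least-squares regression of y on x
#'
#' One-predictor OLS with the usual t test on the slope. Pairs with a missing
#' predictor or response are dropped (pairwise deletion); at least 3 complete
#' pairs are required and the predictor must vary.
#'
#' @param x Predictor vector.
#' @param y Response vector.
#' @return data.frame row: `coefficient` (slope), `se`, `p_value` (two-sided),
#'   `df` (= n - 2), `n`, `intercept`, `r_squared`.
#' @examples
#' simple_ols(1:10, 2 * (1:10) + 1)$coefficient  # 2
#' @export
simple_ols <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete (x, y) pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("predictor has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  data.frame(
    coefficient = unname(s$coefficients["x", "Estimate"]),
    se = unname(s$coefficients["x", "Std. Error"]),
    p_value = unname(s$coefficients["x", "Pr(>|t|)"]),
    df = fit$df.residual,
    n = n,
    intercept = unname(s$coefficients["(Intercept)", "Estimate"]),
    r_squared = s$r.squared
  )
}

#' The study's full series of simple regressions
#'
#' Reproduces the regression grids of the study: each covariate regressed,
#' one at a time, against each f response. Responses and their matched
#' abundance / number-scanned predictors:
#'
#' * **levels** — `f_pre`, `f_d1`, `f_d2` against the same-day abundance and
#'   scanned counts plus preservation time (months), ambient RH (%) and
#'   ambient temperature (deg C);
#' * **actual_diffs** — `f_d1 - f_pre` and `f_d2 - f_d1` against the matching
#'   day-differences of abundance and scanned counts plus the three
#'   conditions;
#' * **relative_diffs** — the tolerance-gated ratios `f_d1 / f_pre` and
#'   `f_d2 / f_d1` against the matching day-ratios of abundance and scanned
#'   counts plus the three conditions;
#' * **flight** — average maximum flight distance (km) against the four
#'   difference/ratio responses, dropping species without a published flight
#'   value.
#'
#' The condition covariates (preservation, RH, T) are species-level scanning
#' averages and enter every grid unchanged. A cell whose regression fails is
#' recorded with NA estimates and the series continues.
#'
#' @param metadata Species metadata ([load_fixture_metadata()] layout).
#' @param profiles f table with `species, f_pre, f_d1, f_d2`
#'   ([load_fixture_f()] or [build_profiles()]).
#' @param tolerance Measurement tolerance used to gate the relative
#'   differences.
#' @return data.frame with columns `table, response, predictor, coefficient,
#'   se, p_value, df, n, significant` (`p < 0.05`).
#' @export
regression_series <- function(metadata, profiles, tolerance = default_tolerance()) {
  m <- merge(metadata, profiles[, c("species", "f_pre", "f_d1", "f_d2")], by = "species")
  diffs <- difference_table(profiles, tolerance)
  m <- merge(m, diffs[, c("species", "actual_d1_pre", "actual_d2_d1",
                          "relative_d1_pre", "relative_d2_d1")], by = "species")

  conditions <- list(
    "preservation_months" = m$preservation_months,
    "rh_percent" = m$rh_percent,
    "temp_c" = m$temp_c
  )
  grids <- list(
    levels = list(
      f_pre = c(list(abundance = m$abundance_pre, scanned = m$scanned_pre), conditions),
      f_d1 = c(list(abundance = m$abundance_d1, scanned = m$scanned_d1), conditions),
      f_d2 = c(list(abundance = m$abundance_d2, scanned = m$scanned_d2), conditions)
    ),
    actual_diffs = list(
      actual_d1_pre = c(list(abundance = m$abundance_d1 - m$abundance_pre,
                             scanned = m$scanned_d1 - m$scanned_pre), conditions),
      actual_d2_d1 = c(list(abundance = m$abundance_d2 - m$abundance_d1,
                            scanned = m$scanned_d2 - m$scanned_d1), conditions)
    ),
    relative_diffs = list(
      relative_d1_pre = c(list(abundance = m$abundance_d1 / m$abundance_pre,
                               scanned = m$scanned_d1 / m$scanned_pre), conditions),
      relative_d2_d1 = c(list(abundance = m$abundance_d2 / m$abundance_d1,
                              scanned = m$scanned_d2 / m$scanned_d1), conditions)
    ),
    flight = list(
      actual_d1_pre = list(max_flight_km = m$max_flight_km),
      actual_d2_d1 = list(max_flight_km = m$max_flight_km),
      relative_d1_pre = list(max_flight_km = m$max_flight_km),
      relative_d2_d1 = list(max_flight_km = m$max_flight_km)
    )
  )

  rows <- list()
  for (tab in names(grids)) {
    for (resp in names(grids[[tab]])) {
      y <- m[[resp]]
      for (pred in names(grids[[tab]][[resp]])) {
        x <- grids[[tab]][[resp]][[pred]]
        res <- tryCatch(simple_ols(x, y), error = function(e) {
          data.frame(coefficient = NA_real_, se = NA_real_, p_value = NA_real_,
                     df = NA_integer_, n = sum(is.finite(x) & is.finite(y)),
                     intercept = NA_real_, r_squared = NA_real_)
        })
        rows[[length(rows) + 1L]] <- data.frame(
          table = tab, response = resp, predictor = pred,
          coefficient = res$coefficient, se = res$se, p_value = res$p_value,
          df = res$df, n = res$n,
          significant = !is.na(res$p_value) & res$p_value < 0.05
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
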