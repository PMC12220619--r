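#' Per-species f profiles across collection days
#'
#' Splits a full study's scans by species and computes the cohort outlier
#' fraction for the PRE, POST d1, POST d2 and pooled POST (d1+d2) cohorts.
#' Treatment cycles are pooled within a collection-day class, and the pooled
#' POST cohort recomputes fences on the combined d1+d2 matrix (it is not an
#' average of the per-day f values). A day class with no scans, or with too
#' few scans for quartile estimation, yields `NA` with a warning and the
#' pooled POST value uses whatever post-treatment scans exist.
#'
#' @param scans A [scan_set()] covering the study.
#' @param ... Passed to [cohort_outlier_fraction()] (`k`, `method`,
#'   `min_scans`, ...).
#' @return data.frame with one row per species: scan counts `n_pre, n_d1,
#'   n_d2, n_post` and fractions `f_pre, f_d1, f_d2, f_post`.
#' @export
build_profiles <- function(scans, ...) {
  stopifnot(inherits(scans, "scan_set"))
  species <- sort(unique(scans$meta$species))
  one_f <- function(keep, label, sp) {
    n <- sum(keep)
    if (n == 0L) {
      warning("species ", sp, ": no scans for ", label, "; f set to NA", call. = FALSE)
      return(c(n = 0L, f = NA_real_))
    }
    f <- tryCatch(
      cohort_outlier_fraction(subset_scans(scans, keep), ...)$f,
      error = function(e) {
        warning("species ", sp, ", ", label, ": ", conditionMessage(e), call. = FALSE)
        NA_real_
      }
    )
    c(n = n, f = f)
  }
  rows <- lapply(species, function(sp) {
    is_sp <- scans$meta$species == sp
    day <- scans$meta$collection_day
    pre <- one_f(is_sp & day == "PRE", "PRE", sp)
    d1 <- one_f(is_sp & day == "POST_D1", "POST d1", sp)
    d2 <- one_f(is_sp & day == "POST_D2", "POST d2", sp)
    post <- one_f(is_sp & day %in% c("POST_D1", "POST_D2"), "POST (d1+d2)", sp)
    data.frame(species = sp,
               n_pre = pre[["n"]], n_d1 = d1[["n"]], n_d2 = d2[["n"]],
               n_post = post[["n"]],
               f_pre = pre[["f"]], f_d1 = d1[["f"]], f_d2 = d2[["f"]],
               f_post = post[["f"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tolerance-gated actual difference in f
#'
#' `actual = f_later - f_earlier`. The pair is gated (treated as "no change")
#' when the absolute difference does not exceed the measurement tolerance.
#' Direction is `younger` when f rose beyond tolerance (younger recruits
#' raise the outlier fraction), `older` when it fell beyond tolerance.
#'
#' @param f_later,f_earlier Numeric f values (vectorized).
#' @param tolerance Measurement tolerance on the f scale.
#' @return data.frame with columns `actual` (full precision; print with
#'   `round(actual, 4)`), `gated`, `direction`.
#' @examples
#' actual_difference(0.0641, 0.0240)          # 0.0401, younger
#' actual_difference(0.0022, 0.0018)$gated    # TRUE at the default tolerance
#' @export
actual_difference <- function(f_later, f_earlier, tolerance = default_tolerance()) {
  stopifnot(length(f_later) == length(f_earlier), tolerance >= 0)
  actual <- f_later - f_earlier
  gated <- !is.na(actual) & abs(actual) <= tolerance
  direction <- ifelse(is.na(actual), NA_character_,
               ifelse(actual > tolerance, "younger",
               ifelse(actual < -tolerance, "older", "no_change")))
  data.frame(actual = actual, gated = gated, direction = direction)
}

#' Tolerance-gated relative difference in f
#'
#' The plain ratio `f_later / f_earlier`, reported to 1 decimal place, set to
#' 0 when the actual difference is within tolerance (gated). A zero
#' denominator with an ungated difference is undefined and flagged.
#'
#' @inheritParams actual_difference
#' @return data.frame with columns `relative` (full precision), `gated`,
#'   `undefined`.
#' @examples
#' round(relative_difference(0.0641, 0.0240)$relative, 1)  # 2.7
#' @export
relative_difference <- function(f_later, f_earlier, tolerance = default_tolerance()) {
  ad <- actual_difference(f_later, f_earlier, tolerance)
  undefined <- !ad$gated & !is.na(f_earlier) & f_earlier == 0
  relative <- ifelse(ad$gated, 0, f_later / f_earlier)
  relative[undefined] <- NA_real_
  data.frame(relative = relative, gated = ad$gated, undefined = undefined)
}

#' Consecutive-day difference table
#'
#' For each species computes the actual and relative differences in f for the
#' two consecutive collection-date pairs (POST d1 vs PRE, POST d2 vs POST d1),
#' with tolerance gating — the layout of the study's printed difference
#' tables.
#'
#' @param profiles Profile table from [build_profiles()] or [load_fixture_f()].
#' @param tolerance Measurement tolerance on the f scale.
#' @return data.frame with per-species columns `actual_d1_pre, gated_d1_pre,
#'   direction_d1_pre, relative_d1_pre, actual_d2_d1, gated_d2_d1,
#'   direction_d2_d1, relative_d2_d1` (full precision; round for reporting).
#' @export
difference_table <- function(profiles, tolerance = default_tolerance()) {
  a1 <- actual_difference(profiles$f_d1, profiles$f_pre, tolerance)
  r1 <- relative_difference(profiles$f_d1, profiles$f_pre, tolerance)
  a2 <- actual_difference(profiles$f_d2, profiles$f_d1, tolerance)
  r2 <- relative_difference(profiles$f_d2, profiles$f_d1, tolerance)
  data.frame(
    species = profiles$species,
    actual_d1_pre = a1$actual, gated_d1_pre = a1$gated,
    direction_d1_pre = a1$direction, relative_d1_pre = r1$relative,
    actual_d2_d1 = a2$actual, gated_d2_d1 = a2$gated,
    direction_d2_d1 = a2$direction, relative_d2_d1 = r2$relative
  )
}

#' Count species whose pooled post-treatment f exceeds pre-treatment f
#'
#' @param profiles Profile table with `f_pre` and `f_post` columns.
#' @return Integer count of species with `f_post > f_pre`.
#' @export
count_increased <- function(profiles) {
  stopifnot(all(c("f_pre", "f_post") %in% names(profiles)))
  sum(profiles$f_post > profiles$f_pre, na.rm = TRUE)
}

#' Classify one species into a trend group
#'
#' Formalizes the study's four-way narrative classification of species by
#' their abundance and f trajectories over PRE, POST d1 and POST d2:
#'
#' * **A** — younger recruits do not offset the abundance reduction by d1
#'   (abundance down, f up beyond tolerance), while older recruits offset it
#'   by d2 (abundance back to at least PRE level, f down beyond tolerance).
#' * **B** — as A on d1, but abundance stays below PRE on d2 while f falls
#'   (older recruits fail to offset the reduction).
#' * **C** — no f rise beyond tolerance by d1; younger recruits appear on d2
#'   (f up beyond tolerance) without restoring abundance.
#' * **D** — everything else.
#'
#' "Offsets the abundance reduction" is read on raw trap counts:
#' `abundance_d2 >= abundance_pre`. The raw predicates are returned so the
#' grouping can be re-derived under other rules.
#'
#' @param abundance Numeric length-3 vector `(pre, d1, d2)` of trap counts.
#' @param f Numeric length-3 vector `(f_pre, f_d1, f_d2)`.
#' @param tolerance Measurement tolerance on the f scale.
#' @return List with `group` (one of `"A","B","C","D"`) and `predicates`.
#' @examples
#' classify_trend_group(c(74, 63, 88), c(0.0163, 0.0438, 0.0267))$group  # "A"
#' @export
classify_trend_group <- function(abundance, f, tolerance = default_tolerance()) {
  stopifnot(length(abundance) == 3L, length(f) == 3L)
  if (anyNA(abundance) || anyNA(f)) stop("classification needs all six values", call. = FALSE)
  a_pre <- abundance[1]; a_d1 <- abundance[2]; a_d2 <- abundance[3]
  df1 <- f[2] - f[1]   # POST d1 - PRE
  df2 <- f[3] - f[2]   # POST d2 - POST d1
  p <- list(
    abundance_down_d1 = a_d1 < a_pre,
    abundance_recovered_d2 = a_d2 >= a_pre,
    f_up_d1 = df1 > tolerance,
    f_down_d2 = df2 < -tolerance,
    f_up_d2 = df2 > tolerance
  )
  group <- if (p$abundance_down_d1 && p$f_up_d1 && p$abundance_recovered_d2 && p$f_down_d2) {
    "A"
  } else if (p$abundance_down_d1 && p$f_up_d1 && !p$abundance_recovered_d2 && p$f_down_d2) {
    "B"
  } else if (df1 <= tolerance && p$f_up_d2 && !p$abundance_recovered_d2) {
    "C"
  } else {
    "D"
  }
  list(group = group, predicates = p,
       evidence = list(abundance = abundance, f = f, df1 = df1, df2 = df2))
}

#' Classify every species in a study
#'
#' @param metadata Species metadata with `abundance_pre, abundance_d1,
#'   abundance_d2` (e.g. [load_fixture_metadata()]).
#' @param profiles Profile table with `f_pre, f_d1, f_d2`, matched by
#'   `species`.
#' @param tolerance Measurement tolerance on the f scale.
#' @return data.frame with one row per species: `species`, `group`, the six
#'   input values and the decision predicates.
#' @export
classify_trends <- function(metadata, profiles, tolerance = default_tolerance()) {
  m <- merge(metadata[, c("species", "abundance_pre", "abundance_d1", "abundance_d2")],
             profiles[, c("species", "f_pre", "f_d1", "f_d2")], by = "species")
  rows <- lapply(seq_len(nrow(m)), function(i) {
    cl <- classify_trend_group(
      c(m$abundance_pre[i], m$abundance_d1[i], m$abundance_d2[i]),
      c(m$f_pre[i], m$f_d1[i], m$f_d2[i]),
      tolerance
    )
    cbind(m[i, , drop = FALSE], group = cl$group,
          as.data.frame(cl$predicates))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}
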