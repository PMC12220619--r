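#' Configuration for the synthetic SWIR study generator
#'
#' Bundles every knob of the generator: the wavelength grid, cohort sizing,
#' the age mixture of the pre-treatment population, the age-to-spectrum drift,
#' per-point noise, per-scan multiplicative/additive scatter (removable by
#' SNV), and the treatment dynamics (age-dependent kill plus a recruit pulse
#' of young adults).
#'
#' The age model is deliberately simple: one fixed unit-norm drift shape whose
#' amplitude grows with age as a saturating exponential
#' `amplitude(a) = age_drift_scale * (1 - exp(-a / age_saturation_days))`.
#' Because amplitude saturates, a homogeneous old cohort is spectrally tight,
#' while a mixed-age cohort (a young bulk with an older minority, the
#' signature of post-treatment recruitment) spreads beyond the per-wavelength
#' fences and raises f.
#'
#' @param seed Integer seed; all randomness flows from a single generator.
#' @param grid [wavelength_grid()] for every scan.
#' @param n_specimens Specimens per pre-treatment cohort.
#' @param scans_per_specimen Scan replicates per specimen (study used 2).
#' @param age_mixture Pre-treatment age mixture: list with numeric `means`,
#'   `sds` (days) and `weights` summing to 1.
#' @param age_drift_scale Saturation amplitude of the age drift, absorbance
#'   units.
#' @param age_saturation_days e-folding age of the drift amplitude, days.
#' @param noise_sd Per-point Gaussian noise SD, absorbance units.
#' @param spike_rate_per_noise Detector glitch rate: each point is replaced by
#'   a spike with probability `spike_rate_per_noise * noise_sd` (noisier
#'   instruments glitch more often; a noise-free instrument never does).
#' @param spike_scale Glitch amplitude as a multiple of `noise_sd` (random
#'   sign).
#' @param scatter_scale_range,scatter_offset_range Per-scan multiplicative /
#'   additive scatter factors drawn uniformly from these ranges.
#' @param kill_fraction Named numeric `c(young = ..., old = ...)` kill
#'   probabilities applied at treatment, both in `[0, 1]`.
#' @param kill_age_threshold Age (days) separating the two kill classes.
#' @param recruit_pulse Recruitment entering on each post-treatment day:
#'   list with `size` (count) and `mean`, `sd` (days) of recruit ages.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              grid = wavelength_grid(),
                              n_specimens = 100L,
                              scans_per_specimen = 2L,
                              age_mixture = list(means = c(5, 15),
                                                 sds = c(1.5, 3),
                                                 weights = c(0.1, 0.9)),
                              age_drift_scale = 0.5,
                              age_saturation_days = 5,
                              noise_sd = 0.005,
                              spike_rate_per_noise = 1,
                              spike_scale = 8,
                              scatter_scale_range = c(0.8, 1.2),
                              scatter_offset_range = c(-0.1, 0.1),
                              kill_fraction = c(young = 0.4, old = 0.85),
                              kill_age_threshold = 7,
                              recruit_pulse = list(size = 80L, mean = 1.5, sd = 0.5)) {
  stopifnot(inherits(grid, "wavelength_grid"))
  w <- age_mixture$weights
  if (length(w) != length(age_mixture$means) || length(w) != length(age_mixture$sds)) {
    stop("age mixture means, sds and weights must have equal length", call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-8) stop("age mixture weights must sum to 1", call. = FALSE)
  if (any(age_mixture$sds < 0) || noise_sd < 0) stop("SDs must be >= 0", call. = FALSE)
  if (any(kill_fraction < 0 | kill_fraction > 1)) {
    stop("kill_fraction values must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_specimens >= 1, scans_per_specimen >= 1,
            age_drift_scale >= 0, age_saturation_days > 0,
            spike_rate_per_noise >= 0, spike_scale >= 0,
            recruit_pulse$size >= 0, recruit_pulse$sd >= 0)
  structure(
    list(seed = as.integer(seed), grid = grid,
         n_specimens = as.integer(n_specimens),
         scans_per_specimen = as.integer(scans_per_specimen),
         age_mixture = age_mixture,
         age_drift_scale = age_drift_scale,
         age_saturation_days = age_saturation_days,
         noise_sd = noise_sd,
         spike_rate_per_noise = spike_rate_per_noise,
         spike_scale = spike_scale,
         scatter_scale_range = scatter_scale_range,
         scatter_offset_range = scatter_offset_range,
         kill_fraction = kill_fraction,
         kill_age_threshold = kill_age_threshold,
         recruit_pulse = recruit_pulse),
    class = "sim_config"
  )
}

# smooth cuticle-like baseline plus O-H water bands at 1210 and 1450 nm
baseline_spectrum <- function(grid) {
  w <- wavelengths(grid)
  t <- if (grid$n_points > 1) (w - w[1]) / (w[length(w)] - w[1]) else 0
  base <- 0.5 + 0.25 * t + 0.15 * t^2
  water <- 0.15 * exp(-((w - 1210) / 20)^2 / 2) + 0.30 * exp(-((w - 1450) / 30)^2 / 2)
  base + water
}

# fixed unit-norm drift shape spanning the whole grid with graded magnitude
# (slow oscillation, zero crossings), so the number of wavelengths on which an
# age contrast clears the noise floor grows with the size of the contrast.
# Defined over the normalized grid index so it stays well-formed on arbitrary
# (including tiny test) grids.
drift_shape <- function(grid) {
  p <- grid$n_points
  t <- if (p > 1) (seq_len(p) - 1) / (p - 1) else 0
  d <- sin(2 * pi * t) + 0.5 * cos(5 * pi * t)
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-12) d <- rep(1, p) / sqrt(p) else d <- d / nrm
  d
}

drift_amplitude <- function(age, config) {
  config$age_drift_scale * (1 - exp(-pmax(age, 0) / config$age_saturation_days))
}

# per-point instrument noise: Gaussian floor plus rare detector glitches whose
# rate scales with the noise level
instrument_noise <- function(p, config) {
  if (config$noise_sd <= 0) return(rep(0, p))
  noise <- stats::rnorm(p, 0, config$noise_sd)
  rate <- min(config$spike_rate_per_noise * config$noise_sd, 0.5)
  if (rate > 0) {
    hit <- stats::runif(p) < rate
    if (any(hit)) {
      noise[hit] <- sample(c(-1, 1), sum(hit), replace = TRUE) *
        config$spike_scale * config$noise_sd
    }
  }
  noise
}

draw_ages <- function(n, mixture) {
  if (n == 0L) return(numeric(0))
  comp <- sample.int(length(mixture$weights), n, replace = TRUE, prob = mixture$weights)
  pmax(stats::rnorm(n, mixture$means[comp], mixture$sds[comp]), 0.05)
}

# scans for a set of individuals of known age; no seeding here so callers
# control the stream
build_scans <- function(config, ages, species, collection_day, treatment_cycle,
                        id_prefix) {
  n <- length(ages)
  reps <- config$scans_per_specimen
  base <- baseline_spectrum(config$grid)
  shape <- drift_shape(config$grid)
  p <- config$grid$n_points
  amp <- drift_amplitude(ages, config)
  mat <- matrix(NA_real_, nrow = n * reps, ncol = p)
  meta <- data.frame(
    specimen_id = rep(sprintf("%s_%05d", id_prefix, seq_len(n)), each = reps),
    species = species,
    treatment_cycle = as.integer(treatment_cycle),
    collection_day = collection_day,
    scan_replicate = rep(seq_len(reps), times = n)
  )
  row <- 0L
  for (i in seq_len(n)) {
    clean <- base + amp[i] * shape
    for (r in seq_len(reps)) {
      row <- row + 1L
      scale <- stats::runif(1, config$scatter_scale_range[1], config$scatter_scale_range[2])
      offset <- stats::runif(1, config$scatter_offset_range[1], config$scatter_offset_range[2])
      mat[row, ] <- scale * (clean + instrument_noise(p, config)) + offset
    }
  }
  scan_set(meta, mat, config$grid)
}

#' Simulate one cohort of SWIR scans
#'
#' Draws specimen ages from the configured mixture (or uses `ages` verbatim),
#' maps age to a spectral drift amplitude, and emits
#' `n_specimens * scans_per_specimen` scans with per-scan scatter and noise.
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param ages Optional numeric vector of specimen ages (days) overriding the
#'   mixture draw.
#' @param species,collection_day,treatment_cycle Labels for the scans.
#' @return A [scan_set()].
#' @export
simulate_cohort <- function(config, ages = NULL, species = "SYN1",
                            collection_day = "PRE", treatment_cycle = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(ages)) ages <- draw_ages(config$n_specimens, config$age_mixture)
  build_scans(config, ages, species, collection_day, treatment_cycle,
              id_prefix = paste(species, collection_day, treatment_cycle, sep = "_"))
}

kill_survivors <- function(ages, config) {
  if (!length(ages)) return(numeric(0))
  p_kill <- ifelse(ages >= config$kill_age_threshold,
                   config$kill_fraction[["old"]], config$kill_fraction[["young"]])
  ages[stats::runif(length(ages)) >= p_kill]
}

#' Simulate a full pre/post adulticide treatment study
#'
#' For each species and treatment cycle: a pre-treatment cohort is drawn from
#' the configured age mixture; treatment kills individuals with the
#' age-dependent kill probabilities; the day-1 post cohort is the survivors
#' plus a recruit pulse of young adults; the day-2 post cohort is the day-1
#' pool aged one day plus a second recruit pulse. Cohort sizes therefore track
#' the kill/recruitment dynamics and are returned as the study's abundance
#' table.
#'
#' @param config A [simulation_config()].
#' @param n_species Number of synthetic species.
#' @param n_cycles Number of treatment cycles (the study ran 4).
#' @return A [scan_set()] holding every scan of the study, with attribute
#'   `"abundance"`: data.frame of per-species cohort sizes
#'   (`abundance_pre, abundance_d1, abundance_d2`, summed over cycles).
#' @export
simulate_treatment_study <- function(config, n_species = 3L, n_cycles = 4L) {
  stopifnot(inherits(config, "sim_config"), n_species >= 1, n_cycles >= 1)
  set.seed(config$seed)
  pieces <- list()
  counts <- list()
  for (s in seq_len(n_species)) {
    sp <- sprintf("SYN%02d", s)
    n_pre <- n_d1 <- n_d2 <- 0L
    for (cy in seq_len(n_cycles)) {
      pre_ages <- draw_ages(config$n_specimens, config$age_mixture)
      surv <- kill_survivors(pre_ages, config)
      pulse <- function() pmax(stats::rnorm(config$recruit_pulse$size,
                                            config$recruit_pulse$mean,
                                            config$recruit_pulse$sd), 0.05)
      # trapping removes collected individuals, so each post day pools the
      # (aging) treatment survivors with that day's newly host-seeking recruits
      d1_ages <- c(surv, pulse())
      if (!length(d1_ages)) stop("post-treatment cohort is empty", call. = FALSE)
      d2_ages <- c(surv + 1, pulse())
      if (!length(d2_ages)) stop("post-treatment cohort is empty", call. = FALSE)
      tag <- function(day) paste(sp, day, cy, sep = "_")
      pieces[[length(pieces) + 1L]] <-
        build_scans(config, pre_ages, sp, "PRE", cy, tag("PRE"))
      pieces[[length(pieces) + 1L]] <-
        build_scans(config, d1_ages, sp, "POST_D1", cy, tag("POST_D1"))
      pieces[[length(pieces) + 1L]] <-
        build_scans(config, d2_ages, sp, "POST_D2", cy, tag("POST_D2"))
      n_pre <- n_pre + length(pre_ages)
      n_d1 <- n_d1 + length(d1_ages)
      n_d2 <- n_d2 + length(d2_ages)
    }
    counts[[s]] <- data.frame(species = sp, abundance_pre = n_pre,
                              abundance_d1 = n_d1, abundance_d2 = n_d2)
  }
  meta <- do.call(rbind, lapply(pieces, function(x) x$meta))
  mat <- do.call(rbind, lapply(pieces, function(x) x$absorbance))
  out <- scan_set(meta, mat, config$grid)
  attr(out, "abundance") <- do.call(rbind, counts)
  out
}

#' Simulate repeated scanning trials of a physical standard
#'
#' Emulates the study's aspirin-tablet control: a fixed, age-free standard
#' spectrum scanned repeatedly. Trials differ only through per-scan scatter
#' and noise, so the tolerance derived from their f values shrinks to 0 as
#' `noise_sd` goes to 0.
#'
#' @param config A [simulation_config()]; only grid, noise and scatter fields
#'   are used.
#' @param n_trials Number of trials (>= 2; the study ran 2).
#' @param scans_per_trial Scans of the standard per trial.
#' @return List of `n_trials` [scan_set()] objects (species `"STANDARD"`).
#' @export
simulate_standard_trials <- function(config, n_trials = 2L, scans_per_trial = 20L) {
  stopifnot(inherits(config, "sim_config"), n_trials >= 2, scans_per_trial >= 4)
  set.seed(config$seed)
  # aspirin-like standard: smooth background with two sharp absorption peaks
  p <- config$grid$n_points
  t <- if (p > 1) (seq_len(p) - 1) / (p - 1) else 0
  shape <- 0.6 + 0.1 * t + 0.35 * exp(-((t - 0.35) / 0.04)^2 / 2) +
    0.25 * exp(-((t - 0.7) / 0.05)^2 / 2)
  lapply(seq_len(n_trials), function(tr) {
    mat <- matrix(NA_real_, nrow = scans_per_trial, ncol = p)
    for (i in seq_len(scans_per_trial)) {
      scale <- stats::runif(1, config$scatter_scale_range[1], config$scatter_scale_range[2])
      offset <- stats::runif(1, config$scatter_offset_range[1], config$scatter_offset_range[2])
      mat[i, ] <- scale * (shape + instrument_noise(p, config)) + offset
    }
    meta <- data.frame(
      specimen_id = sprintf("STD_T%02d_%04d", tr, seq_len(scans_per_trial)),
      species = "STANDARD", treatment_cycle = 1L, collection_day = "PRE",
      scan_replicate = 1L
    )
    scan_set(meta, mat, config$grid)
  })
}
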