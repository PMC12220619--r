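test_that("cohort simulation has the configured shape and is seed-deterministic", {
  cfg <- simulation_config(seed = 5, n_specimens = 50, scans_per_specimen = 2)
  sc <- simulate_cohort(cfg)
  expect_equal(n_scans(sc), 100L)
  expect_equal(ncol(sc$absorbance), 228L)
  expect_true(all(is.finite(sc$absorbance)))

  sc2 <- simulate_cohort(cfg)
  expect_identical(sc$absorbance, sc2$absorbance)
  sc3 <- simulate_cohort(simulation_config(seed = 6, n_specimens = 50))
  expect_false(identical(sc$absorbance, sc3$absorbance))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(age_mixture = list(means = c(1, 2), sds = c(1, 1),
                                                    weights = c(0.7, 0.7))),
               "sum to 1")
  expect_error(simulation_config(age_mixture = list(means = 1, sds = -1, weights = 1)),
               "SDs")
  expect_error(simulation_config(kill_fraction = c(young = 0.5, old = 1.2)),
               "kill_fraction")
})

test_that("a noise-free single-age cohort is SNV-identical with f = 0", {
  cfg <- simulation_config(seed = 7, n_specimens = 10, noise_sd = 0,
                           age_mixture = list(means = 8, sds = 0, weights = 1))
  sc <- simulate_cohort(cfg)
  m <- snv_matrix(sc)
  expect_lt(max(abs(sweep(m, 2, m[1, ]))), 1e-9)
  expect_equal(cohort_outlier_fraction(sc)$f, 0)
})

test_that("a null treatment leaves f unchanged up to Monte-Carlo noise", {
  diffs <- sapply(1:5, function(s) {
    cfg <- simulation_config(seed = s, n_specimens = 40,
                             kill_fraction = c(young = 0, old = 0),
                             recruit_pulse = list(size = 0, mean = 1.5, sd = 0.5))
    pr <- build_profiles(simulate_treatment_study(cfg, n_species = 1, n_cycles = 1))
    pr$f_post - pr$f_pre
  })
  expect_lt(abs(mean(diffs)), 0.01)
})

test_that("the treatment study tracks abundance and survives the writer", {
  cfg <- simulation_config(seed = 8, n_specimens = 20, scans_per_specimen = 2,
                           recruit_pulse = list(size = 15, mean = 1.5, sd = 0.5))
  st <- simulate_treatment_study(cfg, n_species = 2, n_cycles = 2)
  ab <- attr(st, "abundance")
  expect_equal(nrow(ab), 2L)
  expect_equal(ab$abundance_pre, c(40L, 40L))   # n_specimens x cycles
  # every scanned cohort appears with 2 replicates per specimen
  expect_equal(n_scans(st), 2L * sum(ab$abundance_pre, ab$abundance_d1, ab$abundance_d2))

  path <- tempfile(fileext = ".csv")
  write_spectra_table(st, path, "long")
  back <- read_spectra_table(path, "long")
  expect_equal(back$meta, st$meta)
  expect_equal(back$absorbance, st$absorbance, tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(path)
})

test_that("an old-recruit pulse typically lowers post-treatment f", {
  res <- t(sapply(1:15, function(s) {
    cfg <- simulation_config(seed = s, n_specimens = 60,
                             age_mixture = list(means = c(3, 14), sds = c(1, 3),
                                                weights = c(0.2, 0.8)),
                             kill_fraction = c(young = 0.9, old = 0.4),
                             recruit_pulse = list(size = 80, mean = 18, sd = 2))
    pr <- build_profiles(simulate_treatment_study(cfg, n_species = 1, n_cycles = 1))
    c(pre = pr$f_pre, post = pr$f_post)
  }))
  expect_gt(mean(res[, "post"] < res[, "pre"]), 0.5)
})

test_that("standard trials give zero tolerance without noise and reproduce", {
  cfg0 <- simulation_config(seed = 9, noise_sd = 0)
  tr0 <- simulate_standard_trials(cfg0, n_trials = 2, scans_per_trial = 10)
  f0 <- sapply(tr0, function(x) cohort_outlier_fraction(x)$f)
  expect_equal(measurement_tolerance(f0)$value, 0)

  cfg <- simulation_config(seed = 10, noise_sd = 0.005)
  t1 <- simulate_standard_trials(cfg, 2, 10)
  t2 <- simulate_standard_trials(cfg, 2, 10)
  expect_identical(t1[[1]]$absorbance, t2[[1]]$absorbance)
})

test_that("tolerance grows with scanning noise in expectation", {
  tol_at <- function(noise) {
    mean(sapply(1:50, function(s) {
      cfg <- simulation_config(seed = s, noise_sd = noise,
                               grid = wavelength_grid(n_points = 60))
      fs <- sapply(simulate_standard_trials(cfg, 2, 10),
                   function(x) cohort_outlier_fraction(x)$f)
      measurement_tolerance(fs)$value
    }))
  }
  expect_lte(tol_at(0.004), tol_at(0.008))
})

test_that("the pipeline runs end to end, deterministically, from one seed", {
  out1 <- file.path(tempdir(), "pipe1")
  out2 <- file.path(tempdir(), "pipe2")
  cfg <- simulation_config(seed = 11, n_specimens = 15, scans_per_specimen = 2,
                           recruit_pulse = list(size = 12, mean = 1.5, sd = 0.5))
  r1 <- suppressMessages(run_pipeline(scenario = cfg, n_species = 2, n_cycles = 1,
                                      out_dir = out1))
  r2 <- suppressMessages(run_pipeline(scenario = cfg, n_species = 2, n_cycles = 1,
                                      out_dir = out2))
  expect_setequal(basename(r1$paths), c("f_table.csv", "differences.csv", "trend_groups.csv"))
  for (nm in basename(r1$paths)) {
    expect_identical(readLines(file.path(out1, nm)), readLines(file.path(out2, nm)))
  }
  expect_equal(nrow(r1$profiles), 2L)
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("YAML scenarios configure the pipeline", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "grid:", "  start_nm: 950", "  step_nm: 3.5", "  n_points: 50",
    "simulation:", "  seed: 12", "  n_specimens: 10",
    "  recruit_pulse:", "    size: 8", "    mean: 1.5", "    sd: 0.5",
    "n_species: 1", "n_cycles: 1", "tolerance: 0.0008"
  ), yml)
  args <- load_pipeline_config(yml)
  expect_s3_class(args$scenario, "sim_config")
  expect_equal(args$scenario$grid$n_points, 50L)
  res <- suppressMessages(do.call(run_pipeline, args))
  expect_equal(nrow(res$profiles), 1L)
  unlink(yml)
})
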