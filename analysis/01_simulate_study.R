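#!/usr/bin/env Rscript
# Simulate a synthetic pre/post-adulticide SWIR study and write it to disk.
#
# Three synthetic species, four treatment cycles, 40 specimens per
# pre-treatment cohort with duplicate scans — a desk-scale stand-in for the
# field study's shape (the full scale is exercised by the test suite's record
# accounting check). Outputs: canonical long-format spectra CSV plus the
# simulated abundance table.

library(swirf)

out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 1, n_specimens = 40, scans_per_specimen = 2,
                         recruit_pulse = list(size = 32, mean = 1.5, sd = 0.5))
study <- simulate_treatment_study(cfg, n_species = 3, n_cycles = 4)
abundance <- attr(study, "abundance")

write_spectra_table(study, file.path(out_dir, "spectra_long.csv"), "long")
write.csv(abundance, file.path(out_dir, "abundance.csv"), row.names = FALSE)

message(sprintf("simulated %d scans x %d wavelengths (%s records)",
                n_scans(study), study$grid$n_points,
                format(n_scans(study) * study$grid$n_points, big.mark = ",")))
message("abundance by collection day (summed over cycles):")
print(abundance)
message("wrote ", out_dir, "/spectra_long.csv and abundance.csv")
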