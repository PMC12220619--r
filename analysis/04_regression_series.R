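#!/usr/bin/env Rscript
# The study's series of simple OLS regressions of f (levels, actual
# differences, gated relative differences) on the species covariates, plus
# the flight-distance grid with its two missing species dropped.

library(swirf)

out_dir <- "results/published"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

rs <- regression_series(load_fixture_metadata(), load_fixture_f())
rs_out <- rs
rs_out[c("coefficient", "se")] <- lapply(rs_out[c("coefficient", "se")], signif, 3)
rs_out$p_value <- round(rs_out$p_value, 3)
write.csv(rs_out, file.path(out_dir, "regressions.csv"), row.names = FALSE)

message(nrow(rs), " regressions over ", length(unique(rs$table)), " grids")
sig <- rs_out[rs_out$significant, ]
message("significant at 95%:")
print(sig[, c("table", "response", "predictor", "coefficient", "se", "p_value")])
message("(preservation time against the PRE-to-POST-d1 change in f is the only one)")
message("wrote ", out_dir, "/regressions.csv")
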