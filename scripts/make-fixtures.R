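#!/usr/bin/env Rscript
# Regenerates the small packaged fixture under inst/extdata/: a 2-stratum,
# 3-routes-per-stratum, 10-year synthetic dataset with its truth tables.
# Run from the repository root: Rscript scripts/make-fixtures.R
suppressMessages(devtools::load_all("."))

cfg <- sim_config(
  n_strata = 2, routes_per_stratum = 3, year_range = c(2000, 2009),
  mean_log_abundance = 1.2, annual_trend_pct = -2, seed = 42
)
sim <- simulate_dataset(cfg)
paths <- write_simulation(sim, "inst/extdata/synthetic-run")
cat("wrote:", paste(unlist(paths), collapse = "\n       "), "\n")
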