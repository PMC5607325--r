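#!/usr/bin/env Rscript
# Step 5 -- validate the whole pipeline by parameter recovery on
# synthetic sites.
#
# For each site template, synthetic datasets with known ground-truth
# flows are generated (truth drawn from a broadly constrained polytope,
# observations derived from the truth), compiled and sampled; per flow
# we ask whether the truth falls inside the central 95% interval of the
# sampled marginal. Ten seeds per template at 20 000 iterations keep
# the runtime modest; the acceptance script runs the fuller 20-seed
# version.

suppressPackageStartupMessages(library(ventlim))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (tpl in c("off_vent", "low_activity_vent", "high_activity_vent")) {
  cov <- c()
  for (s in 1:10) {
    ds <- generate_site(tpl, seed = 1000 + s)
    rr <- recovery_test(ds, n_iterations = 20000, seed = 2000 + s)
    cov <- c(cov, rr$coverage)
  }
  rows[[tpl]] <- data.frame(template = tpl, n_sites = length(cov),
                            mean_coverage = mean(cov),
                            min_coverage = min(cov))
  cat(sprintf("%-20s mean 95%%-interval coverage %.3f (min %.3f over %d sites)\n",
              tpl, mean(cov), min(cov), length(cov)))
}
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/recovery_coverage.csv", row.names = FALSE)
cat("wrote results/recovery_coverage.csv\n")
cat("Coverage near the nominal 95% shows the compiler, sampler and\n")
cat("interval machinery jointly recover known flows from synthetic\n")
cat("observations.\n")
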