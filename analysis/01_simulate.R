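#!/usr/bin/env Rscript
# Step 1: generate the working datasets for the two crosses.
#
# The raw per-plant phenotypes behind the published analysis are not
# deposited, so the workflow runs on synthetic six-generation datasets drawn
# from the best-supported genetic model (MX2-A-AD) at the published effect
# estimates, variance components and generation sample sizes, bundled with
# the package as crossA.json / crossB.json.

library(segjoint)

seed <- 1
dir.create("results", showWarnings = FALSE)

for (cross in c("crossA", "crossB")) {
  cfg <- cross_fixture(cross, seed = seed)
  d <- simulate_cross(cfg)
  out <- file.path("results", paste0(cross, "_phenotypes.csv"))
  write_dataset(d, out)
  cat(sprintf("%s: wrote %s (%d plants)\n", cross, out,
              sum(vapply(d$samples, function(s) length(s$values), integer(1)))))
}
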