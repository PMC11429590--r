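#!/usr/bin/env Rscript
# Step 2: descriptive layer — per-generation n, range, mean, SD, variance,
# CV and the adjusted skewness/kurtosis, for both simulated crosses.
# Expects the datasets from 01_simulate.R under results/.

library(segjoint)

for (cross in c("crossA", "crossB")) {
  d <- read_dataset(file.path("results", paste0(cross, "_phenotypes.csv")),
                    cross_id = cross)
  tab <- summarize_dataset(d, digits = 2)
  out <- file.path("results", paste0(cross, "_summary.csv"))
  utils::write.csv(cbind(cross = cross, tab), out, row.names = FALSE)
  cat("\n==", cross, "==\n")
  print(tab)
  cat(sprintf("largest offspring CV: %s\n",
              tab$generation[-(1:3)][which.max(tab$cv_percent[-(1:3)])]))
}
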