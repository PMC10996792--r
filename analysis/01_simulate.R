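#!/usr/bin/env Rscript
# Stage 1: generate the synthetic claims cohort used by the whole
# analysis. One 365-day study year; 150 physicians and 600 patients
# across 4 regions; patient-sharing assortative on the physicians'
# latent risky-prescribing propensity; refill chains, multi-class
# concurrent fills, and planted deprescribing events with ground truth.

suppressPackageStartupMessages(library(rxnet))

seed <- 2014L   # the study year doubles as the analysis seed
out <- "results/cohort"

cfg <- sim_config(seed = seed)
cohort <- generate_cohort(cfg)
print(cohort)

paths <- write_cohort(cohort, out, truth = TRUE)
cat("wrote:", paste(basename(paths), collapse = ", "), "->", out, "\n")

cat(sprintf(
  "fills per patient: %.2f | encounters per patient: %.2f | planted deprescribing events: %d\n",
  nrow(cohort$fills) / nrow(cohort$patients),
  nrow(cohort$encounters) / nrow(cohort$patients),
  nrow(cohort$truth$deprescribing)))

# physician metadata (with latent risk, for the recovery checks) is part
# of the ground truth
data.table::fwrite(cohort$physicians, file.path(out, "physicians_truth.csv"))
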