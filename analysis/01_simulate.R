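#!/usr/bin/env Rscript
# Stage 1: simulate the study material.
#
# Generates a synthetic cohort of women (IC = interval cancer, SC =
# screen-detected cancer) together with one synthetic pre-diagnostic MLO
# mammogram per woman, with ground-truth masks. Everything downstream
# (02-04) runs from these files alone.

library(mammodense)

n <- 60L
seed <- 1701L   # fixed study seed for the demonstration run
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- generate_cohort(cohort_sim_params(n = n, seed = seed))
write_cohort(cohort, file.path(out, "cohort.csv"))

for (i in seq_len(n)) {
  sim <- generate_breast_image(image_sim_params(seed = seed + i))
  sim$image$id <- cohort$id[i]
  write_simulated_image(sim, out)
}

cat(sprintf("simulated %d women (%d IC / %d SC) and %d mammograms in %s\n",
            n, sum(cohort$outcome == "IC"), sum(cohort$outcome == "SC"), n,
            out))
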