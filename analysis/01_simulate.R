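#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohorts.
#
# One planted overlapping-network model (200 regions, K = 7, 30% of regions
# on 2-4 networks) stands in for the resting-state sample; two independent
# 20-subject cohorts drawn from it play the exploratory / confirmatory
# split-half samples, and their union is the combined sample. Subject
# timeseries go to scratch/ (large); the model definition is kept alongside.

suppressPackageStartupMessages(library(overnet))

seed <- 1L
model <- sample_planted_model(200, 7, frac_multi = 0.3, seed = seed)
cat(sprintf("planted model: %d regions, K = %d, %d multi-membership regions\n",
            model$n_regions, model$n_networks,
            sum(rowSums(model$membership > 0) > 1)))

cohort_a <- generate_cohort(model, 20, 300, seed = seed + 1L)
cohort_b <- generate_cohort(model, 20, 300, seed = seed + 2L)

dir.create("scratch/cohort_a", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch/cohort_b", recursive = TRUE, showWarnings = FALSE)
write_cohort(cohort_a, "scratch/cohort_a", model = model)
write_cohort(cohort_b, "scratch/cohort_b")
cat("wrote 2 x 20 subject timeseries under scratch/\n")
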