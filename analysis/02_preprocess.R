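#!/usr/bin/env Rscript

# Stage 2 — build sparse binary group connectomes.
#
# Per cohort: Fisher-z correlations per subject, negatives removed, top 10%
# of pairs retained and binarized, averaged across subjects, re-thresholded
# to the top 10%. Regions left without any edge are excluded from every
# downstream analysis (exclusion propagation).

suppressPackageStartupMessages(library(overnet))

read_dir <- function(d) {
  read_cohort(sort(list.files(d, pattern = "^sub.*tsv$", full.names = TRUE)))
}
cohort_a <- read_dir("scratch/cohort_a")
cohort_b <- read_dir("scratch/cohort_b")

ga <- build_group_connectome(cohort_a, 0.10)
gb <- build_group_connectome(cohort_b, 0.10)
dd <- drop_disconnected(ga, gb)
ga <- dd$connectomes[[1]]; gb <- dd$connectomes[[2]]

cat(sprintf("group connectomes: %d shared regions (%d excluded as disconnected)\n",
            length(ga$region_labels), length(dd$excluded)))
cat(sprintf("densities: %.4f / %.4f\n", ga$density, gb$density))

dir.create("scratch/connectomes", showWarnings = FALSE, recursive = TRUE)
write_edge_list(ga, "scratch/connectomes/groupA.edges")
write_edge_list(gb, "scratch/connectomes/groupB.edges")
write_matrix_tsv(ga, "scratch/connectomes/groupA_adj.tsv")
write_matrix_tsv(gb, "scratch/connectomes/groupB_adj.tsv")
writeLines(ga$region_labels, "scratch/connectomes/regions.txt")
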