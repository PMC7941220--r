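#!/usr/bin/env Rscript
## Step 1: simulate the synthetic cohort standing in for the study's subjects.
## Desk-scale conditions: 24x24x12 grid, 4 GM + 5 WM planted networks, 200
## volumes at TR 2 s, 12 pain + 12 control subjects, a +0.3 coupling increase
## on GM2-WM3 in the pain group, and behavioral scores whose change has a
## planted partial correlation of -0.31 with the GM4-WM2 edge.
library(gwnet)

dir.create("results", showWarnings = FALSE)
dir.create("scratch/analysis", recursive = TRUE, showWarnings = FALSE)

spec <- phantom_spec(seed = 20260920L)
truth <- generate_cohort(spec, "scratch/analysis/cohort")

cat("Simulated", nrow(truth$subjects), "subjects (",
    sum(truth$subjects$group == "pain"), "pain /",
    sum(truth$subjects$group == "control"), "control )\n")
cat("Planted parcels:", spec$n_gm_networks, "GM,", spec$n_wm_networks, "WM;",
    sum(truth$tissue == 1), "GM voxels,", sum(truth$tissue == 2),
    "WM voxels\n")

write.table(truth$subjects, "results/01_subjects.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(truth$behavior, "results/01_behavior.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(list(spec = spec, truth = truth), "scratch/analysis/01_cohort.rds")
cat("Cohort files in scratch/analysis/cohort; tables in results/\n")
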