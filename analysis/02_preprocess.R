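#!/usr/bin/env Rscript
## Step 2: group tissue masks, motion screening, and per-subject cleaning.
## Masks: 60% WM / 20% GM across-subject thresholds with deep-nuclei voxels
## relabeled from WM to GM via the atlas. Cleaning: drop 10 volumes, linear
## detrend, 0.01-0.1 Hz band-pass, regression of 24 motion parameters + mean
## CSF + FD > 1 mm spike indicators, then 4 mm FWHM smoothing restricted to
## each tissue mask.
library(gwnet)
library(RNifti)

st <- readRDS("scratch/analysis/01_cohort.rds")
spec <- st$spec; truth <- st$truth
gs <- spec$grid_shape

segs <- lapply(truth$files$seg, readNifti)
names(segs) <- truth$subjects$subject
atlas <- array(as.integer(readNifti(truth$files$atlas)), gs)
mask <- build_group_masks(segs, atlas)
print(mask)

screen <- do.call(rbind, lapply(truth$subjects$subject, function(id) {
  ex <- motion_exclusion(truth$motion[[id]])
  fd <- framewise_displacement(truth$motion[[id]])
  data.frame(subject = id, keep = ex$keep, reason = ex$reason,
             max_trans_mm = ex$max_translation_mm,
             max_rot_deg = ex$max_rotation_deg,
             n_fd_spikes = sum(fd > 1), mean_fd = mean(fd))
}))
write.table(screen, "results/02_motion_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
retained <- screen$subject[screen$keep]
cat("Retained", length(retained), "of", nrow(screen), "subjects;",
    sum(screen$n_fd_spikes), "spike volumes regressed in total\n")

csf <- which(as.integer(mask$mask_volume) == 0L)
series <- list(gm = list(), wm = list())
for (id in retained) {
  bold <- readNifti(file.path(truth$dir, paste0(id, "_bold.nii")))
  bm <- matrix(bold, ncol = dim(bold)[4])
  for (tis in c("gm", "wm"))
    series[[tis]][[id]] <- preprocess_tissue(
      bm, mask_voxels(mask, tis), truth$motion[[id]], csf,
      spec$tr_seconds, gs, spec$voxel_size_mm)
}
saveRDS(list(mask = mask, retained = retained, series = series),
        "scratch/analysis/02_clean.rds")
cat("Cleaned series:", length(retained), "subjects x {GM,WM} written to",
    "scratch/analysis/02_clean.rds\n")
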