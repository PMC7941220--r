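## End-to-end driver: phantom cohort -> group masks -> cleaning -> voxel-FC ->
## parcellation -> network statistics, plus Monte-Carlo helpers used by the
## validation studies.

#' Clean and smooth one subject's tissue series
#'
#' @param bold_mat full-grid voxel x time matrix.
#' @param voxels tissue mask voxel indices.
#' @param motion acquired motion trace.
#' @param csf_voxels indices for the mean-CSF regressor.
#' @param tr_seconds,grid_shape,voxel_size_mm geometry.
#' @param fwhm_mm smoothing kernel FWHM (mm).
#' @param ... further arguments to [clean_series()].
#' @return voxel x time matrix of cleaned, mask-smoothed series.
#' @export
preprocess_tissue <- function(bold_mat, voxels, motion, csf_voxels,
                              tr_seconds, grid_shape, voxel_size_mm,
                              fwhm_mm = 4, ...) {
  cs <- clean_series(bold_mat, voxels, motion, tr_seconds,
                     csf_voxels = csf_voxels, ...)
  smooth_within_mask(cs$series, voxels, grid_shape, fwhm_mm, voxel_size_mm)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the cohort on disk, builds the group masks from the per-subject
#' segmentations and the deep-nuclei atlas, applies the motion exclusion rule,
#' cleans and smooths each retained subject's GM and WM series, computes the
#' checkerboard-subsampled voxel-by-node correlation matrices, averages them
#' with subject-pairwise tissue masking, clusters the rows at the planted K
#' (and over `K_range` for the stability curve), and — optionally — computes
#' network-level statistics: Fisher-z FC matrices, one- and two-sample edge
#' tests with Bonferroni correction, gray-white loop detection, and the
#' behavioral partial correlation.
#'
#' @param spec a [phantom_spec()].
#' @param dir working directory for the cohort files (deleted afterwards
#'   unless `keep_files`).
#' @param K_range K values for the stability curve; default: planted K and
#'   planted K +/- 2, per tissue.
#' @param stability compute the fold-based Dice stability curves.
#' @param do_stats compute network-level statistics.
#' @param replicates K-means restarts.
#' @param keep_files keep the generated NIfTI/TSV files.
#' @return list with `truth`, `mask`, `retained` (subject ids),
#'   and per tissue (`gm`, `wm`): `grid`, `group_corr`, `rows`
#'   (clustered voxel indices), `labels_est`, `labels_true`, `stability`;
#'   plus `stats` when requested.
#' @export
run_phantom_pipeline <- function(spec = phantom_spec(),
                                 dir = tempfile("phantom"),
                                 K_range = NULL, stability = TRUE,
                                 do_stats = FALSE, replicates = 10,
                                 keep_files = FALSE) {
  truth <- generate_cohort(spec, dir)
  if (!keep_files) on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  gs <- spec$grid_shape

  segs <- lapply(truth$files$seg, RNifti::readNifti)
  names(segs) <- truth$subjects$subject
  atlas <- RNifti::readNifti(truth$files$atlas)
  mask <- build_group_masks(segs, array(as.integer(atlas), gs))

  keep <- vapply(truth$subjects$subject, function(id)
    motion_exclusion(truth$motion[[id]])$keep, TRUE)
  retained <- truth$subjects$subject[keep]

  csf_voxels <- which(as.integer(mask$mask_volume) == 0L)
  grids <- list(gm = checkerboard_nodes(mask$gm_voxels, gs),
                wm = checkerboard_nodes(mask$wm_voxels, gs))
  all_mask_vox <- c(mask$gm_voxels, mask$wm_voxels)

  series <- list(gm = list(), wm = list())
  corr <- list(gm = list(), wm = list())
  for (id in retained) {
    bold <- RNifti::readNifti(file.path(dir, paste0(id, "_bold.nii")))
    bm <- matrix(bold, ncol = dim(bold)[4])
    mot <- truth$motion[[id]]
    for (tis in c("gm", "wm")) {
      sm <- preprocess_tissue(bm, mask_voxels(mask, tis), mot, csf_voxels,
                              spec$tr_seconds, gs, spec$voxel_size_mm)
      series[[tis]][[id]] <- sm
      corr[[tis]][[id]] <- subject_corr(sm, grids[[tis]])
    }
    rm(bold, bm)
  }

  out <- list(truth = truth, mask = mask, retained = retained, spec = spec)
  true_lab_full <- list(gm = truth$gm_labels, wm = truth$wm_labels)
  true_K <- c(gm = spec$n_gm_networks, wm = spec$n_wm_networks)
  tis_code <- c(gm = 1L, wm = 2L)
  for (tis in c("gm", "wm")) {
    st <- mask$per_subject_tissue[retained,
                                  match(mask_voxels(mask, tis), all_mask_vox),
                                  drop = FALSE]
    gc_res <- group_average(corr[[tis]], st, grids[[tis]], tis_code[[tis]])
    cr <- clusterable_rows(gc_res)
    vox <- mask_voxels(mask, tis)[cr$rows]
    sol <- kmeans_rows(cr$x, true_K[[tis]], replicates,
                       seed = child_seed(spec$seed, 7L + tis_code[[tis]]))
    res <- list(grid = grids[[tis]], group_corr = gc_res, rows = vox,
                labels_est = sol$labels,
                labels_true = true_lab_full[[tis]][vox],
                solution = sol)
    if (stability) {
      kr <- K_range %||% ((true_K[[tis]] - 2):(true_K[[tis]] + 2))
      res$stability <- stability_profile(cr$x, K_range = kr,
                                         replicates = replicates,
                                         seed = child_seed(spec$seed,
                                                           20L + tis_code[[tis]]))
    }
    out[[tis]] <- res
  }

  if (do_stats)
    out$stats <- pipeline_stats(out, series, truth)
  out
}

## Map estimated cluster ids to planted network ids by majority overlap.
match_clusters <- function(labels_est, labels_true) {
  ct <- table(labels_est, labels_true)
  as.integer(colnames(ct))[max.col(ct, ties.method = "first")]
}

## Network-level statistics on the pipeline output. Estimated clusters are
## renamed by their majority planted network so edge names refer to planted
## networks (GM1.., WM1..).
pipeline_stats <- function(out, series, truth) {
  spec <- out$spec
  relab <- list()
  for (tis in c("gm", "wm")) {
    mp <- match_clusters(out[[tis]]$labels_est, out[[tis]]$labels_true)
    relab[[tis]] <- mp[out[[tis]]$labels_est]
  }
  all_vox <- list(gm = mask_voxels(out$mask, "gm"),
                  wm = mask_voxels(out$mask, "wm"))
  fc_list <- lapply(out$retained, function(id) {
    net <- rbind(
      network_timeseries(series$gm[[id]][match(out$gm$rows, all_vox$gm), ,
                                         drop = FALSE],
                         relab$gm, prefix = "GM"),
      network_timeseries(series$wm[[id]][match(out$wm$rows, all_vox$wm), ,
                                         drop = FALSE],
                         relab$wm, prefix = "WM"))
    fc_matrices(net)
  })
  names(fc_list) <- out$retained
  group <- truth$subjects$group[match(out$retained, truth$subjects$subject)]

  fam <- list()
  for (f in c("gm_gm", "wm_wm", "gm_wm")) {
    z <- collect_edges(fc_list, f)
    screen <- normality_screen(z, group)
    os <- one_sample_edges(z, group)
    ts <- if (length(os$tested_edges) >= 1)
      two_sample_edges(z, group, os$tested_edges) else NULL
    fam[[f]] <- list(z = z, screen = screen, one_sample = os,
                     two_sample = ts)
  }
  loops <- find_loops(Filter(Negate(is.null),
                             lapply(fam, `[[`, "two_sample")))

  beh <- truth$behavior[match(out$retained, truth$behavior$subject), ]
  pain <- beh$group == "pain"
  edge_name <- paste(spec$behavior_spec$edge, collapse = "-")
  z_cross <- fam$gm_wm$z
  pcor <- NULL
  if (edge_name %in% colnames(z_cross) && sum(pain) >= 5) {
    pcor <- behavior_partial_corr(z_cross[pain, edge_name],
                                  beh$vas_24h[pain] - beh$vas_pre[pain],
                                  beh$age[pain], beh$sex[pain])
    pcor$edge <- edge_name
  }
  list(families = fam, loops = loops, behavior_partial = pcor,
       fc_list = fc_list, group = group)
}

#' Monte-Carlo power of the planted group effect
#'
#' Simulates cohorts at the network-latent level (network time courses drawn
#' from the group coupling matrices plus voxel-averaging noise), runs the
#' one-sample screen and the Bonferroni-corrected two-sample comparison on the
#' cross-tissue family, and reports how often the planted edge is flagged.
#'
#' @param spec a [phantom_spec()]; its coupling matrices, group effect and
#'   noise define the simulation.
#' @param n_per_group subjects per group.
#' @param n_seeds number of simulated cohorts.
#' @param n_timepoints retained series length.
#' @param voxels_per_network voxel count whose averaging shrinks the noise.
#' @param alpha family-wise level.
#' @param seed base seed.
#' @return list: `power` (fraction flagged), `hits` (logical per seed),
#'   `edge`, `n_seeds`.
#' @export
edge_power_study <- function(spec = phantom_spec(), n_per_group = 20,
                             n_seeds = 100, n_timepoints = 195,
                             voxels_per_network = 8, alpha = 0.05,
                             seed = 1L) {
  ge <- spec$group_effect[[1]]
  edge <- paste0(ge$a, "-", ge$b)
  n_net <- length(spec$net_names)
  sd_net <- spec$noise_sd / sqrt(voxels_per_network)
  hits <- vapply(seq_len(n_seeds), function(i) {
    with_seed(child_seed(seed, i), {
      fc_list <- c(
        lapply(seq_len(n_per_group), function(s) {
          L <- generate_latents(spec$coupling_pain, n_timepoints) +
            matrix(stats::rnorm(n_net * n_timepoints, sd = sd_net), n_net)
          fc_matrices(L)
        }),
        lapply(seq_len(n_per_group), function(s) {
          L <- generate_latents(spec$coupling, n_timepoints) +
            matrix(stats::rnorm(n_net * n_timepoints, sd = sd_net), n_net)
          fc_matrices(L)
        }))
      names(fc_list) <- sprintf("s%02d", seq_along(fc_list))
      group <- rep(c("pain", "control"), each = n_per_group)
      z <- collect_edges(fc_list, "gm_wm")
      os <- one_sample_edges(z, group, alpha)
      if (!(edge %in% os$tested_edges)) return(FALSE)
      ts <- two_sample_edges(z, group, os$tested_edges, alpha)
      isTRUE(ts$significant[ts$edge == edge])
    })
  }, TRUE)
  list(power = mean(hits), hits = hits, edge = edge, n_seeds = n_seeds)
}

#' Apply the subject-retention screen to a simulated recruitment
#'
#' Generates one motion trace per recruited subject (the first
#' `n_high_motion` with sustained >2 mm translation), applies
#' [motion_exclusion()], and removes `n_other_excluded` further subjects
#' (non-imaging exclusions, e.g. incidental findings).
#'
#' @param n_recruited recruited subjects.
#' @param n_high_motion subjects given exclusion-level head motion.
#' @param n_other_excluded subjects excluded for non-motion reasons.
#' @param n_timepoints volumes per run.
#' @param seed integer.
#' @return list: `n_retained`, `kept` (logical over recruits),
#'   `n_motion_excluded`.
#' @export
screen_recruitment <- function(n_recruited, n_high_motion = 0,
                               n_other_excluded = 0, n_timepoints = 205,
                               seed = 1L) {
  stopifnot(n_high_motion + n_other_excluded <= n_recruited)
  kept <- with_seed(seed, vapply(seq_len(n_recruited), function(s) {
    mot <- inject_motion(n_timepoints, high_motion = s <= n_high_motion)
    motion_exclusion(mot)$keep
  }, TRUE))
  n_ret <- sum(kept) - n_other_excluded
  list(n_retained = n_ret, kept = kept,
       n_motion_excluded = sum(!kept))
}

#' Planted-partition recovery study over multiple phantom seeds
#'
#' Runs the full pipeline on freshly generated phantom cohorts and summarizes
#' how well the parcellation recovers the planted networks: the adjusted Rand
#' index (ARI) between estimated and planted labels at the planted K, and the
#' stability curve's Dice margin between the planted K and K +/- 2.
#'
#' @param n_seeds number of independent cohorts.
#' @param base_seed seed from which the per-cohort seeds are derived.
#' @param spec_fn function(seed) returning the [phantom_spec()] to run.
#' @param replicates K-means restarts.
#' @return data.frame with one row per seed: ari_gm, ari_wm, and per tissue
#'   the Dice at planted K and at K -/+ 2.
#' @export
planted_recovery_study <- function(n_seeds = 10, base_seed = 1L,
                                   spec_fn = function(s) phantom_spec(seed = s),
                                   replicates = 10) {
  if (!requireNamespace("mclust", quietly = TRUE))
    stop("planted_recovery_study needs the mclust package for the ARI")
  rows <- lapply(seq_len(n_seeds), function(i) {
    spec <- spec_fn(child_seed(base_seed, 1000L + i))
    res <- run_phantom_pipeline(spec, stability = TRUE, do_stats = FALSE,
                                replicates = replicates)
    row <- list(seed = spec$seed)
    for (tis in c("gm", "wm")) {
      tk <- if (tis == "gm") spec$n_gm_networks else spec$n_wm_networks
      cv <- res[[tis]]$stability$curve
      row[[paste0("ari_", tis)]] <-
        mclust::adjustedRandIndex(res[[tis]]$labels_est,
                                  res[[tis]]$labels_true)
      row[[paste0("dice_true_", tis)]] <- cv$mean_dice[cv$K == tk]
      row[[paste0("dice_minus2_", tis)]] <- cv$mean_dice[cv$K == tk - 2]
      row[[paste0("dice_plus2_", tis)]] <- cv$mean_dice[cv$K == tk + 2]
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}
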