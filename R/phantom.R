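## Synthetic resting-state BOLD phantom with planted gray- and white-matter
## networks. The phantom emulates the study conditions the pipeline was built
## for: two groups, ~195 retained volumes at TR 2 s, tissue-segmented voxel
## populations whose correlation structure is controlled exactly, head-motion
## traces with optional spikes, and behavioral scores tied to one network edge.

#' Specify a synthetic BOLD cohort
#'
#' Builds and validates the parameter object consumed by [generate_cohort()].
#' Planted networks are spatially contiguous blocks: gray matter (GM) occupies
#' the lower interior slab of the grid, white matter (WM) the upper slab, and a
#' small deep-nuclei block sits inside the WM slab (true deep gray matter that
#' every subject's segmentation mislabels as WM, exercising the atlas-based
#' relabeling in [build_group_masks()]). Latent network time courses are drawn
#' with population correlation matrix exactly equal to `coupling` via a
#' Cholesky transform of independent Gaussian series; the pain group receives
#' `group_effect` deltas on chosen edges.
#'
#' @param grid_shape integer 3-vector, voxels per axis.
#' @param n_timepoints number of volumes acquired (before dropping any).
#' @param tr_seconds repetition time in seconds.
#' @param n_gm_networks,n_wm_networks number of planted networks per tissue
#'   (each at least 2).
#' @param coupling symmetric correlation matrix over all planted network
#'   latents, ordered GM1..GMg then WM1..WMw. Default: unit diagonal, 0.1
#'   baseline everywhere, 0.5 on cross-tissue pairs (GMi, WMi).
#' @param group_effect list of `list(a=, b=, delta_r=)` edges (network names)
#'   whose coupling is shifted by `delta_r` in the pain group.
#' @param noise_sd standard deviation of the independent Gaussian noise added
#'   to each voxel series on top of its network latent (latents have unit
#'   variance).
#' @param n_subjects_per_group integer 2-vector: pain group, control group.
#' @param motion_spec list with fields `baseline_trans_sd`, `baseline_rot_sd`
#'   (random-walk increment SDs, mm and radians), `n_spikes_range` (integer
#'   2-vector), `spike_amp_range` (mm), `high_motion` (character vector of
#'   subject ids to give >2 mm sustained translation).
#' @param behavior_spec list with the behavioral edge (`edge`, two network
#'   names), the target partial correlation between that edge's Fisher z and
#'   the VAS change controlling age and sex (`partial_r`), and score
#'   means/SDs (`vas_pre_mean`, `vas_pre_sd`, `vas_change_mean`,
#'   `vas_change_sd`, `sai_pre_mean`, `sai_pre_sd`, `sai_change_mean`,
#'   `sai_change_sd`).
#' @param voxel_size_mm isotropic voxel size written to the NIfTI headers.
#' @param artifacts add the nuisance structure the cleaning stage removes
#'   (baseline offset, linear trend, slow drift, shared physiological signal,
#'   motion-coupled component, spike artifacts); `FALSE` gives bare
#'   latent-plus-noise voxels, so with `noise_sd = 0` every voxel equals its
#'   network latent exactly.
#' @param seed integer; the whole cohort is a deterministic function of it.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 12L),
                         n_timepoints = 200L,
                         tr_seconds = 2,
                         n_gm_networks = 4L,
                         n_wm_networks = 5L,
                         coupling = NULL,
                         group_effect = list(list(a = "GM2", b = "WM3",
                                                  delta_r = 0.3)),
                         noise_sd = 0.4,
                         n_subjects_per_group = c(12L, 12L),
                         motion_spec = list(),
                         behavior_spec = list(),
                         voxel_size_mm = 3,
                         artifacts = TRUE,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            n_timepoints >= 20, tr_seconds > 0,
            n_gm_networks >= 2, n_wm_networks >= 2,
            noise_sd >= 0, length(n_subjects_per_group) == 2,
            all(n_subjects_per_group >= 1))
  n_net <- n_gm_networks + n_wm_networks
  net_names <- c(paste0("GM", seq_len(n_gm_networks)),
                 paste0("WM", seq_len(n_wm_networks)))
  if (is.null(coupling)) {
    coupling <- matrix(0.1, n_net, n_net)
    for (i in seq_len(min(n_gm_networks, n_wm_networks))) {
      coupling[i, n_gm_networks + i] <- 0.5
      coupling[n_gm_networks + i, i] <- 0.5
    }
    diag(coupling) <- 1
  }
  dimnames(coupling) <- list(net_names, net_names)
  check_coupling <- function(C, what) {
    if (!isSymmetric(unname(C), tol = 1e-10))
      stop(what, " matrix must be symmetric")
    if (any(abs(diag(C) - 1) > 1e-10))
      stop(what, " matrix must have unit diagonal")
    if (any(C < -1 | C > 1)) stop(what, " entries must lie in [-1, 1]")
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10)
      stop(what, " matrix is not positive semidefinite (min eigenvalue ",
           signif(ev, 3), ")")
  }
  check_coupling(coupling, "coupling")
  coupling_pain <- coupling
  for (ge in group_effect) {
    ia <- match(ge$a, net_names); ib <- match(ge$b, net_names)
    if (is.na(ia) || is.na(ib))
      stop("group_effect names unknown network: ", ge$a, "-", ge$b)
    coupling_pain[ia, ib] <- coupling_pain[ia, ib] + ge$delta_r
    coupling_pain[ib, ia] <- coupling_pain[ia, ib]
  }
  check_coupling(coupling_pain, "coupling-plus-group-effect")

  motion_defaults <- list(baseline_trans_sd = 0.01, baseline_rot_sd = 1e-4,
                          n_spikes_range = c(0L, 2L),
                          spike_amp_range = c(1.2, 1.5),
                          high_motion = character(0))
  motion_spec <- utils::modifyList(motion_defaults, motion_spec)
  behavior_defaults <- list(edge = c("GM4", "WM2"), partial_r = -0.31,
                            vas_pre_mean = 13.66, vas_pre_sd = 16.35,
                            vas_change_mean = 6.82, vas_change_sd = 12,
                            sai_pre_mean = 27.73, sai_pre_sd = 11.00,
                            sai_change_mean = 2.09, sai_change_sd = 6)
  behavior_spec <- utils::modifyList(behavior_defaults, behavior_spec)
  if (any(is.na(match(behavior_spec$edge, net_names))))
    stop("behavior_spec$edge names unknown network")

  spec <- structure(list(
    grid_shape = as.integer(grid_shape), n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, n_gm_networks = as.integer(n_gm_networks),
    n_wm_networks = as.integer(n_wm_networks), net_names = net_names,
    coupling = coupling, coupling_pain = coupling_pain,
    group_effect = group_effect, noise_sd = noise_sd,
    n_subjects_per_group = as.integer(n_subjects_per_group),
    motion_spec = motion_spec, behavior_spec = behavior_spec,
    voxel_size_mm = voxel_size_mm, artifacts = isTRUE(artifacts),
    seed = as.integer(seed)),
    class = "phantom_spec")
  layout <- phantom_layout(spec)
  sizes <- c(tabulate(layout$gm_labels[layout$gm_labels > 0L], n_gm_networks),
             tabulate(layout$wm_labels[layout$wm_labels > 0L], n_wm_networks))
  if (any(sizes < 8))
    stop("grid too small: planted parcels must have at least 8 voxels, got ",
         min(sizes))
  spec$layout <- layout
  spec
}

## Axis-aligned box utilities for the planted-parcel layout --------------------

box_volume <- function(b) prod(vapply(b, function(r) r[2] - r[1] + 1, 0))

box_voxels <- function(b, grid_shape) {
  g <- expand.grid(x = b$x[1]:b$x[2], y = b$y[1]:b$y[2], z = b$z[1]:b$z[2])
  coord_to_index(as.matrix(g), grid_shape)
}

## Split a box into n contiguous sub-boxes of near-equal volume by recursively
## cutting the longest axis at the proportional point.
partition_box <- function(box, n) {
  if (n == 1) return(list(box))
  n1 <- n %/% 2L
  lens <- vapply(box, function(r) r[2] - r[1] + 1, 0)
  ax <- names(box)[which.max(lens)]
  cut <- as.integer(box[[ax]][1] + max(1, round(lens[[ax]] * n1 / n)) - 1)
  cut <- min(cut, as.integer(box[[ax]][2]) - 1L)
  b1 <- box; b1[[ax]] <- c(box[[ax]][1], cut)
  b2 <- box; b2[[ax]] <- c(cut + 1L, box[[ax]][2])
  c(partition_box(b1, n1), partition_box(b2, n - n1))
}

## Tissue layout: GM slab in the lower interior of the grid, WM slab above it,
## a 3x3x3 deep-nuclei block inside the WM slab touching the GM/WM boundary,
## everything else CSF/background.
phantom_layout <- function(spec) {
  gs <- spec$grid_shape
  xr <- c(3L, gs[1] - 2L); yr <- c(3L, gs[2] - 2L); zr <- c(2L, gs[3] - 1L)
  nz <- zr[2] - zr[1] + 1L
  z_cut <- zr[1] + nz %/% 2L - 1L
  gm_box <- list(x = xr, y = yr, z = c(zr[1], z_cut))
  wm_box <- list(x = xr, y = yr, z = c(z_cut + 1L, zr[2]))
  cx <- (xr[1] + xr[2]) %/% 2L
  cy <- (yr[1] + yr[2]) %/% 2L
  nuc_box <- list(x = c(cx - 1L, cx + 1L), y = c(cy - 1L, cy + 1L),
                  z = c(z_cut + 1L, min(z_cut + 3L, zr[2])))
  gm_blocks <- partition_box(gm_box, spec$n_gm_networks)
  wm_blocks <- partition_box(wm_box, spec$n_wm_networks)

  lab <- function(blocks) {
    v <- integer(prod(gs))
    for (k in seq_along(blocks)) v[box_voxels(blocks[[k]], gs)] <- k
    v
  }
  gm_lab <- lab(gm_blocks)
  wm_lab <- lab(wm_blocks)
  ## Separate same-tissue parcels by a CSF furrow so mask-restricted
  ## smoothing cannot couple neighboring parcels; otherwise the shared
  ## boundary signal induces a spurious deterministic parcel hierarchy.
  furrow <- function(lv) {
    tis3 <- array(lv, gs)
    idx <- which(lv > 0L)
    co <- index_to_coord(idx, gs)
    gap <- logical(length(idx))
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      nb <- sweep(co, 2, off, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= gs[1] & nb[, 2] >= 1 &
        nb[, 2] <= gs[2] & nb[, 3] >= 1 & nb[, 3] <= gs[3]
      nbv <- rep(0L, length(idx))
      nbv[ok] <- tis3[coord_to_index(nb[ok, , drop = FALSE], gs)]
      gap <- gap | (nbv > 0L & nbv != lv[idx])
    }
    lv[idx[gap]] <- 0L
    lv
  }
  gm_lab <- furrow(gm_lab)
  wm_lab <- furrow(wm_lab)
  nuc_idx <- box_voxels(nuc_box, gs)
  ## Deep nuclei are true gray matter: carve them out of the WM parcels and
  ## give them the latent of the majority GM parcel directly beneath them.
  nuc_co <- index_to_coord(nuc_idx, gs)
  below <- coord_to_index(cbind(nuc_co[, 1], nuc_co[, 2], z_cut), gs)
  bl <- gm_lab[below]
  nuc_lab <- if (any(bl > 0L)) as.integer(names(which.max(table(bl[bl > 0L]))))
             else 1L
  gm_lab[nuc_idx] <- nuc_lab
  wm_lab[nuc_idx] <- 0L

  tissue <- integer(prod(gs))            # 0 = CSF/background, 1 = GM, 2 = WM
  tissue[gm_lab > 0L] <- 1L
  tissue[wm_lab > 0L] <- 2L

  atlas <- integer(prod(gs))
  nuc_parts <- partition_box(nuc_box, 5L)  # thalamus, caudate, putamen,
  for (k in 1:5) atlas[box_voxels(nuc_parts[[k]], gs)] <- k  # pallidum, accumbens
  list(gm_box = gm_box, wm_box = wm_box, nuclei_box = nuc_box,
       gm_blocks = gm_blocks, wm_blocks = wm_blocks,
       gm_labels = gm_lab, wm_labels = wm_lab, tissue = tissue,
       atlas = atlas, nuclei_voxels = nuc_idx)
}

#' Draw latent network time courses with exact population correlation
#'
#' Independent unit-variance Gaussian series are mixed through the upper
#' Cholesky factor of `C`, so the population correlation matrix of the rows is
#' exactly `C`.
#'
#' @param C correlation matrix (networks x networks).
#' @param n_timepoints series length.
#' @return matrix networks x time, rownames from `C`.
#' @export
generate_latents <- function(C, n_timepoints) {
  R <- chol(C)                                  # errors if not PD
  Z <- matrix(stats::rnorm(nrow(C) * n_timepoints), nrow = nrow(C))
  X <- t(R) %*% Z
  rownames(X) <- rownames(C)
  X
}

#' Generate a head-motion trace
#'
#' Baseline motion is a smooth low-amplitude random walk; requested spikes add
#' a single-volume translation step large enough that framewise displacement
#' exceeds any conventional scrubbing threshold at the spike time. A
#' "high-motion" subject additionally receives a slow sinusoidal drift taking
#' x-translation beyond 2 mm, so the subject fails the stated exclusion rule.
#'
#' @param n_timepoints number of volumes.
#' @param spikes data.frame with columns `time` (volume index) and
#'   `amplitude_mm`; may have zero rows.
#' @param high_motion logical.
#' @param baseline_trans_sd,baseline_rot_sd increment SDs of the baseline
#'   random walk (mm, radians).
#' @return numeric matrix n_timepoints x 6 (3 translations mm, 3 rotations
#'   radians).
#' @export
inject_motion <- function(n_timepoints, spikes = NULL, high_motion = FALSE,
                          baseline_trans_sd = 0.01, baseline_rot_sd = 1e-4) {
  n <- as.integer(n_timepoints)
  m <- cbind(
    apply(matrix(stats::rnorm(3L * n, sd = baseline_trans_sd), n), 2, cumsum),
    apply(matrix(stats::rnorm(3L * n, sd = baseline_rot_sd), n), 2, cumsum))
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  if (!is.null(spikes) && nrow(spikes) > 0) {
    stopifnot(all(spikes$time >= 1), all(spikes$time <= n))
    for (i in seq_len(nrow(spikes)))
      m[spikes$time[i], 1] <- m[spikes$time[i], 1] + spikes$amplitude_mm[i]
  }
  if (high_motion)
    m[, 1] <- m[, 1] + 2.5 * sin(2 * pi * seq_len(n) / n)
  m
}

#' Generate a synthetic cohort on disk
#'
#' Writes, per subject, a 4D BOLD NIfTI, a 6-column motion TSV and a tissue
#' label NIfTI (0 = CSF/background, 1 = GM, 2 = WM); plus one deep-nuclei
#' atlas NIfTI and one behavior TSV for the cohort. Every voxel series is its
#' planted network latent plus independent Gaussian noise, on top of nuisance
#' structure the cleaning stage is expected to remove: a baseline offset, a
#' random linear trend, a slow (0.005 Hz) scanner drift, a global
#' physiological signal shared with CSF, a motion-coupled component, and
#' large spike artifacts at high-motion volumes. Deep-nuclei voxels carry a GM
#' latent but are labeled WM in every subject's segmentation; other voxels at
#' the GM/WM interface are mislabeled with probability `flip_p`, creating
#' between-subject segmentation disagreement for the pairwise-masked group
#' averaging. The VAS change of pain-group subjects is constructed to have the
#' target partial correlation (given age and sex) with the Fisher z of the
#' behavioral edge's latent correlation. Output is a deterministic function of
#' `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if needed).
#' @param flip_p per-voxel probability of a GM/WM mislabel at tissue-boundary
#'   voxels in each subject's segmentation.
#' @return invisibly, a `phantom_truth` list: layout, planted labels, subject
#'   table, behavior table, per-subject latent series and file paths.
#' @export
generate_cohort <- function(spec, dir, flip_p = 0.1) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  gs <- spec$grid_shape
  lay <- spec$layout
  n_vox <- prod(gs)
  Tn <- spec$n_timepoints
  n_pain <- spec$n_subjects_per_group[1]
  n_ctrl <- spec$n_subjects_per_group[2]
  ids <- c(sprintf("pain%02d", seq_len(n_pain)),
           sprintf("ctrl%02d", seq_len(n_ctrl)))
  groups <- rep(c("pain", "control"), c(n_pain, n_ctrl))

  subjects <- data.frame(
    subject = ids, group = groups,
    age = sample(19:30, length(ids), replace = TRUE),
    sex = unlist(lapply(c(n_pain, n_ctrl),
                        function(n) rep_len(c(0L, 1L), n))),
    stringsAsFactors = FALSE)

  ## Voxel -> latent-row map over the combined network ordering GM..WM
  net_of_voxel <- integer(n_vox)
  net_of_voxel[lay$gm_labels > 0L] <- lay$gm_labels[lay$gm_labels > 0L]
  wm_in <- lay$wm_labels > 0L
  net_of_voxel[wm_in] <- spec$n_gm_networks + lay$wm_labels[wm_in]
  brain <- which(net_of_voxel > 0L)
  csf <- which(net_of_voxel == 0L)

  ## Boundary voxels eligible for segmentation label flips (6-neighborhood
  ## GM/WM contact, excluding the always-mislabeled deep nuclei).
  tis3 <- array(lay$tissue, gs)
  boundary <- boundary_gm_wm(tis3)
  boundary <- setdiff(boundary, lay$nuclei_voxels)

  t_idx <- seq_len(Tn)
  tsec <- (t_idx - 1) * spec$tr_seconds
  atlas_file <- file.path(dir, "atlas_deep_nuclei.nii")
  write_label_nifti(array(lay$atlas, gs), atlas_file, spec$voxel_size_mm)

  latents <- vector("list", length(ids)); names(latents) <- ids
  motion_list <- vector("list", length(ids)); names(motion_list) <- ids
  seg_list <- vector("list", length(ids)); names(seg_list) <- ids
  files <- list(atlas = atlas_file, bold = character(0), motion = character(0),
                seg = character(0))

  for (s in seq_along(ids)) {
    id <- ids[s]
    C <- if (groups[s] == "pain") spec$coupling_pain else spec$coupling
    L <- generate_latents(C, Tn)
    latents[[id]] <- L

    ## motion
    ms <- spec$motion_spec
    n_spk <- sample(ms$n_spikes_range[1]:ms$n_spikes_range[2], 1)
    spikes <- NULL
    if (n_spk > 0)
      spikes <- data.frame(
        time = sample(15:(Tn - 5), n_spk),
        amplitude_mm = stats::runif(n_spk, ms$spike_amp_range[1],
                                    ms$spike_amp_range[2]))
    mot <- inject_motion(Tn, spikes, high_motion = id %in% ms$high_motion,
                         baseline_trans_sd = ms$baseline_trans_sd,
                         baseline_rot_sd = ms$baseline_rot_sd)
    motion_list[[id]] <- mot

    ## nuisance structure
    drift <- 0.5 * sin(2 * pi * 0.005 * tsec + stats::runif(1, 0, 2 * pi))
    physio <- bandpass_ideal(matrix(stats::rnorm(Tn), 1), spec$tr_seconds,
                             c(0.01, 0.1))[1, ]
    physio <- 0.3 * physio / stats::sd(physio)
    mot_std <- as.numeric(scale(mot[, 1]))
    spike_vols <- if (!is.null(spikes)) spikes$time else integer(0)

    ## assemble voxel x time data
    dat <- matrix(0, nrow = n_vox, ncol = Tn)
    dat[brain, ] <- L[net_of_voxel[brain], , drop = FALSE]
    dat[csf, ] <- matrix(stats::rnorm(length(csf) * Tn, sd = 0.5),
                         length(csf))
    dat <- dat + matrix(stats::rnorm(n_vox * Tn, sd = spec$noise_sd), n_vox)
    if (spec$artifacts) {
      dat <- dat + 100 +
        outer(stats::rnorm(n_vox, sd = 1), (tsec - mean(tsec)) / max(tsec)) +
        outer(rep(1, n_vox), drift + physio) +
        outer(stats::rnorm(n_vox, sd = 0.3), mot_std)
      if (length(spike_vols))
        dat[, spike_vols] <- dat[, spike_vols] +
          matrix(stats::rnorm(n_vox * length(spike_vols), sd = 3), n_vox)
    }

    ## per-subject segmentation: truth, nuclei forced to WM, boundary flips
    seg <- lay$tissue
    seg[lay$nuclei_voxels] <- 2L
    flip <- boundary[stats::runif(length(boundary)) < flip_p]
    seg[flip] <- ifelse(seg[flip] == 1L, 2L, 1L)
    seg_list[[id]] <- seg

    bf <- file.path(dir, paste0(id, "_bold.nii"))
    write_bold_nifti(array(dat, c(gs, Tn)), bf, spec$voxel_size_mm,
                     spec$tr_seconds)
    mf <- file.path(dir, paste0(id, "_motion.tsv"))
    utils::write.table(as.data.frame(mot), mf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    sf <- file.path(dir, paste0(id, "_seg.nii"))
    write_label_nifti(array(seg, gs), sf, spec$voxel_size_mm)
    files$bold <- c(files$bold, bf)
    files$motion <- c(files$motion, mf)
    files$seg <- c(files$seg, sf)
  }

  behavior <- make_behavior(spec, subjects, latents)
  bf <- file.path(dir, "behavior.tsv")
  utils::write.table(behavior, bf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files$behavior <- bf

  truth <- structure(list(
    spec = spec, layout = lay, subjects = subjects, behavior = behavior,
    gm_labels = lay$gm_labels, wm_labels = lay$wm_labels,
    tissue = lay$tissue, net_of_voxel = net_of_voxel,
    latents = latents, motion = motion_list, segmentations = seg_list,
    files = files, dir = dir), class = "phantom_truth")
  invisible(truth)
}

## Voxels whose 6-neighborhood contains the other tissue class (GM vs WM).
boundary_gm_wm <- function(tissue3) {
  gs <- dim(tissue3)
  idx <- which(tissue3 > 0L)
  co <- index_to_coord(idx, gs)
  out <- logical(length(idx))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= gs[1] & nb[, 2] >= 1 & nb[, 2] <= gs[2] &
      nb[, 3] >= 1 & nb[, 3] <= gs[3]
    nbv <- rep(0L, length(idx))
    nbv[ok] <- tissue3[coord_to_index(nb[ok, , drop = FALSE], gs)]
    out <- out | (nbv > 0L & nbv != tissue3[idx])
  }
  idx[out]
}

## Behavioral table: VAS/SAI at baseline and 24 h. The pain group's VAS change
## is built from the standardized residual (on age, sex) of the behavioral
## edge's latent Fisher z, mixed with noise so its population partial
## correlation with that z equals behavior_spec$partial_r.
make_behavior <- function(spec, subjects, latents) {
  bs <- spec$behavior_spec
  n <- nrow(subjects)
  pain <- subjects$group == "pain"
  ia <- match(bs$edge[1], spec$net_names)
  ib <- match(bs$edge[2], spec$net_names)
  z_edge <- vapply(latents[subjects$subject[pain]], function(L)
    atanh(stats::cor(L[ia, ], L[ib, ])), 0)

  vas_pre <- stats::rnorm(n, bs$vas_pre_mean, bs$vas_pre_sd)
  sai_pre <- stats::rnorm(n, bs$sai_pre_mean, bs$sai_pre_sd)
  vas_24h <- rep(NA_real_, n); sai_24h <- rep(NA_real_, n)

  np <- sum(pain)
  if (np >= 6) {
    X <- cbind(1, subjects$age[pain], subjects$sex[pain])
    rz <- stats::lm.fit(X, z_edge)$residuals
    rz <- as.numeric(scale(rz))
    ## noise orthogonal to both covariates and the edge signal, so the
    ## planted partial correlation is exact in-sample, not just in expectation
    eps <- stats::lm.fit(cbind(X, rz), stats::rnorm(np))$residuals
    eps <- as.numeric(scale(eps))
    delta_std <- bs$partial_r * rz + sqrt(1 - bs$partial_r^2) * eps
  } else {
    ## too few pain subjects to anchor the partial correlation: plain noise
    delta_std <- stats::rnorm(np)
  }
  delta <- bs$vas_change_mean + bs$vas_change_sd * delta_std +
    0.5 * (subjects$age[pain] - mean(subjects$age[pain])) +
    2 * (subjects$sex[pain] - 0.5)
  vas_24h[pain] <- vas_pre[pain] + delta
  sai_24h[pain] <- sai_pre[pain] + bs$sai_change_mean +
    stats::rnorm(np, 0, bs$sai_change_sd)
  ## controls never receive the separator: no follow-up scores
  vas_pre[!pain] <- NA_real_; sai_pre[!pain] <- NA_real_

  data.frame(subject = subjects$subject, group = subjects$group,
             age = subjects$age, sex = subjects$sex,
             vas_pre = vas_pre, vas_24h = vas_24h,
             sai_pre = sai_pre, sai_24h = sai_24h,
             stringsAsFactors = FALSE)
}

## NIfTI writers -----------------------------------------------------------

write_bold_nifti <- function(arr4, path, voxel_size_mm, tr_seconds) {
  img <- RNifti::asNifti(arr4)
  img <- RNifti::`pixdim<-`(img, c(rep(voxel_size_mm, 3), tr_seconds))
  RNifti::writeNifti(img, path)
  path
}

write_label_nifti <- function(arr3, path, voxel_size_mm) {
  img <- RNifti::asNifti(array(as.integer(arr3), dim(arr3)))
  img <- RNifti::`pixdim<-`(img, rep(voxel_size_mm, 3))
  RNifti::writeNifti(img, path, datatype = "int16")
  path
}
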