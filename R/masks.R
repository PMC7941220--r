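## Group-level tissue masks from per-subject segmentations, with deep-nuclei
## relabeling from an atlas.

#' Hard tissue labels from a probability or label volume
#'
#' A 4D array (x, y, z, class) of probabilities for CSF/GM/WM is reduced to a
#' per-voxel maximum-probability label; ties favor GM over WM over CSF. A 3D
#' array is assumed to already hold labels 0/1/2 and is returned as integer.
#'
#' @param seg 3D label array (0 = CSF/background, 1 = GM, 2 = WM) or 4D
#'   probability array with classes ordered CSF, GM, WM.
#' @return integer 3D array of labels.
#' @export
hard_tissue_labels <- function(seg) {
  d <- dim(seg)
  if (length(d) == 3) return(array(as.integer(seg), d))
  stopifnot(length(d) == 4, d[4] == 3)
  p <- matrix(seg, ncol = 3)
  ## tie-break preference GM (1) > WM (2) > CSF (0)
  pref <- p[, c(2, 3, 1)]
  lab <- c(1L, 2L, 0L)[max.col(pref, ties.method = "first")]
  array(lab, d[1:3])
}

#' Build disjoint group-level GM and WM masks
#'
#' A voxel enters the WM mask when the across-subject fraction of WM labels is
#' at least `wm_thresh`; deep-nuclei voxels (non-zero in `atlas`) are then
#' removed from WM and added to GM unconditionally. A voxel enters the GM mask
#' when its GM fraction is at least `gm_thresh` and it is not already WM. The
#' two masks are disjoint by construction; voxel ordering is ascending linear
#' index (x-fastest).
#'
#' @param segmentations list of per-subject segmentation volumes (3D label or
#'   4D probability arrays, see [hard_tissue_labels()]).
#' @param atlas 3D integer array; non-zero codes mark deep gray nuclei
#'   (thalamus, caudate, putamen, pallidum, accumbens).
#' @param wm_thresh,gm_thresh inclusion thresholds in (0, 1], compared with
#'   `>=`.
#' @return object of class `group_mask`: `grid_shape`, `wm_voxels`,
#'   `gm_voxels` (ordered linear indices), `per_subject_tissue`
#'   (subject x voxel integer matrix over `c(gm_voxels, wm_voxels)`),
#'   `mask_volume` (3D array, 0/1/2).
#' @export
build_group_masks <- function(segmentations, atlas, wm_thresh = 0.60,
                              gm_thresh = 0.20) {
  stopifnot(length(segmentations) >= 1,
            wm_thresh > 0, wm_thresh <= 1, gm_thresh > 0, gm_thresh <= 1)
  labs <- lapply(segmentations, hard_tissue_labels)
  gs <- dim(labs[[1]])
  if (!all(vapply(labs, function(l) identical(dim(l), gs), TRUE)) ||
      !identical(dim(atlas)[1:3], gs))
    stop("all segmentations and the atlas must share one grid")

  n <- length(labs)
  wm_frac <- Reduce(`+`, lapply(labs, function(l) l == 2L)) / n
  gm_frac <- Reduce(`+`, lapply(labs, function(l) l == 1L)) / n
  nuclei <- as.integer(atlas) != 0L

  wm_pre <- as.vector(wm_frac >= wm_thresh)
  wm <- wm_pre & !nuclei
  gm <- (as.vector(gm_frac >= gm_thresh) & !wm_pre) | (wm_pre & nuclei)

  wm_voxels <- which(wm)
  gm_voxels <- which(gm)
  if (!length(wm_voxels) || !length(gm_voxels))
    stop("empty mask: ", length(gm_voxels), " GM and ", length(wm_voxels),
         " WM voxels at thresholds ", gm_thresh, "/", wm_thresh)

  all_vox <- c(gm_voxels, wm_voxels)
  per_subject <- do.call(rbind, lapply(labs, function(l) as.integer(l)[all_vox]))
  rownames(per_subject) <- names(segmentations)
  colnames(per_subject) <- as.character(all_vox)
  ## the atlas identifies deep-nuclei voxels as gray matter regardless of the
  ## segmentation, so the correction applies to the per-subject labels used
  ## for pairwise masking as well
  relabeled <- all_vox %in% which(wm_pre & nuclei)
  per_subject[, relabeled] <- 1L

  vol <- integer(prod(gs))
  vol[gm_voxels] <- 1L
  vol[wm_voxels] <- 2L
  structure(list(grid_shape = gs, wm_voxels = wm_voxels,
                 gm_voxels = gm_voxels, per_subject_tissue = per_subject,
                 mask_volume = array(vol, gs),
                 wm_thresh = wm_thresh, gm_thresh = gm_thresh),
            class = "group_mask")
}

#' @export
print.group_mask <- function(x, ...) {
  cat("group_mask: grid", paste(x$grid_shape, collapse = "x"), "-",
      length(x$gm_voxels), "GM voxels,", length(x$wm_voxels), "WM voxels\n")
  invisible(x)
}

#' Voxel indices of one tissue in a group mask
#'
#' @param mask a `group_mask`.
#' @param tissue `"gm"` or `"wm"`.
#' @return ordered linear voxel indices.
#' @export
mask_voxels <- function(mask, tissue = c("gm", "wm")) {
  tissue <- match.arg(tissue)
  if (tissue == "gm") mask$gm_voxels else mask$wm_voxels
}
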