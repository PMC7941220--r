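## Voxel-by-node correlation matrices on a checkerboard-subsampled node grid,
## and the subject-pairwise tissue-masked group average.

#' Checkerboard quarter-subsampling of a mask
#'
#' Selects every second voxel along x and y within each slice, with the
#' checkerboard phase alternating between slices (phase p = z mod 2 selects
#' voxels with x = p, y = p mod 2, in 0-based coordinates). Each slice
#' contributes about a quarter of its mask voxels, and a mask confined to a
#' single column is never lost entirely because adjacent slices use
#' complementary phases.
#'
#' @param voxels ordered linear indices of the mask.
#' @param grid_shape grid dimensions.
#' @return list of class `subsample_grid`: `nodes` (linear indices, subset of
#'   `voxels`), `node_cols` (positions of the nodes within `voxels`),
#'   `voxels`, `grid_shape`.
#' @export
checkerboard_nodes <- function(voxels, grid_shape) {
  stopifnot(length(voxels) > 0)
  co <- index_to_coord(voxels, grid_shape) - 1L   # 0-based
  p <- co[, 3] %% 2L
  sel <- (co[, 1] %% 2L == p) & (co[, 2] %% 2L == p)
  if (!any(sel)) stop("checkerboard selection is empty")
  structure(list(nodes = voxels[sel], node_cols = which(sel),
                 voxels = voxels, grid_shape = grid_shape),
            class = "subsample_grid")
}

#' Voxel-by-node correlation matrix for one subject
#'
#' Pearson correlation of every mask voxel's cleaned series with every node's
#' series. Rows (or entries) involving a zero-variance series are returned as
#' `NA`, not zero.
#'
#' @param series voxel x time matrix over the mask voxels (rows aligned with
#'   `grid$voxels`).
#' @param grid a [checkerboard_nodes()] result.
#' @return numeric matrix, length(voxels) x length(nodes).
#' @export
subject_corr <- function(series, grid) {
  stopifnot(nrow(series) == length(grid$voxels), ncol(series) >= 3)
  sds <- apply(series, 1, stats::sd)
  bad <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(
    stats::cor(t(series), t(series[grid$node_cols, , drop = FALSE])))
  r[bad, ] <- NA_real_
  r[, bad[grid$node_cols]] <- NA_real_
  r
}

#' Pairwise tissue-masked group average of correlation matrices
#'
#' Entry (i, j) is averaged only over subjects in whom both voxel i and node j
#' carry the target tissue label in that subject's own segmentation; the
#' number of contributing subjects is recorded per entry. Entries with zero
#' coverage are `NA`.
#'
#' @param matrices list of per-subject voxel x node correlation matrices
#'   (shared shape and ordering).
#' @param subject_tissue subject x voxel integer label matrix over the mask
#'   voxels (rows aligned with `matrices`).
#' @param grid the [checkerboard_nodes()] grid (for node positions).
#' @param target_label tissue code that must hold at both ends (1 = GM,
#'   2 = WM).
#' @param fisher_z average in Fisher-z space (atanh before averaging, tanh
#'   after) instead of averaging raw correlations.
#' @return list of class `group_corr`: `mean` (voxel x node), `coverage`
#'   (integer matrix), `grid`.
#' @export
group_average <- function(matrices, subject_tissue, grid,
                          target_label, fisher_z = FALSE) {
  stopifnot(length(matrices) >= 1,
            nrow(subject_tissue) == length(matrices))
  dims <- dim(matrices[[1]])
  acc <- matrix(0, dims[1], dims[2])
  cov <- matrix(0L, dims[1], dims[2])
  for (s in seq_along(matrices)) {
    m <- matrices[[s]]
    if (!identical(dim(m), dims)) stop("matrix shape mismatch at subject ", s)
    if (fisher_z) m <- atanh(pmin(pmax(m, -1 + 1e-15), 1 - 1e-15))
    v_ok <- subject_tissue[s, ] == target_label
    valid <- outer(v_ok, v_ok[grid$node_cols], `&`) & !is.na(m)
    m[!valid] <- 0
    acc <- acc + m
    cov <- cov + valid
  }
  mean_r <- acc / cov
  if (fisher_z) mean_r <- tanh(mean_r)
  mean_r[cov == 0L] <- NA_real_
  structure(list(mean = mean_r, coverage = cov, grid = grid,
                 target_label = target_label), class = "group_corr")
}

#' Rows of a group correlation matrix usable for clustering
#'
#' Keeps rows with at least `min_frac` non-missing entries and imputes the
#' remaining gaps with the row mean.
#'
#' @param gc a [group_average()] result (or plain matrix).
#' @param min_frac minimum fraction of non-missing entries per row.
#' @return list: `x` (imputed matrix), `rows` (kept row indices).
#' @export
clusterable_rows <- function(gc, min_frac = 0.9) {
  m <- if (inherits(gc, "group_corr")) gc$mean else gc
  frac <- rowMeans(!is.na(m))
  rows <- which(frac >= min_frac)
  x <- m[rows, , drop = FALSE]
  if (anyNA(x)) {
    rm <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- rm[idx[, 1]]
  }
  list(x = x, rows = rows)
}
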