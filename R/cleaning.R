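## BOLD cleaning: volume dropping, linear detrend, band-pass, 24-parameter
## motion + CSF + spike nuisance regression, and tissue-restricted smoothing.

#' Framewise displacement of a motion trace
#'
#' Power-style FD: sum of absolute backward differences of the six rigid-body
#' parameters, rotations converted to arc length at a `head_radius_mm` sphere.
#' The first volume has FD 0 by convention.
#'
#' @param motion numeric matrix, timepoints x 6 (3 translations in mm, 3
#'   rotations in radians).
#' @param head_radius_mm radius used to convert rotations to mm.
#' @return numeric vector of per-volume FD (mm).
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6, nrow(motion) >= 2)
  if (!all(is.finite(motion))) stop("motion trace contains non-finite values")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Subject-level motion exclusion rule
#'
#' A subject is dropped iff maximum absolute translation on any axis strictly
#' exceeds `trans_limit_mm`, or maximum absolute rotation strictly exceeds
#' `rot_limit_deg` (radians converted to degrees). A value exactly at the
#' limit is kept.
#'
#' @param motion timepoints x 6 matrix (mm, radians).
#' @param trans_limit_mm,rot_limit_deg exclusion limits.
#' @return list with `keep` (logical), `reason` (character, "" if kept),
#'   `max_translation_mm`, `max_rotation_deg`.
#' @export
motion_exclusion <- function(motion, trans_limit_mm = 2.0,
                             rot_limit_deg = 2.0) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6)
  mt <- max(abs(motion[, 1:3]))
  mr_rad <- max(abs(motion[, 4:6]))
  ## compare in radians so a rotation set exactly at the limit is kept
  keep <- !(mt > trans_limit_mm || mr_rad > rot_limit_deg * pi / 180)
  reason <- if (keep) "" else if (mt > trans_limit_mm)
    sprintf("translation %.2f mm > %.1f mm", mt, trans_limit_mm) else
      sprintf("rotation %.2f deg > %.1f deg", mr_rad * 180 / pi,
              rot_limit_deg)
  list(keep = keep, reason = reason,
       max_translation_mm = mt, max_rotation_deg = mr_rad * 180 / pi)
}

## Ideal frequency-domain band-pass on the rows of `x` (series in rows).
## Frequency bins with band[1] <= f <= band[2] are kept, everything else
## (including DC) is zeroed. Exactly idempotent.
bandpass_ideal <- function(x, tr_seconds, band) {
  n <- ncol(x)
  f <- seq(0, n - 1) / (n * tr_seconds)
  f <- pmin(f, 1 / tr_seconds - f)            # two-sided frequency axis
  keep <- f >= band[1] & f <= band[2]
  X <- t(stats::mvfft(t(x)))
  X[, !keep] <- 0
  Re(t(stats::mvfft(t(X), inverse = TRUE))) / n
}

## Real Fourier basis (cos/sin columns) spanning every out-of-band frequency
## of an n-sample series, DC excluded (the intercept covers it).
fourier_stop_basis <- function(n, tr_seconds, band) {
  tt <- seq_len(n)
  cols <- list()
  for (k in seq_len(n %/% 2)) {
    f <- k / (n * tr_seconds)
    if (f >= band[1] && f <= band[2]) next
    cols[[length(cols) + 1L]] <- cos(2 * pi * k * tt / n)
    if (k < (n + 1) %/% 2)
      cols[[length(cols) + 1L]] <- sin(2 * pi * k * tt / n)
  }
  if (!length(cols)) return(matrix(0, n, 0))
  do.call(cbind, cols)
}

## Remove per-row intercept and linear trend.
detrend_linear <- function(x) {
  n <- ncol(x)
  B <- cbind(1, seq_len(n) - (n + 1) / 2)
  Q <- qr.Q(qr(B))
  x - (x %*% Q) %*% t(Q)
}

## Friston 24-parameter expansion: p, p(t-1), p^2, p(t-1)^2 (lag zero-padded).
motion_expand24 <- function(motion) {
  p <- as.matrix(motion)
  lag <- rbind(0, p[-nrow(p), , drop = FALSE])
  cbind(p, lag, p^2, lag^2)
}

#' Clean mask-restricted BOLD time series
#'
#' Applies, in order: dropping of the first `drop_first` volumes, per-voxel
#' linear detrending, ideal band-pass filtering (`band`, TR-aware), and
#' regression of nuisance signals — the 24-parameter motion set (6 rigid-body
#' parameters, their one-lag copies, and both squared), the mean CSF signal,
#' and one indicator column per volume whose framewise displacement exceeds
#' `fd_spike_mm` (spike volumes are regressed, not deleted). The motion and
#' CSF regressors are passed through the same detrend + band-pass transform
#' as the data before regression, so the residuals stay band-limited and
#' orthogonal to every nuisance column; with no spike volumes the whole
#' operation is idempotent (rerun with `drop_first = 0`). An intercept and a
#' linear-trend column are always included, so residuals have zero mean and
#' zero linear trend. White-matter and whole-brain mean signals are
#' deliberately not regressed. Collinear nuisance columns are dropped with a
#' warning.
#'
#' @param bold 4D array (x, y, z, time) or voxel x time matrix covering the
#'   full grid.
#' @param voxels 1-based linear indices of the voxels to clean (one tissue's
#'   mask).
#' @param motion timepoints x 6 motion trace aligned with the *acquired*
#'   volumes.
#' @param tr_seconds repetition time.
#' @param csf_voxels linear indices used for the mean-CSF regressor; NULL
#'   omits the regressor.
#' @param drop_first number of initial volumes to discard.
#' @param band band-pass edges in Hz.
#' @param fd_spike_mm FD threshold defining spike volumes.
#' @param head_radius_mm passed to [framewise_displacement()].
#' @param combined use the combined-regression alternative: instead of the
#'   sequential detrend -> filter -> regress order, residualize the dropped
#'   series on a single joint model containing the intercept, linear trend,
#'   a Fourier basis spanning all out-of-band frequencies, the raw nuisance
#'   signals and the spike indicators. Avoids any frequency interaction
#'   between the steps.
#' @return list of class `clean_series`: `series` (voxel x time residuals),
#'   `voxels`, `retained` (indices of retained volumes in the acquired run),
#'   `spike_volumes` (relative to retained run), `regressors`.
#' @export
clean_series <- function(bold, voxels, motion, tr_seconds,
                         csf_voxels = NULL, drop_first = 10,
                         band = c(0.01, 0.1), fd_spike_mm = 1.0,
                         head_radius_mm = 50, combined = FALSE) {
  if (is.array(bold) && length(dim(bold)) == 4) {
    n_t <- dim(bold)[4]
    bold <- matrix(bold, ncol = n_t)
  }
  n_t <- ncol(bold)
  motion <- as.matrix(motion)
  if (nrow(motion) != n_t)
    stop("motion trace rows (", nrow(motion), ") != volumes (", n_t, ")")
  stopifnot(drop_first >= 0, n_t - drop_first >= 20)
  retained <- (drop_first + 1L):n_t
  n <- length(retained)

  mot <- motion[retained, , drop = FALSE]
  fd <- framewise_displacement(motion, head_radius_mm)[retained]
  spikes <- which(fd > fd_spike_mm)
  if (length(spikes) == length(retained))
    stop("all retained volumes exceed the FD spike threshold")
  N <- motion_expand24(mot)
  if (!is.null(csf_voxels) && length(csf_voxels))
    N <- cbind(N, csf = colMeans(bold[csf_voxels, retained, drop = FALSE]))
  S <- NULL
  if (length(spikes)) {
    S <- matrix(0, n, length(spikes))
    S[cbind(spikes, seq_along(spikes))] <- 1
    colnames(S) <- paste0("spike_", spikes)
  }

  if (combined) {
    ## one joint projection: trend + out-of-band Fourier span + raw nuisance
    x <- bold[voxels, retained, drop = FALSE]
    R <- cbind(intercept = 1, trend = seq_len(n) - (n + 1) / 2,
               fourier_stop_basis(n, tr_seconds, band), N)
    if (!is.null(S)) R <- cbind(R, S)
  } else {
    ## the stated step order: detrend, band-pass, then nuisance regression.
    ## Signal-like nuisance columns get the same detrend + band-pass as the
    ## data, and the band-passed raw trend guards against the trend component
    ## the filter reintroduces; residuals are then exactly band-limited,
    ## mean-free and trend-free, and the operator is a projection.
    x <- bandpass_ideal(detrend_linear(bold[voxels, retained, drop = FALSE]),
                        tr_seconds, band)
    filt_cols <- function(M)
      t(bandpass_ideal(detrend_linear(t(M)), tr_seconds, band))
    trend_f <- as.numeric(bandpass_ideal(matrix(seq_len(n), 1), tr_seconds,
                                         band))
    R <- cbind(trend_f = trend_f, filt_cols(N))
    if (!is.null(S)) R <- cbind(R, S)
  }
  ## drop numerically-zero columns, then scale to unit norm so rank detection
  ## is not driven by the regressors' disparate units
  nrm <- sqrt(colSums(R^2))
  R <- R[, nrm > 1e-10 * max(nrm), drop = FALSE]
  R <- sweep(R, 2, sqrt(colSums(R^2)), "/")
  qrR <- qr(R)
  if (qrR$rank < ncol(R)) {
    dropped <- qrR$pivot[(qrR$rank + 1L):ncol(R)]
    warning("dropping ", length(dropped), " collinear nuisance column(s): ",
            paste(colnames(R)[dropped], collapse = ", "))
    R <- R[, -dropped, drop = FALSE]
    qrR <- qr(R)
  }
  res <- t(qr.resid(qrR, t(x)))
  structure(list(series = res, voxels = voxels, retained = retained,
                 spike_volumes = spikes, regressors = R),
            class = "clean_series")
}

#' Build a mask-restricted Gaussian smoothing operator
#'
#' Returns a sparse row-stochastic matrix over the mask voxels; applying it to
#' a voxel x time matrix smooths each volume with a Gaussian kernel of the
#' given FWHM, renormalized over in-mask voxels only, so no signal crosses the
#' mask boundary and constants are preserved.
#'
#' @param voxels linear indices of the mask.
#' @param grid_shape grid dimensions.
#' @param fwhm_mm kernel full width at half maximum in mm.
#' @param voxel_size_mm isotropic voxel size.
#' @return a `Matrix::sparseMatrix` of dimension length(voxels)^2.
#' @export
smoothing_operator <- function(voxels, grid_shape, fwhm_mm = 4,
                               voxel_size_mm = 3) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(3 * sigma_vox))
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= (3 * sigma_vox)^2 + 1e-9, ]
  w_off <- exp(-(off$dx^2 + off$dy^2 + off$dz^2) / (2 * sigma_vox^2))

  pos <- integer(prod(grid_shape))      # grid index -> row in `voxels`
  pos[voxels] <- seq_along(voxels)
  co <- index_to_coord(voxels, grid_shape)
  ii <- jj <- integer(0); ww <- numeric(0)
  for (k in seq_len(nrow(off))) {
    nb <- cbind(co[, 1] + off$dx[k], co[, 2] + off$dy[k], co[, 3] + off$dz[k])
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid_shape[1] &
      nb[, 2] >= 1 & nb[, 2] <= grid_shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= grid_shape[3]
    j <- rep(0L, length(voxels))
    j[ok] <- pos[coord_to_index(nb[ok, , drop = FALSE], grid_shape)]
    sel <- which(j > 0L)
    ii <- c(ii, sel); jj <- c(jj, j[sel]); ww <- c(ww, rep(w_off[k], length(sel)))
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww,
                            dims = c(length(voxels), length(voxels)))
  Matrix::Diagonal(x = 1 / Matrix::rowSums(W)) %*% W
}

#' Smooth series within a tissue mask
#'
#' @param series voxel x time matrix (rows aligned with `voxels`).
#' @inheritParams smoothing_operator
#' @return smoothed voxel x time matrix.
#' @export
smooth_within_mask <- function(series, voxels, grid_shape, fwhm_mm = 4,
                               voxel_size_mm = 3) {
  W <- smoothing_operator(voxels, grid_shape, fwhm_mm, voxel_size_mm)
  as.matrix(W %*% series)
}

#' Trilinear resampling of a 3D volume
#'
#' Minimal resampler for bringing real data onto a target grid; phantom data
#' are generated at target resolution so this is a no-op in the synthetic
#' pipeline.
#'
#' @param vol 3D array.
#' @param out_shape integer 3-vector.
#' @return resampled array of dimension `out_shape`.
#' @export
resample_trilinear <- function(vol, out_shape) {
  ins <- dim(vol)
  g <- lapply(1:3, function(a) {
    if (out_shape[a] == 1) rep((ins[a] + 1) / 2, 1)
    else (seq_len(out_shape[a]) - 0.5) * ins[a] / out_shape[a] + 0.5
  })
  out <- array(0, out_shape)
  co <- as.matrix(expand.grid(x = g[[1]], y = g[[2]], z = g[[3]]))
  lo <- pmin(pmax(floor(co), 1), matrix(ins, nrow(co), 3, byrow = TRUE))
  hi <- pmin(lo + 1, matrix(ins, nrow(co), 3, byrow = TRUE))
  fr <- pmin(pmax(co - lo, 0), 1)
  acc <- numeric(nrow(co))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    idx <- cbind(if (dx) hi[, 1] else lo[, 1],
                 if (dy) hi[, 2] else lo[, 2],
                 if (dz) hi[, 3] else lo[, 3])
    acc <- acc + w * vol[idx]
  }
  array(acc, out_shape)
}
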