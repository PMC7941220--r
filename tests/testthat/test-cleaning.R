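test_that("framewise displacement matches its definition and the brute-force oracle", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 10))

  m[6:10, 1] <- 1                       # single 1 mm x-step between t=5 and 6
  fd <- framewise_displacement(m)
  expect_equal(fd[6], 1.0)
  expect_equal(fd[7], 0)
  expect_equal(fd[1], 0)

  mr <- withr::with_seed(3, matrix(rnorm(60, sd = 0.3), 10, 6))
  expect_equal(framewise_displacement(mr), oracle_fd(mr), tolerance = 1e-12)
  expect_equal(framewise_displacement(mr, head_radius_mm = 35),
               oracle_fd(mr, 35), tolerance = 1e-12)
  expect_error(framewise_displacement(matrix(c(NA, rep(0, 11)), 2, 6)),
               "non-finite")
})

test_that("motion exclusion uses strict limits in mm and degrees", {
  m <- matrix(0, 5, 6)
  expect_true(motion_exclusion(m)$keep)
  m[3, 2] <- 2.5
  ex <- motion_exclusion(m)
  expect_false(ex$keep)
  expect_match(ex$reason, "translation")
  m[3, 2] <- 2.0                        # exactly at the limit: kept
  expect_true(motion_exclusion(m)$keep)
  m[3, 2] <- 0
  m[2, 5] <- 2.0 * pi / 180             # exactly 2 degrees: kept
  expect_true(motion_exclusion(m)$keep)
  m[2, 5] <- 2.1 * pi / 180
  expect_false(motion_exclusion(m)$keep)
})

test_that("cleaning removes constants, out-of-band signal and motion copies", {
  Tn <- 210; tr <- 2
  mot <- withr::with_seed(8, inject_motion(Tn))
  tt <- seq_len(Tn)
  ## 0.005 Hz sits on an exact frequency bin of the 200 retained volumes
  sine <- sin(2 * pi * 0.005 * (tt - 1) * tr)
  bold <- rbind(const = rep(7, Tn),
                slow = sine,
                motcopy = mot[, 1],
                noise = withr::with_seed(9, rnorm(Tn)))
  cs <- clean_series(bold, 1:4, mot, tr, drop_first = 10)
  expect_equal(ncol(cs$series), 200)
  expect_lt(max(abs(cs$series[1, ])), 1e-10)
  p_in <- sum(sine[11:Tn]^2)
  expect_lt(sum(cs$series[2, ]^2) / p_in, 0.01)
  expect_lt(max(abs(cs$series[3, ])), 1e-10)
  expect_gt(stats::sd(cs$series[4, ]), 0)
})

test_that("cleaning is an exact projection: orthogonal residuals, idempotent", {
  Tn <- 120; tr <- 2
  mot <- withr::with_seed(2, inject_motion(Tn))
  bold <- withr::with_seed(4, matrix(rnorm(40 * Tn), 40))
  cs1 <- clean_series(bold, 1:30, mot, tr, csf_voxels = 31:40,
                      drop_first = 10)
  expect_lt(max(abs(cs1$series %*% cs1$regressors)), 1e-10)
  expect_lt(max(abs(rowMeans(cs1$series))), 1e-12)
  cs2 <- clean_series(cs1$series, 1:30, mot[cs1$retained, ], tr,
                      drop_first = 0)
  expect_equal(cs2$series, cs1$series, tolerance = 1e-10)
})

test_that("FD spikes become indicator regressors that null the spiked volumes", {
  Tn <- 80; tr <- 2
  mot <- withr::with_seed(6, inject_motion(Tn, spikes = data.frame(
    time = 40, amplitude_mm = 2)))
  bold <- withr::with_seed(7, matrix(rnorm(5 * Tn), 5))
  cs <- clean_series(bold, 1:5, mot, tr, drop_first = 10)
  expect_true(length(cs$spike_volumes) >= 1)
  expect_true(30 %in% cs$spike_volumes)   # volume 40 is retained volume 30
  expect_lt(max(abs(cs$series[, cs$spike_volumes])), 1e-10)
})

test_that("collinear nuisance columns are dropped with a warning", {
  Tn <- 60; tr <- 2
  mot <- withr::with_seed(1, inject_motion(Tn))
  mot[, 2] <- mot[, 1]                   # duplicate parameter
  bold <- withr::with_seed(2, matrix(rnorm(4 * Tn), 4))
  expect_warning(clean_series(bold, 1:4, mot, tr, drop_first = 5),
                 "collinear")
})

test_that("mask-restricted smoothing preserves constants and tissue separation", {
  gs <- c(6, 6, 3)
  vox <- coord_to_index(as.matrix(expand.grid(x = 1:6, y = 1:3, z = 1:3)), gs)
  series <- matrix(5, length(vox), 4)
  expect_equal(smooth_within_mask(series, vox, gs, fwhm_mm = 4,
                                  voxel_size_mm = 3),
               series, ignore_attr = TRUE, tolerance = 1e-12)
  ## a GM voxel adjacent to WM: smoothing the WM mask never sees GM values
  wm_vox <- coord_to_index(as.matrix(expand.grid(x = 1:6, y = 4:6, z = 1:3)),
                           gs)
  wm_series <- withr::with_seed(3, matrix(rnorm(length(wm_vox) * 4),
                                          length(wm_vox)))
  sm1 <- smooth_within_mask(wm_series, wm_vox, gs, 4, 3)
  ## identical WM input with arbitrary GM values elsewhere cannot change it
  expect_equal(sm1, smooth_within_mask(wm_series, wm_vox, gs, 4, 3),
               tolerance = 1e-15)
  expect_error(smooth_within_mask(wm_series, wm_vox, gs, fwhm_mm = 0, 3),
               "fwhm")
})

test_that("an impulse smooths to explicitly renormalized Gaussian weights", {
  gs <- c(5, 5, 5)
  ## an irregular mask around the center
  vox <- coord_to_index(as.matrix(expand.grid(x = 2:5, y = 1:4, z = 2:4)), gs)
  center <- coord_to_index(cbind(3, 3, 3), gs)
  series <- matrix(0, length(vox), 1)
  series[vox == center, 1] <- 1
  fwhm <- 4; vs <- 3
  out <- smooth_within_mask(series, vox, gs, fwhm, vs)
  ## oracle: per-voxel direct renormalized convolution
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vs
  co <- index_to_coord(vox, gs)
  w_at <- function(i) {
    ## weight of the center voxel within voxel i's renormalized kernel
    di <- sweep(co, 2, co[i, ])
    d2 <- rowSums(di^2)
    w <- exp(-d2 / (2 * sigma^2))
    w[d2 > (3 * sigma)^2 + 1e-9] <- 0
    w[vox == center] / sum(w)
  }
  expected <- vapply(seq_along(vox), w_at, 0)
  expect_equal(as.numeric(out), expected, tolerance = 1e-10)
})

test_that("combined-regression cleaning removes the same structure in one projection", {
  Tn <- 210; tr <- 2
  mot <- withr::with_seed(8, inject_motion(Tn))
  tt <- seq_len(Tn)
  sine <- sin(2 * pi * 0.005 * (tt - 1) * tr)
  bold <- rbind(rep(7, Tn), sine, mot[, 1],
                withr::with_seed(9, rnorm(Tn)))
  cs <- clean_series(bold, 1:4, mot, tr, drop_first = 10, combined = TRUE)
  expect_lt(max(abs(cs$series[1, ])), 1e-8)
  expect_lt(sum(cs$series[2, ]^2) / sum(sine[11:Tn]^2), 0.01)
  expect_lt(max(abs(cs$series[3, ])), 1e-8)
  expect_gt(stats::sd(cs$series[4, ]), 0)
  ## combined cleaning is a projection too
  cs2 <- clean_series(cs$series, 1:4, mot[cs$retained, ], tr, drop_first = 0,
                      combined = TRUE)
  expect_equal(cs2$series, cs$series, tolerance = 1e-8)
})
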