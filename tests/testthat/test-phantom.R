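small_spec <- function(...) {
  phantom_spec(grid_shape = c(16, 16, 10), n_gm_networks = 2,
               n_wm_networks = 2,
               group_effect = list(list(a = "GM2", b = "WM1", delta_r = 0.3)),
               behavior_spec = list(edge = c("GM1", "WM1")),
               n_subjects_per_group = c(2, 2), ...)
}

test_that("spec validation rejects non-PSD couplings and too-small parcels", {
  C <- matrix(0.9, 4, 4); diag(C) <- 1
  C[1, 2] <- C[2, 1] <- -0.9                  # violates PSD
  expect_error(phantom_spec(n_gm_networks = 2, n_wm_networks = 2,
                            coupling = C, group_effect = list(),
                            behavior_spec = list(edge = c("GM1", "WM1"))),
               "positive semidefinite")
  expect_error(phantom_spec(grid_shape = c(8, 8, 8), n_gm_networks = 6,
                            n_wm_networks = 6, group_effect = list(),
                            behavior_spec = list(edge = c("GM1", "WM1"))),
               "at least 8 voxels")
  ## a group effect that breaks PSD is rejected even when the base is fine
  expect_error(phantom_spec(group_effect = list(list(a = "GM1", b = "WM1",
                                                     delta_r = 0.6))),
               "group-effect")
  ## asymmetric coupling is rejected
  C2 <- diag(4); C2[1, 2] <- 0.3
  expect_error(phantom_spec(n_gm_networks = 2, n_wm_networks = 2,
                            coupling = C2, group_effect = list(),
                            behavior_spec = list(edge = c("GM1", "WM1"))),
               "symmetric")
})

test_that("zero-noise artifact-free voxels equal their network latent exactly", {
  spec <- small_spec(noise_sd = 0, artifacts = FALSE, seed = 7)
  d <- withr::local_tempdir()
  tr <- generate_cohort(spec, d)
  id <- tr$subjects$subject[1]
  bold <- RNifti::readNifti(file.path(d, paste0(id, "_bold.nii")))
  bm <- matrix(bold, ncol = spec$n_timepoints)
  brain <- which(tr$net_of_voxel > 0)
  expect_equal(bm[brain, ],
               tr$latents[[id]][tr$net_of_voxel[brain], ],
               ignore_attr = TRUE, tolerance = 1e-6)
  ## all within-network voxel pairs perfectly correlated
  gm1 <- which(tr$gm_labels == 1)
  cc <- stats::cor(t(bm[gm1[1:5], ]))
  expect_true(all(cc > 1 - 1e-9))
})

test_that("latent correlations match the requested coupling within sampling error", {
  C <- matrix(c(1, 0.6, 0.6, 1), 2)
  r <- withr::with_seed(11, {
    L <- generate_latents(C, 600)
    stats::cor(L[1, ], L[2, ])
  })
  ## 600 timepoints: Fisher-z sampling SD ~ 1/sqrt(597), so |r - 0.6| < 0.05
  ## is a ~2.9-sigma bound
  expect_lt(abs(r - 0.6), 0.05)
  C3 <- matrix(0.3, 3, 3); diag(C3) <- 1
  r3 <- withr::with_seed(2, stats::cor(t(generate_latents(C3, 2e4))))
  expect_lt(max(abs(r3 - C3)), 0.03)
})

test_that("motion traces obey baseline and spike contracts", {
  withr::with_seed(5, {
    m0 <- inject_motion(200)
    expect_lt(max(framewise_displacement(m0)), 0.5)
    expect_true(motion_exclusion(m0)$keep)

    m1 <- inject_motion(200, spikes = data.frame(time = 50, amplitude_mm = 2))
    expect_gt(framewise_displacement(m1)[50], 1)

    mh <- inject_motion(200, high_motion = TRUE)
    expect_gt(max(abs(mh[, 1:3])), 2.0)
    expect_false(motion_exclusion(mh)$keep)
  })
})

test_that("regenerating a cohort from the same seed is byte-identical", {
  spec <- small_spec(seed = 123)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(spec, d1)
  generate_cohort(spec, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  md5 <- function(d, f) as.character(tools::md5sum(file.path(d, f)))
  expect_identical(vapply(f1, function(f) md5(d1, f), ""),
                   vapply(f1, function(f) md5(d2, f), ""))
})

test_that("planted labels partition each tissue and behavior table is well-formed", {
  spec <- small_spec(seed = 9)
  d <- withr::local_tempdir()
  tr <- generate_cohort(spec, d)
  gm <- which(tr$tissue == 1L); wm <- which(tr$tissue == 2L)
  expect_true(all(tr$gm_labels[gm] >= 1))
  expect_true(all(tr$wm_labels[wm] >= 1))
  expect_true(all(tr$gm_labels[wm] == 0))
  expect_true(all(tr$wm_labels[gm] == 0))
  b <- tr$behavior
  expect_setequal(names(b), c("subject", "group", "age", "sex",
                              "vas_pre", "vas_24h", "sai_pre", "sai_24h"))
  expect_true(all(is.na(b$vas_24h[b$group == "control"])))
  expect_true(all(!is.na(b$vas_24h[b$group == "pain"])))
  expect_true(all(b$age >= 19 & b$age <= 30))
})

test_that("the planted behavioral partial correlation is exact on latent z", {
  spec <- phantom_spec(grid_shape = c(16, 16, 10), n_gm_networks = 2,
                       n_wm_networks = 2, group_effect = list(),
                       behavior_spec = list(edge = c("GM1", "WM1"),
                                            partial_r = -0.31),
                       n_subjects_per_group = c(12, 2),
                       n_timepoints = 60, seed = 31)
  d <- withr::local_tempdir()
  tr <- generate_cohort(spec, d)
  b <- tr$behavior
  pain <- b$group == "pain"
  z <- vapply(tr$latents[b$subject[pain]], function(L)
    atanh(stats::cor(L["GM1", ], L["WM1", ])), 0)
  pc <- behavior_partial_corr(z, b$vas_24h[pain] - b$vas_pre[pain],
                              b$age[pain], b$sex[pain])
  expect_equal(pc$r, -0.31, tolerance = 1e-8)
})
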