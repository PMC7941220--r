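test_that("network time courses are member means", {
  x <- withr::with_seed(3, matrix(rnorm(7 * 12), 7))
  labels <- c(1, 2, 2, 3, 3, 3, 3)
  nt <- network_timeseries(x, labels, prefix = "GM")
  expect_equal(unname(nt["GM1", ]), x[1, ])          # single-voxel network
  expect_equal(unname(nt["GM2", ]), colMeans(x[2:3, ]))
  ## oracle: per-timepoint arithmetic mean
  for (t in 1:12) expect_equal(unname(nt["GM3", t]), mean(x[4:7, t]))
  x2 <- rbind(x[1, ], x[1, ])
  expect_equal(unname(network_timeseries(x2, c(1, 1), "N")[1, ]), x[1, ])
  expect_error(network_timeseries(x, c(1, 1, 1, 3, 3, 3, 3), "N"),
               "empty network")
})

test_that("Fisher z transform and its degenerate cases", {
  net <- withr::with_seed(5, matrix(rnorm(3 * 40), 3))
  rownames(net) <- c("GM1", "GM2", "WM1")
  fc <- fc_matrices(net)
  r <- stats::cor(net[1, ], net[2, ])
  expect_equal(fc$gm_gm["GM1", "GM2"], atanh(r))
  expect_equal(atanh(0.5), 0.5493061, tolerance = 1e-6)
  expect_equal(atanh(-0.3), -atanh(0.3))             # odd function
  expect_true(is.na(fc$gm_gm["GM1", "GM1"]))
  net2 <- rbind(net, net[1, ] * 2)
  rownames(net2) <- c(rownames(net), "WM2")
  expect_error(fc_matrices(net2), "Fisher z is infinite")
})

test_that("skewness/kurtosis screen matches moment formulas and conventions", {
  ## symmetric two-point sample has skewness 0
  z2 <- cbind(e1 = rep(c(-2, 2), 5), e2 = withr::with_seed(6, rnorm(10)))
  scr <- normality_screen(z2, rep("g", 10))
  expect_equal(scr$skewness[1], 0, tolerance = 1e-12)
  ## published scale/anxiety score moments lie inside the (-2, 2) band
  tab <- data.frame(skew = c(-0.92, -0.88, 0.02, 0.17),
                    kurt = c(0.43, -0.28, -0.61, -0.53))
  expect_true(all(abs(tab$skew) < 2 & abs(tab$kurt) < 2))
  ## random sample matches the type-2 moment formulas
  x <- withr::with_seed(7, rnorm(25)^2)
  scr2 <- normality_screen(cbind(e = x), rep("g", 25))
  expect_equal(scr2$skewness, oracle_skew2(x), tolerance = 1e-12)
  expect_equal(scr2$kurtosis, oracle_kurt2(x), tolerance = 1e-12)
  expect_error(normality_screen(cbind(e = rep(1, 10)), rep("g", 10)),
               "zero-variance")
})

test_that("one-sample edge screen matches the analytic t and is Bonferroni-corrected", {
  z <- withr::with_seed(8, matrix(rnorm(10 * 4, mean = c(0, 0, 0.8, 0)),
                                  10, 4, byrow = TRUE))
  colnames(z) <- paste0("GM1-GM", 2:5)
  z <- rbind(z, z)                      # two groups of 10
  grp <- rep(c("a", "b"), each = 10)
  os <- one_sample_edges(z, grp, alpha = 0.05)
  for (i in 1:4) {
    v <- z[grp == "a", i]
    t_exp <- mean(v) / (stats::sd(v) / sqrt(10))
    p_exp <- 2 * stats::pt(-abs(t_exp), 9)
    row <- os$per_group[os$per_group$group == "a", ][i, ]
    expect_equal(row$t, t_exp, tolerance = 1e-12)
    expect_equal(row$p, p_exp, tolerance = 1e-12)
    expect_equal(row$significant, p_exp < 0.05 / 4)
  }
  ## all-zero edge never significant; zero variance errors
  z0 <- cbind(e = rep(0, 6)); expect_error(one_sample_edges(z0, rep("a", 6)),
                                           "zero-variance")
  z1 <- cbind(a = c(rnorm(6)), b = rep(1, 6))
  expect_error(one_sample_edges(z1, rep("a", 6)), "zero-variance")
})

test_that("two-sample edge tests use pooled variance and per-family Bonferroni", {
  withr::with_seed(9, {
    za <- matrix(rnorm(12 * 3), 12); zb <- matrix(rnorm(12 * 3), 12)
    colnames(za) <- colnames(zb) <- c("GM1-WM1", "GM1-WM2", "GM2-WM1")
    zb[, 2] <- zb[, 2] + 1.5
    z <- rbind(za, zb)
    grp <- rep(c("pain", "control"), each = 12)
    ts <- two_sample_edges(z, grp, alpha = 0.05)
    expect_equal(attr(ts, "m"), 3)
    for (i in 1:3) {
      ht <- stats::t.test(za[, i], zb[, i], var.equal = TRUE)
      expect_equal(ts$t[i], unname(ht$statistic), tolerance = 1e-12)
      expect_equal(ts$p[i], ht$p.value, tolerance = 1e-12)
      expect_equal(ts$significant[i], ht$p.value < 0.05 / 3)
    }
    expect_equal(ts$direction[2], -1)
    ## identical groups: t = 0, not significant
    t0 <- two_sample_edges(rbind(za, za), grp)
    expect_true(all(abs(t0$t) < 1e-12) && !any(t0$significant))
    ## Bonferroni family size: m tested edges -> threshold alpha/m
    ts2 <- two_sample_edges(z, grp, tested_edges = c("GM1-WM1", "GM1-WM2"))
    expect_equal(attr(ts2, "m"), 2)
  })
})

test_that("partial correlation matches the precision-matrix oracle and limits", {
  withr::with_seed(10, {
    n <- 44
    age <- runif(n, 19, 30); sex <- rep(0:1, n / 2)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    pc <- behavior_partial_corr(x, y, age, sex)
    expect_equal(pc$r, oracle_partial_r(x, y, cbind(age, sex)),
                 tolerance = 1e-10)
    expect_equal(pc$df, n - 4)
    ## orthogonal covariates: partial r equals plain r (constructed exactly)
    X <- cbind(1, age, sex)
    xo <- stats::lm.fit(X, rnorm(n))$residuals
    yo <- stats::lm.fit(X, 0.3 * xo + rnorm(n))$residuals
    pc2 <- behavior_partial_corr(xo, yo, age, sex)
    expect_equal(pc2$r, stats::cor(xo, yo), tolerance = 1e-10)
    ## behavior (almost) fully explained by age: partial r near 0
    n2 <- 2000
    age2 <- runif(n2, 19, 30); sex2 <- rep(0:1, n2 / 2)
    pc3 <- behavior_partial_corr(rnorm(n2), 2 * age2 + rnorm(n2, sd = 0.01),
                                 age2, sex2)
    expect_lt(abs(pc3$r), 0.08)
    expect_error(behavior_partial_corr(rnorm(n), rep(1, n), age, sex),
                 "constant")
  })
})

test_that("loop detection finds gray-white cycles and rejects same-tissue ones", {
  ## the canonical 3-loop: GM5-WM12, WM12-WM4, WM4-GM5 all significant
  st <- data.frame(edge = c("GM5-WM12", "WM12-WM4", "WM4-GM5"),
                   significant = TRUE, direction = c(1, 1, 1))
  ls <- find_loops(st)
  expect_length(ls, 1)
  expect_setequal(ls[[1]]$nodes, c("GM5", "WM12", "WM4"))
  expect_true(all(ls[[1]]$edges$direction == 1))

  ## a GM-only triangle is not a gray-white loop
  st2 <- data.frame(edge = c("GM1-GM2", "GM2-GM3", "GM3-GM1"),
                    significant = TRUE, direction = 1)
  expect_length(find_loops(st2), 0)

  ## non-significant edges cannot close a loop
  st3 <- st; st3$significant[2] <- FALSE
  expect_length(find_loops(st3), 0)
})

test_that("loop enumeration equals exhaustive brute force on random graphs", {
  nodes <- c(paste0("GM", 1:4), paste0("WM", 1:4))
  for (seed in 1:6) {
    edges <- withr::with_seed(seed, {
      all_pairs <- t(utils::combn(nodes, 2))
      sel <- runif(nrow(all_pairs)) < 0.35
      data.frame(edge = paste0(all_pairs[sel, 1], "-", all_pairs[sel, 2]),
                 significant = TRUE,
                 direction = sample(c(-1, 1), sum(sel), replace = TRUE))
    })
    ab <- do.call(rbind, strsplit(edges$edge, "-"))
    got <- loopset_keys(find_loops(edges, max_len = 4))
    want <- oracle_cycles(data.frame(a = ab[, 1], b = ab[, 2]), max_len = 4)
    expect_equal(got, want)
  }
})
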