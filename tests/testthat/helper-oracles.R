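## Independent brute-force oracles used to validate the package's
## implementations on small randomized inputs.

oracle_fd <- function(motion, head_radius_mm = 50) {
  n <- nrow(motion)
  fd <- numeric(n)
  for (t in 2:n) {
    s <- 0
    for (j in 1:3) s <- s + abs(motion[t, j] - motion[t - 1, j])
    for (j in 4:6) s <- s + head_radius_mm * abs(motion[t, j] - motion[t - 1, j])
    fd[t] <- s
  }
  fd
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

## Type-2 (SPSS) skewness and excess kurtosis from raw moments.
oracle_skew2 <- function(x) {
  n <- length(x); m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

oracle_kurt2 <- function(x) {
  n <- length(x); m <- mean(x)
  m2 <- mean((x - m)^2); m4 <- mean((x - m)^4)
  g2 <- m4 / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

## Partial correlation of x and y given covariate matrix via inversion of the
## joint correlation matrix (a different route than residual regression).
oracle_partial_r <- function(x, y, covs) {
  P <- solve(stats::cor(cbind(x, y, covs)))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

## Pairwise-masked mean: entry-by-entry loop over subjects.
oracle_masked_mean <- function(mats, tissue, node_cols, target) {
  nv <- nrow(mats[[1]]); nn <- ncol(mats[[1]])
  mean_r <- matrix(NA_real_, nv, nn)
  cov_n <- matrix(0L, nv, nn)
  for (i in seq_len(nv)) for (j in seq_len(nn)) {
    vals <- c()
    for (s in seq_along(mats)) {
      if (tissue[s, i] == target && tissue[s, node_cols[j]] == target &&
          !is.na(mats[[s]][i, j]))
        vals <- c(vals, mats[[s]][i, j])
    }
    if (length(vals)) {
      mean_r[i, j] <- mean(vals)
      cov_n[i, j] <- length(vals)
    }
  }
  list(mean = mean_r, coverage = cov_n)
}

## O(n^2) Dice between co-assignment adjacencies.
oracle_dice <- function(la, lb) {
  n <- length(la)
  inter <- a <- b <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ca <- la[i] == la[j]; cb <- lb[i] == lb[j]
    a <- a + ca; b <- b + cb; inter <- inter + (ca && cb)
  }
  2 * inter / (a + b)
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

## Exhaustive simple-cycle enumeration with the gray/white tissue constraint.
## Returns canonical keys "n1|n2|...|nk" (smallest node first, smaller
## neighbor second).
oracle_cycles <- function(edges, max_len) {
  has_edge <- function(a, b)
    any((edges$a == a & edges$b == b) | (edges$a == b & edges$b == a))
  nodes <- sort(unique(c(edges$a, edges$b)))
  keys <- character(0)
  for (len in 3:max_len) {
    if (length(nodes) < len) next
    subsets <- utils::combn(nodes, len, simplify = FALSE)
    for (s in subsets) {
      first <- min(s)
      for (p in all_perms(setdiff(s, first))) {
        cyc <- c(first, p)
        if (cyc[2] > cyc[len]) next           # one direction only
        ok <- has_edge(cyc[len], cyc[1])
        if (ok) for (i in 1:(len - 1)) {
          if (!has_edge(cyc[i], cyc[i + 1])) { ok <- FALSE; break }
        }
        if (ok && any(grepl("^GM", cyc)) && any(grepl("^WM", cyc)))
          keys <- c(keys, paste(cyc, collapse = "|"))
      }
    }
  }
  sort(unique(keys))
}

loopset_keys <- function(loops)
  sort(vapply(loops, function(l) paste(l$nodes, collapse = "|"), ""))

## Rows drawn around `k` planted profile vectors plus noise.
planted_rows <- function(n_per, profiles, noise_sd = 0.05) {
  x <- do.call(rbind, lapply(seq_len(nrow(profiles)), function(k)
    matrix(rep(profiles[k, ], each = n_per), n_per) +
      matrix(stats::rnorm(n_per * ncol(profiles), sd = noise_sd), n_per)))
  list(x = x, labels = rep(seq_len(nrow(profiles)), each = n_per))
}

## Small segmentation stacks for mask tests.
random_segs <- function(n_subj, gs, seed) {
  withr::with_seed(seed, lapply(seq_len(n_subj), function(s)
    array(sample(0:2, prod(gs), replace = TRUE), gs)))
}
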