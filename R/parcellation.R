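## Correlation-distance K-means over connectivity-profile rows, and fold-based
## Dice stability selection of the number of networks.

## Center and unit-normalize rows so that 1 - u_i . u_j equals the correlation
## distance between the original rows.
standardize_rows <- function(x) {
  u <- x - rowMeans(x)
  nrm <- sqrt(rowSums(u^2))
  bad <- which(nrm == 0 | !is.finite(nrm))
  if (length(bad))
    stop("constant row(s) have undefined correlation distance: row ",
         paste(utils::head(bad, 5), collapse = ", "))
  u / nrm
}

kmeans_corr_once <- function(u, K, max_iter = 100) {
  n <- nrow(u)
  cent <- u[sample.int(n, K), , drop = FALSE]
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    sim <- u %*% t(cent)                  # Pearson r to each centroid
    new_labels <- max.col(sim, ties.method = "first")
    ## re-seed empty clusters at the row farthest from its assigned centroid
    repeat {
      empty <- which(tabulate(new_labels, K) == 0L)
      if (!length(empty)) break
      k <- empty[1]
      far <- which.min(sim[cbind(seq_len(n), new_labels)])
      cent[k, ] <- u[far, ]
      sim[, k] <- u %*% cent[k, ]
      new_labels <- max.col(sim, ties.method = "first")
      new_labels[far] <- k
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (k in seq_len(K)) {
      ck <- colMeans(u[labels == k, , drop = FALSE])
      cent[k, ] <- ck / sqrt(sum(ck^2))
    }
  }
  sim <- u %*% t(cent)
  disp <- sum(1 - sim[cbind(seq_len(n), labels)])
  list(labels = labels, dispersion = disp)
}

#' Correlation-distance K-means over matrix rows
#'
#' Lloyd iterations with row distance 1 - Pearson correlation, centroids
#' renormalized each step, and empty clusters re-seeded at the row farthest
#' from all centroids. The best of `replicates` random initializations by
#' total within-cluster dispersion is returned; the result is deterministic
#' given `seed`.
#'
#' @param x numeric matrix; rows are clustered.
#' @param K number of clusters (>= 2).
#' @param replicates number of random restarts.
#' @param seed integer or NULL (use the current RNG stream).
#' @return object of class `cluster_solution`: `K`, `labels` (1..K per row),
#'   `dispersion`, `seed`.
#' @export
kmeans_rows <- function(x, K, replicates = 10, seed = NULL) {
  stopifnot(K >= 2, nrow(x) >= K)
  u <- standardize_rows(x)
  if (K > nrow(unique(round(u, 12)))) stop("K exceeds the number of distinct rows")
  best <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(replicates)) {
      fit <- kmeans_corr_once(u, K)
      if (is.null(best) || fit$dispersion < best$dispersion) best <- fit
    }
    best
  })
  structure(list(K = as.integer(K), labels = best$labels,
                 dispersion = best$dispersion, seed = seed),
            class = "cluster_solution")
}

#' Partition indices into near-equal random folds
#'
#' @param n number of items.
#' @param n_folds number of folds; sizes differ by at most one.
#' @param seed integer or NULL.
#' @return list of integer index vectors.
#' @export
partition_folds <- function(n, n_folds = 4, seed = NULL) {
  stopifnot(n >= n_folds, n_folds >= 2)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(n_folds), sizes))
}

#' Dice coefficient between two co-assignment structures
#'
#' Each label vector induces a binary co-assignment adjacency over item pairs
#' (1 iff two items share a cluster); the Dice coefficient
#' 2|A and B| / (|A| + |B|) is computed over the upper triangle via the
#' contingency table, so it is invariant to label permutation and symmetric in
#' its arguments.
#'
#' @param labels_a,labels_b integer cluster labels of the same items.
#' @return Dice coefficient in [0, 1] (NaN if both partitions are all
#'   singletons).
#' @export
dice_coassign <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  ct <- table(labels_a, labels_b)
  pairs <- function(v) sum(v * (v - 1) / 2)
  inter <- pairs(as.vector(ct))
  a <- pairs(rowSums(ct))
  b <- pairs(colSums(ct))
  2 * inter / (a + b)
}

#' Fold-based clustering stability curve
#'
#' Columns (nodes) are randomly split into `n_folds` near-equal folds; the
#' rows are clustered independently within each fold at every K; each fold's
#' solution is summarized by its co-assignment adjacency over a fixed row
#' subsample (at most `max_rows` rows, drawn once per run); and every pair of
#' folds is compared with the Dice coefficient. The curve reports the mean
#' over all fold pairs per K.
#'
#' @param x voxel x node matrix (e.g. `clusterable_rows()$x`).
#' @param K_range candidate numbers of clusters.
#' @param n_folds number of column folds.
#' @param replicates K-means restarts per fold.
#' @param seed integer controlling fold assignment, row subsample and all
#'   K-means restarts.
#' @param max_rows co-assignment row-subsample cap.
#' @return object of class `stability_curve`: data.frame `curve` (K,
#'   mean_dice), matrix `pair_dice` (fold pairs x K), `folds`, `rows_used`,
#'   `seed`.
#' @export
stability_profile <- function(x, K_range = 2:22, n_folds = 4,
                              replicates = 10, seed = 1L, max_rows = 2000) {
  folds <- partition_folds(ncol(x), n_folds, seed = child_seed(seed, 1L))
  if (min(lengths(folds)) < max(K_range))
    stop("a fold has fewer columns (", min(lengths(folds)),
         ") than the largest K (", max(K_range), ")")
  rows_used <- seq_len(nrow(x))
  if (nrow(x) > max_rows)
    rows_used <- sort(with_seed(child_seed(seed, 2L),
                                sample.int(nrow(x), max_rows)))
  pair_idx <- utils::combn(n_folds, 2)
  pair_dice <- matrix(NA_real_, ncol(pair_idx), length(K_range),
                      dimnames = list(paste0("f", pair_idx[1, ], "f",
                                             pair_idx[2, ]), K_range))
  for (ki in seq_along(K_range)) {
    K <- K_range[ki]
    labs <- lapply(seq_len(n_folds), function(f)
      kmeans_rows(x[, folds[[f]], drop = FALSE], K, replicates,
                  seed = child_seed(seed, 100L + K * 10L + f))$labels[rows_used])
    for (p in seq_len(ncol(pair_idx)))
      pair_dice[p, ki] <- dice_coassign(labs[[pair_idx[1, p]]],
                                        labs[[pair_idx[2, p]]])
  }
  structure(list(curve = data.frame(K = K_range,
                                    mean_dice = colMeans(pair_dice)),
                 pair_dice = pair_dice, folds = folds,
                 rows_used = rows_used, seed = seed),
            class = "stability_curve")
}

#' Stable K values from a stability curve
#'
#' @param curve a [stability_profile()] result (or its `curve` data.frame).
#' @param threshold minimum mean Dice; the comparison is strict (`>`), so a
#'   mean Dice exactly at the threshold is not stable.
#' @return integer vector of stable K values.
#' @export
select_stable_K <- function(curve, threshold = 0.85) {
  cv <- if (inherits(curve, "stability_curve")) curve$curve else curve
  stopifnot(nrow(cv) > 0)
  as.integer(cv$K[cv$mean_dice > threshold])
}
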