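## Network-level functional connectivity: Fisher-z matrices, normality
## screening, one- and two-sample edge tests with Bonferroni correction,
## behavioral partial correlation, and gray-white loop detection.

#' Average network time courses
#'
#' @param series voxel x time matrix.
#' @param labels integer vector (1..K) assigning each row to a network.
#' @param prefix name prefix for the networks (e.g. `"GM"`).
#' @return K x time matrix of unweighted member means, rownames
#'   `prefix1..prefixK`.
#' @export
network_timeseries <- function(series, labels, prefix = "N") {
  stopifnot(nrow(series) == length(labels))
  K <- max(labels)
  empty <- setdiff(seq_len(K), unique(labels))
  if (length(empty)) stop("empty network(s): ", paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(seq_len(K), function(k)
    colMeans(series[labels == k, , drop = FALSE])))
  rownames(out) <- paste0(prefix, seq_len(K))
  out
}

#' Fisher-z functional connectivity matrices
#'
#' Pearson correlation between every pair of network time courses, Fisher-z
#' transformed (z = atanh r), split into within-GM, within-WM and GM-WM
#' families by the row-name prefixes.
#'
#' @param net network x time matrix with rownames prefixed `GM`/`WM` (as from
#'   [network_timeseries()] stacked over tissues).
#' @return list of class `fc_set`: `gm_gm`, `wm_wm` (square symmetric, NA
#'   diagonal), `gm_wm` (GM x WM).
#' @export
fc_matrices <- function(net) {
  stopifnot(ncol(net) >= 3)
  r <- stats::cor(t(net))
  off <- abs(r) >= 1 - 1e-12 & row(r) != col(r)
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1, ]
    stop("|r| = 1 between ", rownames(r)[bad[1]], " and ",
         rownames(r)[bad[2]], ": Fisher z is infinite")
  }
  z <- atanh(r)
  diag(z) <- NA_real_
  gm <- grep("^GM", rownames(net))
  wm <- grep("^WM", rownames(net))
  structure(list(gm_gm = z[gm, gm, drop = FALSE],
                 wm_wm = z[wm, wm, drop = FALSE],
                 gm_wm = z[gm, wm, drop = FALSE]), class = "fc_set")
}

## Edge list of one family: data.frame(a, b) of unordered pairs (within-tissue
## upper triangle) or all cross pairs.
family_edges <- function(fc, family) {
  m <- fc[[family]]
  if (family == "gm_wm") {
    expand.grid(a = rownames(m), b = colnames(m),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    ut <- which(upper.tri(m), arr.ind = TRUE)
    data.frame(a = rownames(m)[ut[, 1]], b = colnames(m)[ut[, 2]],
               stringsAsFactors = FALSE)
  }
}

#' Subjects-by-edges matrix of Fisher-z values for one family
#'
#' @param fc_list list of per-subject [fc_matrices()] results.
#' @param family `"gm_gm"`, `"wm_wm"` or `"gm_wm"`.
#' @return numeric matrix, subjects x edges, edge columns named `"A-B"`.
#' @export
collect_edges <- function(fc_list, family = c("gm_gm", "wm_wm", "gm_wm")) {
  family <- match.arg(family)
  ed <- family_edges(fc_list[[1]], family)
  out <- do.call(rbind, lapply(fc_list, function(fc)
    fc[[family]][cbind(match(ed$a, rownames(fc[[family]])),
                       match(ed$b, colnames(fc[[family]])))]))
  colnames(out) <- paste0(ed$a, "-", ed$b)
  rownames(out) <- names(fc_list)
  out
}

#' Skewness/kurtosis screen of edge distributions
#'
#' Sample skewness and excess kurtosis (type 2, the SPSS/SAS convention) of
#' each edge's Fisher-z values within each group; an edge passes when both
#' statistics lie strictly within (-2, 2), the conventional band for treating
#' values as near-normal.
#'
#' @param z subjects x edges matrix.
#' @param group factor/character vector per subject.
#' @return data.frame: edge, group, skewness, kurtosis, pass.
#' @export
normality_screen <- function(z, group) {
  stopifnot(nrow(z) == length(group))
  res <- do.call(rbind, lapply(unique(group), function(g) {
    zg <- z[group == g, , drop = FALSE]
    if (nrow(zg) < 4) stop("need >= 4 subjects per group, got ", nrow(zg))
    if (any(apply(zg, 2, stats::sd) == 0)) stop("zero-variance edge in group ", g)
    data.frame(edge = colnames(z), group = g,
               skewness = apply(zg, 2, e1071::skewness, type = 2),
               kurtosis = apply(zg, 2, e1071::kurtosis, type = 2),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  res$pass <- abs(res$skewness) < 2 & abs(res$kurtosis) < 2
  res
}

#' One-sample edge tests within each group
#'
#' Per edge and group, a one-sample t-test of the Fisher-z values against
#' zero, Bonferroni-corrected within the matrix family (m = number of edges in
#' `z`). The union of the two groups' significant edges defines the tested
#' set passed to the group comparison.
#'
#' @param z subjects x edges matrix (one family).
#' @param group two-level grouping vector per subject.
#' @param alpha family-wise significance level.
#' @return list: `per_group` data.frame (edge, group, t, p, significant),
#'   `tested_edges` (character union), `m` (family size).
#' @export
one_sample_edges <- function(z, group, alpha = 0.05) {
  stopifnot(nrow(z) == length(group))
  m <- ncol(z)
  per <- do.call(rbind, lapply(unique(group), function(g) {
    zg <- z[group == g, , drop = FALSE]
    if (nrow(zg) < 3) stop("need >= 3 subjects per group")
    tt <- apply(zg, 2, function(v) {
      if (stats::sd(v) == 0) stop("zero-variance edge")
      ht <- stats::t.test(v, mu = 0)
      c(ht$statistic, ht$p.value)
    })
    data.frame(edge = colnames(z), group = g, t = tt[1, ], p = tt[2, ],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  per$significant <- per$p < alpha / m
  list(per_group = per,
       tested_edges = unique(per$edge[per$significant]), m = m)
}

#' Two-sample edge tests between groups
#'
#' Pooled-variance (or Welch) two-sample t-test per tested edge; the
#' Bonferroni family is the number of tested edges in this matrix family.
#'
#' @param z subjects x edges matrix (one family).
#' @param group two-level grouping vector; the first level in `levels`
#'   (default: pain-like first level encountered) is reported as group A.
#' @param tested_edges character vector of edge names to test (default: all).
#' @param alpha family-wise significance level.
#' @param var_equal use the pooled-variance form (default TRUE).
#' @return data.frame of class `edge_stats`: edge, mean_z_a, mean_z_b, t, p,
#'   significant, direction (+1 if group A > group B), with attributes `m`
#'   (family size) and `alpha`.
#' @export
two_sample_edges <- function(z, group, tested_edges = colnames(z),
                             alpha = 0.05, var_equal = TRUE) {
  gl <- unique(group)
  stopifnot(length(gl) == 2, length(tested_edges) >= 1)
  za <- z[group == gl[1], tested_edges, drop = FALSE]
  zb <- z[group == gl[2], tested_edges, drop = FALSE]
  if (nrow(za) < 3 || nrow(zb) < 3) stop("need >= 3 subjects per group")
  m <- length(tested_edges)
  res <- do.call(rbind, lapply(seq_len(m), function(j) {
    ht <- stats::t.test(za[, j], zb[, j], var.equal = var_equal)
    data.frame(edge = tested_edges[j],
               mean_z_a = mean(za[, j]), mean_z_b = mean(zb[, j]),
               t = unname(ht$statistic), p = ht$p.value,
               stringsAsFactors = FALSE)
  }))
  res$significant <- res$p < alpha / m
  res$direction <- sign(res$mean_z_a - res$mean_z_b)
  attr(res, "m") <- m
  attr(res, "alpha") <- alpha
  attr(res, "groups") <- gl
  class(res) <- c("edge_stats", class(res))
  res
}

#' Partial correlation of an edge with behavior, controlling age and sex
#'
#' Both variables are residualized on an intercept, age and sex; the Pearson
#' correlation of the residuals is reported with a t-based p-value on
#' n - 2 - k degrees of freedom (k = 2 covariates).
#'
#' @param edge_z per-subject Fisher-z values of one edge.
#' @param behavior per-subject behavioral score (e.g. VAS change).
#' @param age,sex covariates (sex coded 0/1).
#' @return list: r, p, df, n.
#' @export
behavior_partial_corr <- function(edge_z, behavior, age, sex) {
  ok <- stats::complete.cases(edge_z, behavior, age, sex)
  edge_z <- edge_z[ok]; behavior <- behavior[ok]
  age <- age[ok]; sex <- sex[ok]
  n <- length(edge_z); k <- 2L
  if (n < k + 3L) stop("need at least ", k + 3L, " complete observations")
  if (stats::sd(behavior) == 0) stop("behavior score is constant")
  X <- cbind(1, age, sex)
  rx <- stats::lm.fit(X, edge_z)$residuals
  ry <- stats::lm.fit(X, behavior)$residuals
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), df = df, n = n)
}

#' Find gray-white loops in the significant-difference edge graph
#'
#' Enumerates all simple cycles of length 3..`max_len` in the graph whose
#' edges are the significantly different network pairs (across all three
#' matrix families), keeping only cycles that contain at least one GM and one
#' WM network. Each cycle is reported once, canonicalized over rotation and
#' reflection, with the per-edge direction of the group difference retained.
#'
#' @param stats_list list of [two_sample_edges()] results (any subset of the
#'   three families), or a single data.frame.
#' @param max_len maximum cycle length.
#' @return list of class `loop_set`; each element has `nodes` (ordered
#'   cycle), `tissues`, and `edges` (data.frame a, b, direction).
#' @export
find_loops <- function(stats_list, max_len = 4) {
  if (is.data.frame(stats_list)) stats_list <- list(stats_list)
  ed <- do.call(rbind, lapply(stats_list, function(s)
    s[s$significant, c("edge", "direction")]))
  loops <- list()
  if (nrow(ed)) {
    ab <- do.call(rbind, strsplit(ed$edge, "-", fixed = TRUE))
    edges <- data.frame(a = ab[, 1], b = ab[, 2], direction = ed$direction,
                        stringsAsFactors = FALSE)
    nodes <- sort(unique(c(edges$a, edges$b)))
    adj <- lapply(nodes, function(v)
      sort(unique(c(edges$b[edges$a == v], edges$a[edges$b == v]))))
    names(adj) <- nodes
    dirmap <- stats::setNames(edges$direction, paste0(pmin(edges$a, edges$b),
                                                      "|", pmax(edges$a, edges$b)))
    cycles <- list()
    ## DFS from each start node over nodes that sort after it; a cycle is
    ## recorded once per direction, deduplicated by requiring the second node
    ## to sort before the last.
    dfs <- function(start, path) {
      v <- path[length(path)]
      for (w in adj[[v]]) {
        if (w == start && length(path) >= 3) {
          if (path[2] < path[length(path)])
            cycles[[length(cycles) + 1L]] <<- path
        } else if (w > start && !(w %in% path) && length(path) < max_len) {
          dfs(start, c(path, w))
        }
      }
    }
    for (s in nodes) dfs(s, s)
    keep <- Filter(function(cy) any(grepl("^GM", cy)) && any(grepl("^WM", cy)),
                   cycles)
    loops <- lapply(keep, function(cy) {
      a <- cy; b <- c(cy[-1], cy[1])
      list(nodes = cy,
           tissues = ifelse(grepl("^GM", cy), "GM", "WM"),
           edges = data.frame(a = a, b = b,
                              direction = unname(dirmap[paste0(pmin(a, b), "|",
                                                               pmax(a, b))]),
                              stringsAsFactors = FALSE))
    })
  }
  structure(loops, class = "loop_set")
}

#' @export
print.loop_set <- function(x, ...) {
  cat("loop_set:", length(x), "gray-white loop(s)\n")
  for (l in x)
    cat("  ", paste(c(l$nodes, l$nodes[1]), collapse = "-"), " (",
        paste(ifelse(l$edges$direction > 0, "+", "-"), collapse = ""),
        ")\n", sep = "")
  invisible(x)
}
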