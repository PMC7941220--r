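#!/usr/bin/env Rscript
## Step 5: network-level statistics. Mean time course per estimated network,
## Fisher-z FC matrices per subject (within-GM, within-WM, GM-WM), the
## skewness/kurtosis screen, one-sample tests defining the tested-edge set,
## Bonferroni-corrected two-sample group comparisons, gray-white loop
## detection in the significant-difference graph, and the behavioral partial
## correlation (VAS change vs the planted edge, age and sex controlled).
library(gwnet)

st1 <- readRDS("scratch/analysis/01_cohort.rds")
st2 <- readRDS("scratch/analysis/02_clean.rds")
st3 <- readRDS("scratch/analysis/03_group.rds")
st4 <- readRDS("scratch/analysis/04_parcels.rds")
spec <- st1$spec; truth <- st1$truth

## estimated clusters renamed by their majority planted network so edge names
## are comparable across runs
relab <- list()
for (tis in c("gm", "wm")) {
  vox <- st3$grids[[tis]]$voxels[st4[[tis]]$rows]
  tl <- (if (tis == "gm") truth$gm_labels else truth$wm_labels)[vox]
  ct <- table(st4[[tis]]$solution$labels, tl)
  mp <- as.integer(colnames(ct))[max.col(ct, ties.method = "first")]
  relab[[tis]] <- mp[st4[[tis]]$solution$labels]
}

fc_list <- lapply(st2$retained, function(id) {
  net <- rbind(
    network_timeseries(st2$series$gm[[id]][st4$gm$rows, , drop = FALSE],
                       relab$gm, prefix = "GM"),
    network_timeseries(st2$series$wm[[id]][st4$wm$rows, , drop = FALSE],
                       relab$wm, prefix = "WM"))
  fc_matrices(net)
})
names(fc_list) <- st2$retained
group <- truth$subjects$group[match(st2$retained, truth$subjects$subject)]

all_stats <- list(); all_rows <- NULL
for (fam in c("gm_gm", "wm_wm", "gm_wm")) {
  z <- collect_edges(fc_list, fam)
  scr <- normality_screen(z, group)
  cat(fam, ": ", ncol(z), " edges, ", sum(scr$pass), "/", nrow(scr),
      " group-edge distributions pass the (-2,2) skew/kurtosis screen\n",
      sep = "")
  os <- one_sample_edges(z, group, alpha = 0.05)
  if (length(os$tested_edges)) {
    ts <- two_sample_edges(z, group, os$tested_edges, alpha = 0.05)
    all_stats[[fam]] <- ts
    all_rows <- rbind(all_rows, cbind(family = fam, as.data.frame(ts)))
  }
}
write.table(all_rows, "results/05_edge_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- all_rows[all_rows$significant, ]
cat("Significant group differences after Bonferroni:", nrow(sig), "edge(s)\n")
if (nrow(sig)) print(sig[, c("family", "edge", "t", "p", "direction")],
                     row.names = FALSE)

loops <- find_loops(all_stats, max_len = 4)
print(loops)
if (length(loops)) {
  ldf <- do.call(rbind, lapply(seq_along(loops), function(i)
    data.frame(loop = i, cycle = paste(c(loops[[i]]$nodes,
                                         loops[[i]]$nodes[1]),
                                       collapse = "-"),
               directions = paste(ifelse(loops[[i]]$edges$direction > 0,
                                         "+", "-"), collapse = ""))))
  write.table(ldf, "results/05_loops.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
}

beh <- truth$behavior[match(st2$retained, truth$behavior$subject), ]
pain <- beh$group == "pain"
edge <- paste(spec$behavior_spec$edge, collapse = "-")
z_cross <- collect_edges(fc_list, "gm_wm")
pc <- behavior_partial_corr(z_cross[pain, edge],
                            beh$vas_24h[pain] - beh$vas_pre[pain],
                            beh$age[pain], beh$sex[pain])
cat(sprintf("Partial correlation (VAS change vs %s | age, sex): r = %.3f, p = %.3f (n = %d)\n",
            edge, pc$r, pc$p, pc$n))
write.table(data.frame(edge = edge, r = pc$r, p = pc$p, n = pc$n,
                       planted_r = spec$behavior_spec$partial_r),
            "results/05_behavior_partial_corr.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
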