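#!/usr/bin/env Rscript

# Step 5: unsupervised structure of the differential mitochondrial proteins.
# Complete-linkage hierarchical clustering (k = 6) of z-scored per-timepoint
# mean profiles, classical MDS of samples, per-cluster profile summaries,
# and a hypergeometric over-representation test of the clusters against the
# generator's response classes used as stand-in pathway sets.

suppressPackageStartupMessages({library(bestnorm); library(readr); library(dplyr)})

need <- c("results/tables/best_normalised.tsv",
          "results/tables/global_differential_set.tsv")
if (!all(file.exists(need))) stop("run analysis/03 and /04 first")

design <- read_design("results/data/effects/design.csv")
vals <- read_tsv(need[1], show_col_types = FALSE)
m <- as.matrix(vals[, -1]); rownames(m) <- vals$feature
global <- read_tsv(need[2], show_col_types = FALSE)$feature

d <- design[match(colnames(m), design$sample), ]
tpm <- vapply(levels(d$timepoint), function(tp) {
  rowMeans(m[global, d$sample[as.character(d$timepoint) == tp], drop = FALSE])
}, numeric(length(global)))

cl <- hierarchical_cluster(zscore_rows(tpm), "complete", k = 6)
write_tsv(tibble::tibble(feature = names(cl$cluster), cluster = cl$cluster),
          "results/tables/clusters.tsv")
cat("cluster sizes:\n"); print(table(cl$cluster))

mds <- classical_mds(zscore_rows(m))
write_tsv(tibble::as_tibble(mds$points, rownames = "sample") |>
            mutate(timepoint = as.character(d$timepoint)),
          "results/tables/mds.tsv")

prof <- profile_summary(m, design, split(names(cl$cluster), cl$cluster))
write_tsv(prof, "results/tables/cluster_profiles.tsv")

truth <- read_tsv("results/data/effects/truth.tsv", show_col_types = FALSE)
classes <- split(truth$feature, truth$effect_class)
classes$stoichiometric <- NULL
universe <- rownames(m)
enr <- bind_rows(lapply(sort(unique(cl$cluster)), function(k) {
  overrepresentation_test(names(cl$cluster)[cl$cluster == k],
                          lapply(classes, intersect, universe), universe) |>
    mutate(cluster = k, .before = 1)
}))
write_tsv(enr, "results/tables/cluster_enrichment.tsv")

ari <- mclust::adjustedRandIndex(
  truth$effect_class[match(names(cl$cluster), truth$feature)], cl$cluster)
cat(sprintf("adjusted Rand index of clusters vs programmed classes: %.3f\n", ari))
top <- enr |> filter(adj_p < 0.01) |> group_by(cluster) |> slice_min(adj_p, n = 1)
cat("top enriched class per cluster:\n")
print(as.data.frame(top[, c("cluster", "pathway", "overlap", "adj_p")]))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  library(ggplot2)
  pts <- tibble::as_tibble(mds$points, rownames = "sample") |>
    mutate(timepoint = as.character(d$timepoint))
  ggsave("results/figures/mds.png",
         ggplot(pts, aes(dim1, dim2, colour = timepoint)) +
           geom_point(size = 2.5) + theme_minimal() +
           labs(title = "Classical MDS of BESt-normalised samples"),
         width = 5, height = 4, dpi = 150)
  ggsave("results/figures/cluster_profiles.png",
         ggplot(prof, aes(factor(timepoint, levels = levels(d$timepoint)),
                          mean_z, group = set)) +
           geom_line() + geom_point() +
           geom_errorbar(aes(ymin = mean_z - sd_z, ymax = mean_z + sd_z), width = 0.15) +
           facet_wrap(~set) + theme_minimal() +
           labs(x = "timepoint", y = "mean z-score",
                title = "Cluster response profiles"),
         width = 7, height = 5, dpi = 150)
  cat("figures written under results/figures\n")
}
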