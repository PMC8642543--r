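#!/usr/bin/env Rscript

# Step 4: differential abundance on the BESt scale.
# Per-feature linear models on the timepoint factor with participant
# blocking, empirical-Bayes variance shrinkage, BH-adjusted moderated F at
# adj-p < 0.01 for the global set, and pairwise permutation-FDR t-tests
# versus baseline intersected with the global set (the conservative
# two-tier scheme). Lipidomics: cardiolipin-class normalisation, log2, the
# same moderated models at adj-p < 0.05.

suppressPackageStartupMessages({library(bestnorm); library(readr); library(dplyr)})

src <- "results/data/effects"
if (!dir.exists(src)) stop("run analysis/01_simulate.R first")
if (!file.exists("results/tables/best_normalised.tsv")) {
  stop("run analysis/03_normalise.R first")
}

design <- read_design(file.path(src, "design.csv"))
vals <- read_tsv("results/tables/best_normalised.tsv", show_col_types = FALSE)
m <- as.matrix(vals[, -1])
rownames(m) <- vals$feature

stats <- empirical_bayes_moderation(fit_linear_models(m, design, "phase"))
print(stats)

tps <- levels(droplevels(design$timepoint[design$layer == "proteomics"]))
perm <- lapply(tps[-1], function(tp) {
  pairwise_permutation_fdr(m, design, c(tp, tps[1]), n_perm = 1000,
                           seed = 400 + match(tp, tps))
})
sets <- differential_features(stats, perm, alpha_global = 0.01,
                              alpha_pairwise = 0.05)

write_tsv(stats$table, "results/tables/moderated_stats.tsv")
write_tsv(bind_rows(lapply(perm, function(p) {
  mutate(p$table, comparison = paste(p$comparison, collapse = "-"))
})), "results/tables/perm_fdr.tsv")
write_tsv(tibble::tibble(feature = sets$global),
          "results/tables/global_differential_set.tsv")

truth <- read_tsv(file.path(src, "truth.tsv"), show_col_types = FALSE)
pos <- truth$feature[truth$effect_class != "stoichiometric"]
pos <- intersect(pos, stats$table$feature)
called <- sets$global
cat(sprintf("global set: %d proteins at adjusted p(F) < 0.01\n", length(called)))
for (nm in names(sets$per_comparison)) {
  cat(sprintf("  %s: %d proteins (q < 0.05 and global)\n",
              nm, length(sets$per_comparison[[nm]])))
}
cat(sprintf("against the generator truth: sensitivity %.2f, observed FDP %.2f\n",
            length(intersect(called, pos)) / length(pos),
            ifelse(length(called) > 0,
                   length(setdiff(called, pos)) / length(called), NA)))

# lipidomics branch
lip_design <- design[design$layer == "lipidomics", ]
lipids <- read_lipid_table(file.path(src, "lipids.csv"), design)
lip_norm <- normalise_lipids_by_class(lipids, "CL")
lip_stats <- empirical_bayes_moderation(fit_linear_models(
  log2(lip_norm$values), lip_design, "phase"))
write_tsv(lip_stats$table, "results/tables/lipid_stats.tsv")
cat(sprintf("lipids: %d species differential at adjusted p(F) < 0.05 after CL normalisation\n",
            sum(lip_stats$table$adj_p_F < 0.05)))
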