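#' Pipeline configuration
#'
#' Bundles the options of every stage of the end-to-end analysis. Exactly
#' one input source is active: either a pre-built `synth_cohort` / ingested
#' data (`cohort`) or a simulation configuration (`sim`).
#'
#' @param cohort optional `synth_cohort` (or list with the same slots built
#'   from ingested data).
#' @param sim optional [cohort_config()]; used when `cohort` is NULL.
#' @param min_valid_fraction,level,vsn_scope,lts_quantile BESt chain options.
#' @param contrast_scheme,alpha_global,alpha_pairwise,n_perm,perm_mode
#'   differential-abundance options.
#' @param k,linkage clustering options.
#' @param anchor_class,alpha_lipids lipidomics options.
#' @param out_dir optional output directory; when set, every stage output is
#'   written as TSV with a sidecar JSON of parameters.
#' @param seed global seed fanned out to stage seeds via [stage_seed()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, sim = NULL,
                            min_valid_fraction = 0.70,
                            level = "Known Mitochondrial",
                            vsn_scope = "mito", lts_quantile = 0.9,
                            contrast_scheme = "phase",
                            alpha_global = 0.01, alpha_pairwise = 0.05,
                            n_perm = 1000, perm_mode = "unpaired",
                            k = 6, linkage = "complete",
                            anchor_class = "CL", alpha_lipids = 0.05,
                            out_dir = NULL, seed = 1L) {
  if (is.null(cohort) && is.null(sim)) abort_fmt("provide either cohort or sim")
  if (!is.null(cohort) && !is.null(sim)) abort_fmt("provide cohort or sim, not both")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the end-to-end BESt analysis
#'
#' Executes the fixed stage order: (simulate) -> MPE -> BESt normalisation
#' (valid-value filter, mitochondrial subset, variance calibration,
#' left-censored imputation) -> moderated linear models with empirical-Bayes
#' shrinkage and BH adjustment -> pairwise permutation FDR vs baseline ->
#' two-tier differential sets -> clustering / MDS / profiles ->
#' cardiolipin-normalised lipidomics -> recovery report against the
#' generator's ground truth when available.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `mpe`, `normalised`,
#'   `stats`, `perm`, `sets`, `clusters`, `mds`, `profiles`, `lipid_stats`,
#'   `recovery`, `timings`, `config`.
#' @export
run_best_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  tick <- function(expr, name) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    val
  }

  cohort <- config$cohort %||% tick(generate_cohort(config$sim), "simulate")
  design <- cohort$design

  mpe <- tick(compute_mpe(cohort$proteins, cohort$annotation, config$level), "mpe")

  normalised <- tick(suppressMessages(best_normalise(
    cohort$proteins, cohort$annotation,
    min_valid_fraction = config$min_valid_fraction, level = config$level,
    vsn_scope = config$vsn_scope, lts_quantile = config$lts_quantile,
    seed = stage_seed(config$seed, 11))), "normalise")

  fits <- tick(fit_linear_models(normalised, design, config$contrast_scheme), "fit")
  stats <- tick(empirical_bayes_moderation(fits), "moderate")

  tps <- levels(droplevels(design$timepoint))
  perm <- tick(lapply(tps[-1], function(tp) {
    pairwise_permutation_fdr(normalised, design, c(tp, tps[1]),
                             n_perm = config$n_perm,
                             seed = stage_seed(config$seed, 13 + match(tp, tps)),
                             mode = config$perm_mode)
  }), "permutation")

  sets <- differential_features(stats, perm, config$alpha_global, config$alpha_pairwise)

  # structure on the differential features (fall back to all when too few)
  feats <- if (length(sets$global) >= config$k) sets$global else rownames(normalised$values)
  z <- zscore_rows(tp_mean_matrix(normalised$values[feats, , drop = FALSE], design))
  clusters <- tick(hierarchical_cluster(z, config$linkage, min(config$k, nrow(z))), "cluster")
  mds <- tick(classical_mds(zscore_rows(normalised$values)), "mds")
  profiles <- profile_summary(
    normalised$values, design,
    split(names(clusters$cluster), clusters$cluster))

  lipid_stats <- NULL
  if (!is.null(cohort$lipids)) {
    lipid_stats <- tick(lipid_de(cohort, config), "lipids")
  }

  recovery <- NULL
  if (!is.null(cohort$truth)) {
    recovery <- recovery_report(cohort, normalised, stats, sets, clusters, config)
  }

  result <- structure(list(
    mpe = mpe, normalised = normalised, stats = stats, perm = perm,
    sets = sets, clusters = clusters, mds = mds, profiles = profiles,
    lipid_stats = lipid_stats, recovery = recovery,
    timings = unlist(timings), config = config
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_result(result, cohort, config$out_dir)
  result
}

# per-timepoint mean profile matrix (features x timepoints)
tp_mean_matrix <- function(values, design) {
  d <- design[match(colnames(values), design$sample), , drop = FALSE]
  tps <- levels(droplevels(d$timepoint))
  out <- vapply(tps, function(tp) {
    rowMeans(values[, d$sample[as.character(d$timepoint) == tp], drop = FALSE])
  }, numeric(nrow(values)))
  rownames(out) <- rownames(values)
  out
}

# lipidomics branch: anchor-class normalisation, log2, moderated stats at 0.05
lipid_de <- function(cohort, config) {
  lip <- normalise_lipids_by_class(cohort$lipids, config$anchor_class)
  vals <- log2(pmax(lip$values, .Machine$double.xmin))
  fits <- fit_linear_models(vals, cohort$lipid_design %||% cohort$design,
                            config$contrast_scheme)
  stats <- empirical_bayes_moderation(fits)
  sets <- differential_features(stats, alpha_global = config$alpha_lipids)
  list(stats = stats, sets = sets, normalised = lip)
}

# compare calls, clusters and realised MPE against the generator truth
recovery_report <- function(cohort, normalised, stats, sets, clusters, config) {
  truth <- cohort$truth
  universe <- stats$table$feature
  true_pos <- names(truth$effect_class)[truth$effect_class != "stoichiometric"]
  true_pos <- intersect(true_pos, universe)
  called <- sets$global
  sensitivity <- if (length(true_pos) > 0) {
    length(intersect(called, true_pos)) / length(true_pos)
  } else NA_real_
  fdp <- if (length(called) > 0) {
    length(setdiff(called, true_pos)) / length(called)
  } else NA_real_

  ari <- NA_real_
  cl_feats <- intersect(names(clusters$cluster), true_pos)
  if (length(cl_feats) >= 2 &&
      length(unique(truth$effect_class[cl_feats])) >= 2) {
    ari <- mclust::adjustedRandIndex(truth$effect_class[cl_feats],
                                     clusters$cluster[cl_feats])
  }

  mpe_err <- NA_real_
  if (!is.null(cohort$config) && is.null(cohort$config$content_multiplier)) {
    d <- cohort$design
    grp <- tapply(truth$realised_mpe[d$sample], as.character(d$timepoint), mean)
    tgt <- cohort$config$mpe_target
    mpe_err <- max(abs(grp[names(tgt)] - tgt))
  }

  cfg <- config
  cfg$cohort <- NULL
  list(sensitivity = sensitivity, fdp = fdp, cluster_ari = ari,
       n_called = length(called), n_true = length(true_pos),
       mpe_trajectory_error = mpe_err,
       degenerate_truth = length(true_pos) == 0,
       config_hash = rlang::hash(cfg))
}

write_pipeline_result <- function(result, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$mpe, file.path(dir, "mpe.tsv"))
  nm <- result$normalised
  readr::write_tsv(tibble::as_tibble(nm$values, rownames = "feature"),
                   file.path(dir, "normalised.tsv"))
  jsonlite::write_json(
    list(a = as.list(nm$a), b = as.list(nm$b), offset = nm$offset,
         iterations = nm$iterations, seed = result$config$seed),
    file.path(dir, "normalised.params.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(result$stats$table, file.path(dir, "moderated_stats.tsv"))
  for (p in result$perm) {
    readr::write_tsv(p$table, file.path(
      dir, sprintf("perm_fdr_%s.tsv", paste(p$comparison, collapse = "_"))))
  }
  readr::write_tsv(tibble::tibble(feature = names(result$clusters$cluster),
                                  cluster = result$clusters$cluster),
                   file.path(dir, "clusters.tsv"))
  readr::write_tsv(tibble::as_tibble(result$mds$points, rownames = "sample"),
                   file.path(dir, "mds.tsv"))
  readr::write_tsv(result$profiles, file.path(dir, "profiles.tsv"))
  if (!is.null(result$lipid_stats)) {
    readr::write_tsv(result$lipid_stats$stats$table, file.path(dir, "lipid_stats.tsv"))
  }
  if (!is.null(result$recovery)) {
    jsonlite::write_json(result$recovery, file.path(dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Side-by-side comparison of normalisation strategies
#'
#' Quantifies, against the generator's ground truth, what each strategy does
#' to per-feature effect estimates for mitochondrial proteins:
#' `none` (log2 of the closed raw intensities), `single_marker` (each sample
#' divided by one designated marker protein's value, the single-value
#' content-normalisation analogue of CS activity), and `best` (the BESt
#' chain). For every mitochondrial feature and timepoint the bias is the
#' estimated mean log2 change from baseline minus the true deviation; the
#' false-positive rate is the fraction of no-effect features below
#' `alpha` on the BH-adjusted moderated F. Per-feature residual variance
#' (within-timepoint, pooled) shows the cost of anchoring the correction to
#' a single noisy marker instead of the pooled subproteome trend.
#'
#' Runs on the complete (pre-missingness) matrix so the comparison isolates
#' the normalisation strategies from imputation.
#'
#' @param cohort a `synth_cohort`.
#' @param marker_feature feature id of the single marker; defaults to the
#'   first mitochondrial feature.
#' @param marker_cv_extra extra lognormal noise (sd on the log scale)
#'   injected into the marker's measurements before use, emulating a noisy
#'   single-marker assay; 0 for none.
#' @param alpha significance threshold for the false-positive rate.
#' @param seed seed for the marker-noise draw.
#' @return list with `per_feature` (tibble: strategy, feature, timepoint,
#'   estimate, true_delta, bias) and `summary` (tibble: strategy,
#'   mean_abs_bias, fp_rate, mean_feature_variance).
#' @export
compare_normalisations <- function(cohort, marker_feature = NULL,
                                   marker_cv_extra = 0, alpha = 0.01,
                                   seed = 1L) {
  stopifnot(inherits(cohort, "synth_cohort"))
  truth <- cohort$truth
  design <- cohort$design
  Y <- cohort$proteins_complete
  mito <- names(truth$is_mito)[truth$is_mito]
  if (is.null(marker_feature)) marker_feature <- mito[1]
  if (!marker_feature %in% rownames(Y)) abort_fmt("marker feature '%s' not in matrix", marker_feature)

  marker <- Y[marker_feature, ]
  if (marker_cv_extra > 0) {
    set.seed(seed)
    marker <- marker * exp(stats::rnorm(length(marker), 0, marker_cv_extra))
  }

  mats <- list(
    none = log2(Y[mito, , drop = FALSE]),
    single_marker = log2(sweep(Y[mito, , drop = FALSE], 2, marker, `/`)),
    best = suppressMessages(best_normalise(
      Y, cohort$annotation, seed = stage_seed(seed, 3)))$values)

  d <- design
  tps <- levels(droplevels(d$timepoint))
  null_feats <- names(truth$effect_class)[truth$effect_class == "stoichiometric"]

  per_feature <- list()
  summary_rows <- list()
  for (strat in names(mats)) {
    M <- mats[[strat]]
    est <- tp_mean_matrix(M, d)
    est <- est - est[, tps[1]]
    delta <- truth$delta[rownames(M), tps, drop = FALSE]
    delta <- delta - delta[, tps[1]]
    bias <- est - delta
    pf <- tibble::tibble(
      strategy = strat,
      feature = rep(rownames(M), length(tps)),
      timepoint = rep(tps, each = nrow(M)),
      estimate = as.numeric(est),
      true_delta = as.numeric(delta),
      bias = as.numeric(bias))
    per_feature[[strat]] <- pf

    fits <- fit_linear_models(M, d, "phase")
    st <- empirical_bayes_moderation(fits)
    nulls <- intersect(null_feats, st$table$feature)
    fp <- mean(st$table$adj_p_F[match(nulls, st$table$feature)] < alpha)

    # pooled within-timepoint variance per feature
    ss <- vapply(tps, function(tp) {
      cols <- d$sample[as.character(d$timepoint) == tp]
      apply(M[, cols, drop = FALSE], 1, stats::var)
    }, numeric(nrow(M)))
    summary_rows[[strat]] <- tibble::tibble(
      strategy = strat,
      mean_abs_bias = mean(abs(bias[, -1])),
      fp_rate = fp,
      mean_feature_variance = mean(ss))
  }
  list(per_feature = dplyr::bind_rows(per_feature),
       summary = dplyr::bind_rows(summary_rows),
       marker_feature = marker_feature, marker_cv_extra = marker_cv_extra)
}
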