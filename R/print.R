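#' @export
print.synth_cohort <- function(x, ...) {
  cat("Synthetic mitochondrial-isolate cohort\n")
  cat(sprintf("  proteins: %d features x %d samples (%.1f%% missing)\n",
              nrow(x$proteins), ncol(x$proteins), 100 * mean(is.na(x$proteins))))
  cat(sprintf("  lipids:   %d species (%d classes)\n",
              nrow(x$lipids$values), length(unique(x$lipids$classes))))
  cat(sprintf("  mito fraction: %.2f; timepoints: %s\n",
              mean(x$truth$is_mito),
              paste(levels(x$design$timepoint), collapse = " < ")))
  cat(sprintf("  content multipliers: %s\n",
              paste(sprintf("%s=%.3f", names(x$truth$content_multiplier),
                            x$truth$content_multiplier), collapse = ", ")))
  invisible(x)
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("Calibrated glog2 matrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  fit: %d objective evaluations, converged = %s\n",
              x$iterations, x$converged))
  cat(sprintf("  imputed entries: %d\n", sum(x$imputed)))
  invisible(x)
}

#' @export
print.moderated_stats <- function(x, ...) {
  cat(sprintf("Moderated statistics for %d features (%s contrasts)\n",
              nrow(x$table), x$contrast_scheme))
  cat(sprintf("  prior: d0 = %.3g, s0^2 = %.3g; residual df = %d; total df = %.4g\n",
              x$d0, x$s02, x$df_residual, x$df_total))
  cat(sprintf("  features at adjusted p(F) < 0.01: %d\n",
              sum(x$table$adj_p_F < 0.01, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("BESt pipeline result\n")
  cat(sprintf("  global differential set: %d features\n", length(x$sets$global)))
  for (nm in names(x$sets$per_comparison)) {
    cat(sprintf("    %s: %d\n", nm, length(x$sets$per_comparison[[nm]])))
  }
  if (!is.null(x$recovery) && !x$recovery$degenerate_truth) {
    cat(sprintf("  recovery: sensitivity %.2f, FDP %.2f, ARI %.2f\n",
                x$recovery$sensitivity, x$recovery$fdp, x$recovery$cluster_ari))
  }
  cat(sprintf("  runtime: %.1f s\n", sum(x$timings)))
  invisible(x)
}
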