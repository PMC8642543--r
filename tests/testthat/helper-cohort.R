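# shared fixtures, generated in code and cached per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small default-structure cohort for unit tests (fast)
small_config <- function(...) {
  cohort_config(n_participants = 6, n_features = 300, n_lipids = 60, ...)
}

small_cohort <- function() {
  cached("small", suppressWarnings(generate_cohort(small_config(seed = 11))))
}

# noise-free, complete, delta = 0: the analytic regime
clean_config <- function(...) {
  small_config(noise = list(cv = 0, sd_a = 0), participant_sd = 0,
               missingness = list(enabled = FALSE), ...)
}

clean_cohort <- function() cached("clean", generate_cohort(clean_config(seed = 5)))

make_design <- function(n_participants, timepoints = c("BL", "PN", "PH", "PR"),
                        layer = "proteomics") {
  participants <- sprintf("P%02d", seq_len(n_participants))
  g <- expand.grid(participant = participants, timepoint = timepoints,
                   stringsAsFactors = FALSE)
  tibble::tibble(
    sample = paste(g$participant, g$timepoint, sep = "_"),
    participant = g$participant,
    timepoint = factor(g$timepoint, levels = timepoints, ordered = TRUE),
    layer = layer)
}

# per-timepoint group means of a named per-sample vector
group_means <- function(x, design) {
  tapply(x[design$sample], as.character(design$timepoint), mean)
}

# orthogonal Procrustes residual (rotation/reflection + translation, no scale)
procrustes_error <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  sqrt(sum((Xc - Yc %*% R)^2))
}
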