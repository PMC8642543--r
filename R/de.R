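#' Per-feature linear models with participant blocking
#'
#' Ordinary least squares of each feature's transformed abundance on the
#' timepoint factor, with participant included as a fixed blocking factor
#' (the samples are repeated measures on the same subjects). Two contrast
#' schemes are supported: `"phase"` takes successive differences
#' (PN-BL, PH-PN, PR-PH), `"vs_baseline"` compares every later timepoint to
#' baseline (PN-BL, PH-BL, PR-BL). Coefficients are in log2 units when the
#' input is on a log2-compatible scale.
#'
#' @param matrix complete features x samples matrix (a `norm_matrix` is
#'   accepted) on the transformed scale.
#' @param design design tibble covering the samples.
#' @param contrast_scheme "phase" or "vs_baseline".
#' @param block_participant include the participant blocking factor
#'   (default TRUE); switch off for sensitivity analyses.
#' @return object of class `feature_fits`: `coefficients` (features x
#'   contrasts), `cov_unscaled` (contrast covariance up to sigma^2),
#'   `stdev_unscaled`, `sigma2`, `df_residual`, `contrasts`, `design_matrix`.
#' @export
fit_linear_models <- function(matrix, design,
                              contrast_scheme = c("phase", "vs_baseline"),
                              block_participant = TRUE) {
  contrast_scheme <- match.arg(contrast_scheme)
  Y <- if (inherits(matrix, "norm_matrix")) matrix$values else matrix
  if (anyNA(Y)) abort_fmt("linear models need a complete matrix; impute first")
  d <- design[match(colnames(Y), design$sample), , drop = FALSE]
  if (anyNA(d$sample)) abort_fmt("design does not cover all matrix samples")
  tp <- factor(as.character(d$timepoint), levels = levels(d$timepoint))
  tp <- droplevels(tp)
  dat <- data.frame(timepoint = tp, participant = factor(d$participant))
  X <- if (block_participant && nlevels(dat$participant) > 1) {
    stats::model.matrix(~ 0 + timepoint + participant, dat)
  } else {
    stats::model.matrix(~ 0 + timepoint, dat)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort_fmt("rank-deficient design; aliased term(s): %s", paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qrX, t(Y))                       # p x features
  res <- t(Y) - X %*% beta
  df_residual <- nrow(X) - qrX$rank
  sigma2 <- colSums(res^2) / df_residual

  C <- contrast_matrix(levels(tp), contrast_scheme, ncol(X), colnames(X))
  coefficients <- t(crossprod(C, beta))            # features x k
  xtx_inv <- chol2inv(qr.R(qrX)[seq_len(qrX$rank), , drop = FALSE])
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  cov_unscaled <- crossprod(C, xtx_inv %*% C)

  structure(list(
    coefficients = coefficients,
    cov_unscaled = cov_unscaled,
    stdev_unscaled = sqrt(diag(cov_unscaled)),
    sigma2 = stats::setNames(as.numeric(sigma2), rownames(Y)),
    df_residual = df_residual,
    contrasts = C, contrast_scheme = contrast_scheme,
    design_matrix = X
  ), class = "feature_fits")
}

contrast_matrix <- function(tp_levels, scheme, p, coef_names) {
  k <- length(tp_levels) - 1
  if (k < 1) abort_fmt("need >= 2 timepoints for contrasts")
  C <- matrix(0, p, k, dimnames = list(coef_names, character(k)))
  for (j in seq_len(k)) {
    ref <- if (scheme == "phase") tp_levels[j] else tp_levels[1]
    num <- tp_levels[j + 1]
    C[paste0("timepoint", num), j] <- 1
    C[paste0("timepoint", ref), j] <- -1
    colnames(C)[j] <- paste0(num, "-", ref)
  }
  C
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Shrinks per-feature residual variances towards a common prior by
#' modelling `s_g^2 ~ s0^2 * chisq_d / d` with an inverse-chi-square prior of
#' `d0` degrees of freedom on the true variances. The prior parameters are
#' estimated by moment matching on `e_g = log s_g^2 - psi(d/2) + log(d/2)`:
#' `trigamma(d0/2) = max(var(e) - trigamma(d/2), eps)` is solved by numerical
#' trigamma inversion, and `s0^2 = exp(mean(e) + psi(d0/2) - log(d0/2))`.
#' The posterior variance `s~^2 = (d0 s0^2 + d s^2)/(d0 + d)` replaces `s^2`
#' in t- and F-statistics, whose degrees of freedom become `d0 + d`. A
#' non-positive moment estimate gives `d0 = Inf` (all posterior variances
#' equal `s0^2`); `d0` may be forced (e.g. `d0 = 0` gives ordinary
#' statistics).
#'
#' @param fits a `feature_fits`.
#' @param d0,s02 optional prior overrides; estimated when `NULL`.
#' @return object of class `moderated_stats`: `table` (tibble with
#'   coefficients, moderated t and F, raw and BH-adjusted p per contrast),
#'   `d0`, `s02`, `s2_post`, `df_residual`, `df_total`.
#' @export
empirical_bayes_moderation <- function(fits, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(fits, "feature_fits"))
  s2 <- fits$sigma2
  d <- fits$df_residual
  if (length(s2) < 2) abort_fmt("need >= 2 features to estimate the variance prior")
  if (d <= 0) abort_fmt("no residual degrees of freedom")

  ok <- is.finite(s2) & s2 > 0
  if (is.null(d0) || is.null(s02)) {
    e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
    ebar <- mean(e)
    evar <- stats::var(e)            # sample variance, n/(n-1) factor included
    rhs <- evar - trigamma(d / 2)
    if (!is.finite(rhs) || rhs <= 1e-10) {
      est_d0 <- Inf
      est_s02 <- mean(s2[ok])   # point-mass prior: moment estimate is the mean
    } else {
      est_d0 <- 2 * trigamma_inverse(rhs)
      est_s02 <- exp(ebar + digamma(est_d0 / 2) - log(est_d0 / 2))
    }
    if (is.null(d0)) d0 <- est_d0
    if (is.null(s02)) s02 <- est_s02
  }

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else (d0 * s02 + d * s2) / (d0 + d)
  names(s2_post) <- names(s2)
  # total df capped at the pooled residual df: shrinkage cannot borrow more
  # information than the whole ensemble carries
  df_total <- min(d0 + d, d * length(s2))

  B <- fits$coefficients
  k <- ncol(B)
  tstat <- sweep(B, 2, fits$stdev_unscaled, `/`) / sqrt(s2_post)
  pt2 <- 2 * stats::pt(-abs(tstat), df = df_total)

  # moderated F over the contrast set via the contrast covariance
  Ri <- solve(chol(fits$cov_unscaled))
  Bw <- B %*% Ri                                     # whitened coefficients
  Fstat <- rowSums(Bw^2) / (k * s2_post)
  pF <- stats::pf(Fstat, k, df_total, lower.tail = FALSE)

  tab <- tibble::tibble(feature = rownames(B))
  for (j in seq_len(k)) {
    cn <- colnames(B)[j]
    tab[[paste0("coef_", cn)]] <- unname(B[, j])
    tab[[paste0("t_", cn)]] <- unname(tstat[, j])
    tab[[paste0("p_", cn)]] <- unname(pt2[, j])
    tab[[paste0("adj_p_", cn)]] <- adjust_bh(unname(pt2[, j]))
  }
  tab$F <- unname(Fstat)
  tab$p_F <- unname(pF)
  tab$adj_p_F <- adjust_bh(unname(pF))
  tab$s2 <- unname(s2)
  tab$s2_post <- unname(s2_post)

  structure(list(table = tab, d0 = d0, s02 = s02, s2_post = s2_post,
                 df_residual = d, df_total = df_total,
                 contrast_scheme = fits$contrast_scheme),
            class = "moderated_stats")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p-values ascending, multiplies `p_(i)` by `m/i`, takes the
#' cumulative minimum from the largest rank down, caps at 1 and restores the
#' input order. Missing p-values propagate as missing and do not count
#' towards `m`. Output is invariant to the input order and monotone
#' non-decreasing in raw-p order.
#'
#' @param pvalues numeric vector in [0, 1] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort_fmt("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  ok <- which(!is.na(pvalues))
  m <- length(ok)
  if (m == 0) return(out)
  p <- pvalues[ok]
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  out[ok][o] <- adj
  out
}

#' Pairwise two-sample tests with permutation-based FDR
#'
#' Welch t-statistics per feature between two timepoints, with the null
#' distribution taken from group-label permutations (unpaired mode) or
#' within-participant sign flips (paired mode). The permutation set is
#' exhaustive when the number of distinct relabelings is at most
#' `20 * n_perm`, otherwise `n_perm` distinct relabelings are sampled
#' without replacement. The estimated FDR at threshold c is
#' `mean_perm #\{|t_null| >= c\} / max(1, #\{|t_obs| >= c\})`; each
#' feature's q-value is the minimum estimated FDR over thresholds at or
#' below its own |t|, clipped to [0, 1] (monotone non-increasing in |t|).
#'
#' @param matrix complete features x samples matrix (a `norm_matrix` is
#'   accepted).
#' @param design design tibble.
#' @param comparison length-2 character: (timepoint A, timepoint B); the
#'   observed t is A minus B.
#' @param n_perm permutations requested when sampling.
#' @param seed RNG seed for sampled relabelings.
#' @param mode "unpaired" (label permutations) or "paired" (sign flips of
#'   within-participant differences).
#' @return object of class `perm_fdr`: `table` (feature, t, q), `n_perm`
#'   (permutations used), `exhaustive`, `comparison`, `mode`.
#' @export
pairwise_permutation_fdr <- function(matrix, design, comparison,
                                     n_perm = 1000, seed = 1L,
                                     mode = c("unpaired", "paired")) {
  mode <- match.arg(mode)
  Y <- if (inherits(matrix, "norm_matrix")) matrix$values else matrix
  if (anyNA(Y)) abort_fmt("permutation tests need a complete matrix")
  stopifnot(length(comparison) == 2)
  d <- design[match(colnames(Y), design$sample), , drop = FALSE]

  if (mode == "unpaired") {
    idx <- which(as.character(d$timepoint) %in% comparison)
    g <- as.character(d$timepoint)[idx]
    Y2 <- Y[, idx, drop = FALSE]
    n1 <- sum(g == comparison[1])
    n2 <- sum(g == comparison[2])
    if (n1 < 3 || n2 < 3) abort_fmt("need >= 3 samples per group")
    n <- n1 + n2
    n_distinct <- choose(n, n1)
    exhaustive <- n_distinct <= 20 * n_perm
    combos <- if (exhaustive) {
      utils::combn(n, n1, simplify = FALSE)
    } else {
      sample_combinations(n, n1, n_perm, seed)
    }
    t_of <- function(sel) welch_t(Y2[, sel, drop = FALSE],
                                  Y2[, -sel, drop = FALSE])
    t_obs <- t_of(which(g == comparison[1]))
    t_null <- vapply(combos, t_of, numeric(nrow(Y2)))
    n_used <- length(combos)
  } else {
    # paired: within-participant differences, null by sign flips
    dA <- d[as.character(d$timepoint) == comparison[1], ]
    dB <- d[as.character(d$timepoint) == comparison[2], ]
    common <- intersect(dA$participant, dB$participant)
    if (length(common) < 3) abort_fmt("need >= 3 paired participants")
    D <- Y[, dA$sample[match(common, dA$participant)], drop = FALSE] -
      Y[, dB$sample[match(common, dB$participant)], drop = FALSE]
    np <- length(common)
    n_distinct <- 2^np
    exhaustive <- n_distinct <= 20 * n_perm
    signs <- if (exhaustive) {
      as.matrix(expand.grid(rep(list(c(1, -1)), np)))
    } else {
      set.seed(seed)
      unique_rows(matrix(sample(c(1, -1), np * n_perm * 1.2, replace = TRUE),
                         ncol = np), n_perm)
    }
    t_of <- function(sg) {
      Ds <- sweep(D, 2, sg, `*`)
      mns <- rowMeans(Ds)
      se <- sqrt(apply(Ds, 1, stats::var) / np)
      mns / se
    }
    t_obs <- t_of(rep(1, np))
    t_null <- apply(signs, 1, t_of)
    n_used <- nrow(signs)
  }
  if (!exhaustive && n_used < n_perm) {
    warn_fmt("only %d distinct relabelings available; using all", n_used)
  }

  abs_obs <- abs(t_obs)
  ord <- order(abs_obs, decreasing = TRUE)
  thr <- abs_obs[ord]
  obs_count <- seq_along(thr)                     # #{|t_obs| >= thr_i}
  null_sorted <- sort(abs(as.numeric(t_null)))
  null_ge <- length(null_sorted) -
    findInterval(thr - 1e-12, null_sorted)        # >= with tolerance
  fdr_at <- (null_ge / n_used) / pmax(1, obs_count)
  # q_i = min over thresholds c <= |t_(i)| of FDR(c): with thresholds sorted
  # descending this is a suffix minimum, monotone non-increasing in |t|
  q_sorted <- pmin(1, rev(cummin(rev(fdr_at))))
  q <- numeric(length(thr))
  q[ord] <- q_sorted

  structure(list(
    table = tibble::tibble(feature = rownames(Y), t = unname(t_obs), q = q),
    n_perm = n_used, exhaustive = exhaustive,
    comparison = comparison, mode = mode
  ), class = "perm_fdr")
}

welch_t <- function(A, B) {
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1)
  v2 <- rowSums((B - m2)^2) / (n2 - 1)
  (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
}

sample_combinations <- function(n, n1, n_perm, seed) {
  set.seed(seed)
  seen <- new.env(hash = TRUE)
  out <- vector("list", n_perm)
  got <- 0
  tries <- 0
  while (got < n_perm && tries < 50 * n_perm) {
    tries <- tries + 1
    sel <- sort(sample.int(n, n1))
    key <- paste(sel, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1
      out[[got]] <- sel
    }
  }
  out[seq_len(got)]
}

unique_rows <- function(m, n_max) {
  m <- m[!duplicated(m), , drop = FALSE]
  m[seq_len(min(nrow(m), n_max)), , drop = FALSE]
}

#' Two-tier differential feature sets
#'
#' The global set holds features whose BH-adjusted moderated-F p-value falls
#' below `alpha_global`; each pairwise set holds features below
#' `alpha_pairwise` on the permutation q-value *and* in the global set (the
#' conservative intersection).
#'
#' @param stats a `moderated_stats`.
#' @param perm a `perm_fdr` or a (named) list of them.
#' @param alpha_global,alpha_pairwise thresholds in (0, 1).
#' @return list with `global` (character vector), `per_comparison` (named
#'   list), and `provenance`.
#' @export
differential_features <- function(stats, perm = NULL,
                                  alpha_global = 0.01, alpha_pairwise = 0.05) {
  if (!(alpha_global > 0 && alpha_global < 1) ||
      !(alpha_pairwise > 0 && alpha_pairwise < 1)) {
    abort_fmt("alpha thresholds must lie in (0, 1)")
  }
  tab <- stats$table
  global <- tab$feature[!is.na(tab$adj_p_F) & tab$adj_p_F < alpha_global]
  per <- list()
  if (!is.null(perm)) {
    if (inherits(perm, "perm_fdr")) perm <- list(perm)
    for (p in perm) {
      nm <- paste(p$comparison, collapse = "-")
      hits <- p$table$feature[p$table$q < alpha_pairwise]
      per[[nm]] <- intersect(hits, global)
    }
  }
  list(global = global, per_comparison = per,
       provenance = list(alpha_global = alpha_global,
                         alpha_pairwise = alpha_pairwise,
                         n_global = length(global)))
}
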