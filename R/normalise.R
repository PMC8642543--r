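#' Mitochondrial protein enrichment (MPE) per sample
#'
#' MPE is the percent of a sample's summed raw intensity contributed by
#' annotated mitochondrial proteins:
#' `MPE_s = 100 * sum(raw, mito) / sum(raw, all)`. It proxies the purity of
#' the mitochondrial isolate and, over timepoints, the global change in
#' mitochondrial content. It is computed on the full, unfiltered matrix of
#' raw intensities with missing values contributing zero to the sums.
#'
#' @param matrix features x samples raw intensity matrix (`NA` = missing) or
#'   a `protein_data` object (its `raw` slot is used).
#' @param annotation annotation tibble (`feature`, `confidence`).
#' @param level confidence tier(s) counted as mitochondrial; default the
#'   highest-confidence "Known Mitochondrial" tier, or "Known+Predicted".
#' @return tibble with `sample`, `mpe` (percent), `level`, `column_type`.
#' @export
compute_mpe <- function(matrix, annotation, level = "Known Mitochondrial") {
  m <- if (inherits(matrix, "protein_data")) matrix$raw else matrix
  levels_used <- resolve_confidence_level(level)
  mito_ids <- annotation$feature[annotation$confidence %in% levels_used]
  mito <- rownames(m) %in% mito_ids
  if (!any(mito)) abort_fmt("no feature in the matrix is annotated at level '%s'", level)
  m0 <- m
  m0[is.na(m0)] <- 0
  tot <- colSums(m0)
  if (any(tot <= 0)) {
    abort_fmt("sample(s) with zero total intensity: %s",
              paste(colnames(m)[tot <= 0], collapse = ", "))
  }
  tibble::tibble(
    sample = colnames(m),
    mpe = unname(100 * colSums(m0[mito, , drop = FALSE]) / tot),
    level = paste(levels_used, collapse = "+"),
    column_type = "raw")
}

resolve_confidence_level <- function(level) {
  if (identical(level, "Known+Predicted")) {
    c("Known Mitochondrial", "Predicted Mitochondrial")
  } else {
    bad <- setdiff(level, CONFIDENCE_LEVELS)
    if (length(bad) > 0) abort_fmt("unknown confidence level(s): %s", paste(bad, collapse = ", "))
    level
  }
}

#' Remove features with too few valid values
#'
#' Retains features observed in at least `min_fraction` of samples. The
#' boundary is inclusive: a feature observed in exactly 70% of samples is
#' kept, since removal applies to features with strictly fewer valid values.
#'
#' @param matrix features x samples matrix (`NA` = missing).
#' @param min_fraction minimum fraction of valid values, in (0, 1].
#' @return the filtered matrix; number removed reported via message.
#' @export
filter_valid_values <- function(matrix, min_fraction = 0.70) {
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    abort_fmt("min_fraction must lie in (0, 1]")
  }
  frac <- rowMeans(!is.na(matrix))
  keep <- frac >= min_fraction
  message(sum(!keep), " feature(s) removed with < ", round(100 * min_fraction, 1),
          "% valid values; ", sum(keep), " retained")
  matrix[keep, , drop = FALSE]
}

#' Subset to annotated mitochondrial features
#'
#' @param matrix features x samples matrix.
#' @param annotation annotation tibble.
#' @param level confidence tier(s); see [compute_mpe()].
#' @return matrix restricted to features annotated at the requested level.
#' @export
subset_mitochondrial <- function(matrix, annotation, level = "Known Mitochondrial") {
  levels_used <- resolve_confidence_level(level)
  ids <- annotation$feature[annotation$confidence %in% levels_used]
  keep <- rownames(matrix) %in% ids
  if (!any(keep)) abort_fmt("no feature at confidence level '%s' in the matrix", level)
  message(sum(keep), " feature(s) retained at level '", paste(levels_used, collapse = "+"), "'")
  matrix[keep, , drop = FALSE]
}

#' Variance-stabilising generalised-log calibration
#'
#' Fits, per sample, an affine calibration inside a generalised log:
#' `h_s(x) = glog2(a_s + b_s * x) - offset`, choosing `(a_s, b_s)` to make
#' features homoskedastic across samples. The fit maximises a
#' normal-errors profile likelihood on the transformed scale that includes
#' the transformation Jacobian (without it the criterion would collapse all
#' samples to a point), alternating row-mean estimation with per-sample
#' parameter updates, and is made resistant by least-trimmed-squares row
#' trimming: only the `lts_quantile` fraction of features with the smallest
#' squared residuals enter the fit, so a minority of genuinely changing
#' features cannot drag the calibration.
#'
#' The output scale is anchored so that the sample with the median fitted
#' scale factor satisfies `h(x) -> log2(x)` for large `x`; values therefore
#' read as calibrated log2 intensities.
#'
#' @param matrix features x samples positive intensity matrix (`NA` allowed;
#'   fitted on observed entries).
#' @param lts_quantile fraction of features kept in the trimmed fit.
#' @param maxit maximum outer iterations.
#' @param tol relative objective-change convergence tolerance.
#' @return object of class `norm_matrix`: `values` (transformed matrix),
#'   `a`, `b`, `offset`, `iterations`, `converged`, `imputed` (all-FALSE mask
#'   until [impute_left_censored()] fills it).
#' @export
vsn_transform <- function(matrix, lts_quantile = 0.9, maxit = 400, tol = 1e-10,
                          lts_rounds = 3) {
  if (ncol(matrix) < 2) abort_fmt("variance calibration needs >= 2 samples")
  if (any(matrix <= 0, na.rm = TRUE)) abort_fmt("intensities must be positive")
  n_s <- ncol(matrix)
  n_g <- nrow(matrix)
  obs <- !is.na(matrix)
  ln2 <- log(2)

  # init: bring every column to a common median on the raw scale
  med <- apply(matrix, 2, stats::median, na.rm = TRUE)
  par <- c(rep(0, n_s), log(1 / med))

  # profile negative log-likelihood over a fixed set of used entries: the row
  # means are profiled out exactly, so their dependence on (a, b) drops from
  # the gradient (envelope theorem); the Jacobian term prevents the collapse
  # b -> 0 that plain variance minimisation would choose
  make_obj <- function(use) {
    n_use <- sum(use)
    col_n <- colSums(use)
    nll <- function(par) {
      a <- par[seq_len(n_s)]
      b <- exp(par[n_s + seq_len(n_s)])
      z <- sweep(sweep(matrix, 2, b, `*`), 2, a, `+`)
      h <- glog2(z)
      h[!use] <- NA
      mu <- rowMeans(h, na.rm = TRUE)
      r <- h - mu
      rss <- max(sum(r[use]^2), 1e-300)
      (n_use / 2) * log(rss) + sum(0.5 * log(z[use]^2 + 1)) -
        sum(col_n * (par[n_s + seq_len(n_s)]))
    }
    grad <- function(par) {
      a <- par[seq_len(n_s)]
      b <- exp(par[n_s + seq_len(n_s)])
      z <- sweep(sweep(matrix, 2, b, `*`), 2, a, `+`)
      u2 <- z^2 + 1
      h <- log2(z + sqrt(u2)) - 1
      h[!use] <- NA
      mu <- rowMeans(h, na.rm = TRUE)
      r <- h - mu
      r[!use] <- 0
      rss <- max(sum(r^2), 1e-300)
      dh <- 1 / (ln2 * sqrt(u2))
      ddata <- (n_use / rss) * r * dh
      djac <- z / u2
      g_total <- ddata + djac
      g_total[!use] <- 0
      z[!use] <- 0   # masked entries must not contribute to the chain rule
      ga <- colSums(g_total)
      glb <- colSums(g_total * sweep(z, 2, a, `-`)) - col_n
      c(ga, glb)
    }
    list(nll = nll, grad = grad)
  }

  use <- obs
  fit <- NULL
  n_evals <- 0
  for (round in seq_len(lts_rounds)) {
    o <- make_obj(use)
    fit <- stats::optim(par, o$nll, o$grad, method = "BFGS",
                        control = list(maxit = maxit, reltol = tol))
    par <- fit$par
    n_evals <- n_evals + unname(fit$counts["function"])
    if (round < lts_rounds && lts_quantile < 1) {
      a <- par[seq_len(n_s)]
      b <- exp(par[n_s + seq_len(n_s)])
      h <- glog2(sweep(sweep(matrix, 2, b, `*`), 2, a, `+`))
      h[!obs] <- NA
      r2 <- (h - rowMeans(h, na.rm = TRUE))^2
      row_ms <- rowSums(r2, na.rm = TRUE) / pmax(rowSums(obs), 1)
      keep_rows <- row_ms <= stats::quantile(row_ms, lts_quantile, names = FALSE)
      use <- obs & matrix(keep_rows, n_g, n_s)
    }
  }
  converged <- fit$convergence == 0
  a <- par[seq_len(n_s)]
  b <- exp(par[n_s + seq_len(n_s)])
  if (!converged) {
    cond <- simpleError(sprintf(
      "variance calibration did not converge within %d iterations (objective %.6g)",
      maxit, fit$value))
    cond$diagnostics <- list(a = a, b = b, counts = fit$counts)
    stop(cond)
  }
  if (any(b <= 0)) abort_fmt("non-positive fitted scale factor")
  it <- n_evals
  h_of <- function(a, b) glog2(sweep(sweep(matrix, 2, b, `*`), 2, a, `+`))

  offset <- log2(b[order(b)[ceiling(n_s / 2)]])  # anchor: median-scale sample -> log2
  values <- h_of(a, b) - offset
  structure(list(
    values = values,
    a = stats::setNames(a, colnames(matrix)),
    b = stats::setNames(b, colnames(matrix)),
    offset = offset, iterations = it, converged = converged,
    lts_quantile = lts_quantile,
    imputed = matrix(FALSE, nrow(matrix), ncol(matrix), dimnames = dimnames(matrix))
  ), class = "norm_matrix")
}

#' Impute left-censored missing values from the lower tail
#'
#' Quantile-regression imputation of left-censored data: per sample, the
#' observed order statistics are treated as the upper portion of a normal
#' distribution whose low tail was censored. Assigning observed rank i (of
#' n_obs observed among N total values) the plotting position
#' `p_i = (n_missing + i - 0.375) / (N + 0.25)`, the mean and sd of the
#' underlying complete distribution are estimated by least squares of the
#' observed values on `qnorm(p_i)` over the uncensored quantile range
#' (default 0.25-1.0). Missing entries are then drawn from that normal
#' truncated above at the sample's observed minimum, so imputed values land
#' in the censored tail. Deterministic under a fixed seed.
#'
#' @param matrix a `norm_matrix` (transformed scale) or plain matrix with
#'   `NA` for missing.
#' @param seed integer RNG seed.
#' @param quantile_range quantile interval of the complete distribution used
#'   in the regression.
#' @return same class as the input with missing entries filled and the
#'   imputation mask recorded (`imputed` element for `norm_matrix`,
#'   `"imputed"` attribute for plain matrices).
#' @export
impute_left_censored <- function(matrix, seed = 1L, quantile_range = c(0.25, 1.0)) {
  is_nm <- inherits(matrix, "norm_matrix")
  vals <- if (is_nm) matrix$values else matrix
  mask <- is.na(vals)
  if (!any(mask)) {
    if (is_nm) return(matrix)
    attr(vals, "imputed") <- mask
    return(vals)
  }
  set.seed(seed)
  for (s in seq_len(ncol(vals))) {
    mis <- mask[, s]
    if (!any(mis)) next
    y <- sort(vals[!mis, s])
    n_obs <- length(y)
    if (n_obs < 10) {
      abort_fmt("sample '%s' has only %d observed values; too few to fit the tail",
                colnames(vals)[s], n_obs)
    }
    n_mis <- sum(mis)
    N <- n_obs + n_mis
    p <- (n_mis + seq_len(n_obs) - 0.375) / (N + 0.25)
    use <- p >= quantile_range[1] & p < quantile_range[2]
    q <- stats::qnorm(p[use])
    fit <- stats::lm.fit(cbind(1, q), y[use])
    mu <- fit$coefficients[1]
    sigma <- fit$coefficients[2]
    if (!is.finite(sigma) || sigma <= 0) {
      warn_fmt("sample '%s': non-positive tail-fit sd, falling back to observed sd",
               colnames(vals)[s])
      sigma <- stats::sd(y)
    }
    p_top <- stats::pnorm((min(y) - mu) / sigma)
    u <- stats::runif(n_mis, 0, p_top)
    vals[mis, s] <- mu + sigma * stats::qnorm(pmax(u, .Machine$double.xmin))
  }
  if (is_nm) {
    matrix$values <- vals
    matrix$imputed <- mask
    matrix
  } else {
    attr(vals, "imputed") <- mask
    vals
  }
}

#' Normalise lipid species by a per-sample anchor-class total
#'
#' Divides every species by the sample's summed concentration of the anchor
#' class (cardiolipin by default, the mitochondria-specific lipid class that
#' tracks mitochondrial content), then rescales by the cohort-mean anchor
#' total so values keep their original units. After normalisation the
#' per-sample anchor totals are identical across samples, and within-sample
#' ratios of any two species are unchanged.
#'
#' @param lipids a `lipid_matrix`.
#' @param anchor_class class label used as the per-sample divisor.
#' @return normalised `lipid_matrix`.
#' @export
normalise_lipids_by_class <- function(lipids, anchor_class = "CL") {
  stopifnot(inherits(lipids, "lipid_matrix"))
  anchor <- lipids$classes == anchor_class
  if (!any(anchor)) abort_fmt("anchor class '%s' not present", anchor_class)
  tot <- colSums(lipids$values[anchor, , drop = FALSE], na.rm = TRUE)
  zero <- tot <= 0
  if (any(zero)) {
    abort_fmt("zero %s total in sample(s): %s", anchor_class,
              paste(colnames(lipids$values)[zero], collapse = ", "))
  }
  scale <- mean(tot) / tot
  lipids$values <- sweep(lipids$values, 2, scale, `*`)
  lipids
}

#' Normalise a scalar marker by a per-sample content scaler
#'
#' Elementwise ratio of a per-sample measurement (for example a band density
#' or a respiration rate) to a per-sample mitochondrial-content scaler (CS
#' activity or MPE). Returns per-sample ratios; any aggregation across
#' samples is the caller's, since the ratio of group means is not the mean
#' of ratios. Units are value-unit per scaler-unit.
#'
#' @param values numeric per-sample measurements.
#' @param scaler numeric per-sample scaler, strictly positive.
#' @return numeric vector of ratios.
#' @export
content_normalise <- function(values, scaler) {
  if (length(values) != length(scaler)) abort_fmt("values and scaler lengths differ")
  if (any(scaler <= 0, na.rm = TRUE)) abort_fmt("scaler must be strictly positive")
  values / scaler
}

#' Run the BESt normalisation chain
#'
#' Fixed-order chain for mitochondrial-isolate proteomics: marker-flagged
#' rows are assumed already removed at ingestion; then valid-value filtering,
#' mitochondrial subsetting, variance-stabilising calibration, and
#' left-censored imputation. `vsn_scope = "all"` fits the calibration on all
#' retained proteins before subsetting instead (exposed as a switch; the
#' default follows subset-then-normalise).
#'
#' @param matrix raw features x samples matrix (`NA` = missing) or
#'   `protein_data` (LFQ slot used when present, else raw).
#' @param annotation annotation tibble.
#' @param min_valid_fraction valid-value threshold.
#' @param level mitochondrial confidence tier.
#' @param vsn_scope "mito" (default) or "all".
#' @param seed seed for the imputation draws.
#' @param lts_quantile trimming fraction passed to [vsn_transform()].
#' @return `norm_matrix` restricted to the mitochondrial subset.
#' @export
best_normalise <- function(matrix, annotation, min_valid_fraction = 0.70,
                           level = "Known Mitochondrial", vsn_scope = c("mito", "all"),
                           seed = 1L, lts_quantile = 0.9) {
  vsn_scope <- match.arg(vsn_scope)
  m <- if (inherits(matrix, "protein_data")) (matrix$lfq %||% matrix$raw) else matrix
  m <- filter_valid_values(m, min_valid_fraction)
  if (vsn_scope == "mito") {
    m <- subset_mitochondrial(m, annotation, level)
    nm <- vsn_transform(m, lts_quantile = lts_quantile)
  } else {
    nm <- vsn_transform(m, lts_quantile = lts_quantile)
    keep <- rownames(nm$values) %in%
      annotation$feature[annotation$confidence %in% resolve_confidence_level(level)]
    if (!any(keep)) abort_fmt("no mitochondrial feature left after filtering")
    nm$values <- nm$values[keep, , drop = FALSE]
    nm$imputed <- nm$imputed[keep, , drop = FALSE]
  }
  impute_left_censored(nm, seed = seed)
}
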