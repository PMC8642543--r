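sim_matrix <- function(n_features, design, sd = 1, seed = 1, shift = NULL) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_features * nrow(design), 20, sd),
              n_features, nrow(design),
              dimnames = list(sprintf("f%04d", seq_len(n_features)), design$sample))
  if (!is.null(shift)) {
    for (tp in names(shift)) {
      cols <- design$sample[as.character(design$timepoint) == tp]
      m[, cols] <- m[, cols] + shift[[tp]]
    }
  }
  m
}

test_that("paired two-timepoint design: contrast equals mean within-participant difference", {
  d <- make_design(5, c("BL", "PN"))
  m <- sim_matrix(10, d, seed = 2)
  fits <- fit_linear_models(m, d, "phase")
  diffs <- m[, d$sample[d$timepoint == "PN"]] - m[, d$sample[d$timepoint == "BL"]]
  expect_equal(unname(fits$coefficients[, "PN-BL"]), unname(rowMeans(diffs)),
               tolerance = 1e-12)
})

test_that("a constant added to one participant's samples changes no contrast", {
  d <- make_design(4)
  m <- sim_matrix(8, d, seed = 3)
  fits0 <- fit_linear_models(m, d, "phase")
  m2 <- m
  m2[, d$sample[d$participant == "P02"]] <- m2[, d$sample[d$participant == "P02"]] + 5
  fits1 <- fit_linear_models(m2, d, "phase")
  expect_equal(fits0$coefficients, fits1$coefficients, tolerance = 1e-10)
})

test_that("coefficients match an explicit normal-equations solve", {
  d <- make_design(3)
  m <- sim_matrix(6, d, seed = 4)
  for (scheme in c("phase", "vs_baseline")) {
    fits <- fit_linear_models(m, d, scheme)
    dat <- data.frame(timepoint = factor(as.character(d$timepoint),
                                         levels = levels(d$timepoint)),
                      participant = factor(d$participant))
    X <- stats::model.matrix(~ 0 + timepoint + participant, dat)
    XtXi <- solve(t(X) %*% X)
    for (g in seq_len(nrow(m))) {
      beta <- XtXi %*% t(X) %*% m[g, ]
      expect_equal(unname(fits$coefficients[g, ]),
                   unname(as.numeric(t(fits$contrasts) %*% beta)),
                   tolerance = 1e-10)
    }
  }
})

test_that("rank-deficient designs raise an error naming the aliased terms", {
  d <- make_design(3, c("BL", "PN"))
  d$participant <- d$timepoint   # participant aliased with timepoint
  m <- sim_matrix(4, d, seed = 5)
  expect_error(fit_linear_models(m, d), "aliased")
})

test_that("moderated statistics agree with the limma oracle", {
  skip_if_not_installed("limma")
  d <- make_design(5)
  set.seed(6)
  sds <- sqrt(0.25 * 4 / stats::rchisq(80, 4))   # heterogeneous true variances
  m <- matrix(stats::rnorm(80 * nrow(d), 20, rep(sds, nrow(d))), 80, nrow(d),
              dimnames = list(sprintf("f%04d", 1:80), d$sample))
  cols_ph <- d$sample[d$timepoint == "PH"]
  m[, cols_ph] <- m[, cols_ph] + 0.4
  fits <- fit_linear_models(m, d, "vs_baseline")
  st <- empirical_bayes_moderation(fits)

  dat <- data.frame(timepoint = factor(as.character(d$timepoint),
                                       levels = levels(d$timepoint)),
                    participant = factor(d$participant))
  X <- stats::model.matrix(~ 0 + timepoint + participant, dat)
  lfit <- limma::lmFit(m, X)
  cm <- matrix(0, ncol(X), 3,
               dimnames = list(colnames(X), c("PN-BL", "PH-BL", "PR-BL")))
  cm["timepointPN", 1] <- cm["timepointPH", 2] <- cm["timepointPR", 3] <- 1
  cm["timepointBL", ] <- -1
  lfit <- limma::contrasts.fit(lfit, cm)
  lfit <- limma::eBayes(lfit)

  expect_equal(unname(fits$coefficients), unname(lfit$coefficients), tolerance = 1e-10)
  expect_equal(unname(fits$sigma2), unname(lfit$sigma^2), tolerance = 1e-10)
  expect_equal(st$d0, lfit$df.prior, tolerance = 1e-4)
  expect_equal(st$s02, lfit$s2.prior, tolerance = 1e-4)
  expect_equal(unname(as.matrix(st$table[, c("t_PN-BL", "t_PH-BL", "t_PR-BL")])),
               unname(lfit$t), tolerance = 1e-6)
  expect_equal(st$table$F, unname(lfit$F), tolerance = 1e-6)
  expect_equal(st$table$p_F, unname(lfit$F.p.value), tolerance = 1e-6)
})

test_that("d0 = 0 gives ordinary t-statistics; equal variances give the d0 = Inf branch", {
  d <- make_design(4)
  m <- sim_matrix(30, d, seed = 7)
  fits <- fit_linear_models(m, d)
  st0 <- empirical_bayes_moderation(fits, d0 = 0)
  ord_t <- sweep(fits$coefficients, 2, fits$stdev_unscaled, `/`) / sqrt(fits$sigma2)
  expect_equal(unname(as.matrix(st0$table[, paste0("t_", colnames(fits$coefficients))])),
               unname(ord_t), tolerance = 1e-12)
  expect_equal(st0$table$s2_post, unname(fits$sigma2))

  # identical residual variances: moment estimate collapses to d0 = Inf
  m_const <- m
  fits_c <- fit_linear_models(m_const, d)
  fits_c$sigma2[] <- 2.5
  st_inf <- empirical_bayes_moderation(fits_c)
  expect_identical(st_inf$d0, Inf)
  expect_true(all(abs(st_inf$table$s2_post - 2.5) < 1e-12))
})

test_that("variance prior parameters are recovered from simulated variances", {
  set.seed(12)
  n <- 5000; d0 <- 4; s02 <- 2; d <- 10
  true_var <- d0 * s02 / stats::rchisq(n, d0)
  s2 <- true_var * stats::rchisq(n, d) / d
  fits <- structure(list(
    coefficients = matrix(0, n, 1, dimnames = list(sprintf("f%d", 1:n), "PN-BL")),
    cov_unscaled = matrix(0.2, 1, 1), stdev_unscaled = sqrt(0.2),
    sigma2 = s2, df_residual = d, contrasts = matrix(1),
    contrast_scheme = "phase"), class = "feature_fits")
  st <- empirical_bayes_moderation(fits)
  expect_lt(abs(st$d0 - d0) / d0, 0.25)
  expect_lt(abs(st$s02 - s02) / s02, 0.10)
})

test_that("moderated F with a single contrast equals the squared moderated t", {
  d <- make_design(4, c("BL", "PN"))
  m <- sim_matrix(25, d, seed = 8)
  st <- empirical_bayes_moderation(fit_linear_models(m, d))
  expect_equal(st$table$F, st$table$`t_PN-BL`^2, tolerance = 1e-10)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(adjust_bh(c(0.005, 0.01, 0.03, 0.04)), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))

  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) adj[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
    adj
  }
  set.seed(20)
  for (rep in 1:25) {
    p <- stats::runif(40)^sample(c(1, 3), 1)
    expect_equal(adjust_bh(p), brute_bh(p), tolerance = 1e-14)
    expect_equal(adjust_bh(p), stats::p.adjust(p, "BH"), tolerance = 1e-14)
  }
  # missing values propagate and do not count towards m
  p <- c(0.01, NA, 0.04)
  expect_equal(adjust_bh(p), c(0.02, NA, 0.04))
  # permutation equivariance
  p <- stats::runif(30)
  perm <- sample(30)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
})

test_that("3 vs 3 permutation q-values equal full enumeration", {
  d <- make_design(3, c("BL", "PN"))
  m <- sim_matrix(12, d, seed = 9, shift = list(PN = 1.5))
  m[7:12, ] <- sim_matrix(6, d, seed = 10)   # half null features
  res <- pairwise_permutation_fdr(m, d, c("PN", "BL"), n_perm = 1000, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, choose(6, 3))

  # independent oracle: enumerate every relabeling with t.test
  idx <- which(as.character(d$timepoint) %in% c("PN", "BL"))
  g <- as.character(d$timepoint)[idx]
  Y <- m[, idx]
  combos <- utils::combn(6, 3, simplify = FALSE)
  t_for <- function(sel) {
    apply(Y, 1, function(y) unname(stats::t.test(y[sel], y[-sel])$statistic))
  }
  t_obs <- t_for(which(g == "PN"))
  t_null <- sapply(combos, t_for)
  q_oracle <- vapply(seq_len(nrow(Y)), function(gi) {
    cands <- abs(t_obs)[abs(t_obs) <= abs(t_obs[gi])]
    min(vapply(cands, function(c0) {
      mean(colSums(abs(t_null) >= c0 - 1e-12)) / max(1, sum(abs(t_obs) >= c0 - 1e-12))
    }, numeric(1)), 1)
  }, numeric(1))
  expect_equal(res$table$t, unname(t_obs), tolerance = 1e-10)
  expect_equal(res$table$q, pmin(q_oracle, 1), tolerance = 1e-10)
})

test_that("permutation FDR controls the null call rate on pure-noise data", {
  d <- make_design(4, c("BL", "PN"))
  props <- vapply(1:10, function(sd) {
    m <- sim_matrix(300, d, seed = 100 + sd)
    res <- pairwise_permutation_fdr(m, d, c("PN", "BL"), n_perm = 200, seed = sd)
    mean(res$table$q <= 0.05)
  }, numeric(1))
  bsd <- sqrt(0.05 * 0.95 / 300)
  expect_true(mean(props) <= 0.05 + 2 * bsd)
})

test_that("the Welch statistic is scale free: rescaling all values leaves t unchanged", {
  d <- make_design(3, c("BL", "PN"))
  m <- sim_matrix(10, d, seed = 11, shift = list(PN = 0.8))
  r1 <- pairwise_permutation_fdr(m, d, c("PN", "BL"), n_perm = 50, seed = 1)
  r2 <- pairwise_permutation_fdr(m * 7.3, d, c("PN", "BL"), n_perm = 50, seed = 1)
  expect_equal(r2$table$t, r1$table$t, tolerance = 1e-12)
  expect_equal(r2$table$q, r1$table$q, tolerance = 1e-12)
})

test_that("paired mode uses within-participant sign flips", {
  d <- make_design(4, c("BL", "PN"))
  m <- sim_matrix(15, d, seed = 12, shift = list(PN = 1))
  res <- pairwise_permutation_fdr(m, d, c("PN", "BL"), n_perm = 1000, seed = 1,
                                  mode = "paired")
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 2^4)
  diffs <- m[, d$sample[d$timepoint == "PN"]] - m[, d$sample[d$timepoint == "BL"]]
  t_paired <- apply(diffs, 1, function(x) mean(x) / (stats::sd(x) / sqrt(length(x))))
  expect_equal(res$table$t, unname(t_paired), tolerance = 1e-12)
})

test_that("two-tier differential sets intersect the pairwise calls with the global set", {
  d <- make_design(5)
  m <- sim_matrix(60, d, seed = 13, shift = list(PN = 0, PH = 1.2, PR = 1.2))
  m[31:60, ] <- sim_matrix(30, d, seed = 14)
  st <- empirical_bayes_moderation(fit_linear_models(m, d, "phase"))
  perm <- pairwise_permutation_fdr(m, d, c("PH", "BL"), n_perm = 200, seed = 2)
  sets <- differential_features(st, perm, 0.01, 0.05)
  expect_true(all(sets$per_comparison[["PH-BL"]] %in% sets$global))

  # alpha_global = 1 - eps: pairwise sets equal the q-threshold sets
  sets_all <- differential_features(st, perm, 1 - 1e-12, 0.05)
  expect_setequal(sets_all$per_comparison[["PH-BL"]],
                  perm$table$feature[perm$table$q < 0.05])

  # empty global set forces empty pairwise sets
  st2 <- st
  st2$table$adj_p_F <- 1
  sets_none <- differential_features(st2, perm, 0.01, 0.05)
  expect_length(sets_none$global, 0)
  expect_length(sets_none$per_comparison[["PH-BL"]], 0)

  expect_error(differential_features(st, perm, alpha_global = 0), "alpha")
})
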