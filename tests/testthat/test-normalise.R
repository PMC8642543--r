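test_that("MPE is the mitochondrial share of summed raw intensity", {
  ann <- tibble::tibble(feature = c("m1", "m2", "x1"),
                        confidence = c("Known Mitochondrial", "Known Mitochondrial", "none"))
  m <- matrix(c(2, 3, 5, 4, 6, 10), 3, 2,
              dimnames = list(c("m1", "m2", "x1"), c("s1", "s2")))
  mpe <- compute_mpe(m, ann)
  expect_equal(mpe$mpe, c(50, 50))

  # all features mitochondrial: 100% everywhere
  ann2 <- tibble::tibble(feature = rownames(m),
                         confidence = "Known Mitochondrial")
  expect_equal(compute_mpe(m, ann2)$mpe, c(100, 100))

  # missing treated as zero in the sums
  m_na <- m
  m_na["m2", "s1"] <- NA
  expect_equal(compute_mpe(m_na, ann)$mpe[1], 100 * 2 / 7)

  expect_error(compute_mpe(m, ann, level = "nonsense"), "confidence")
  ann3 <- tibble::tibble(feature = "zz", confidence = "Known Mitochondrial")
  expect_error(compute_mpe(m, ann3), "no feature")
})

test_that("valid-value filter keeps the 70% boundary and removes below it", {
  set.seed(1)
  m <- matrix(stats::rlnorm(3 * 40, 14, 1), 3, 40,
              dimnames = list(c("at", "below", "full"), sprintf("s%02d", 1:40)))
  m["at", 1:12] <- NA      # 28/40 = 70.0% observed -> retained
  m["below", 1:13] <- NA   # 27/40 = 67.5% -> removed
  out <- suppressMessages(filter_valid_values(m, 0.70))
  expect_setequal(rownames(out), c("at", "full"))

  complete <- m["full", , drop = FALSE]
  expect_equal(suppressMessages(filter_valid_values(complete)), complete)
  expect_error(filter_valid_values(m, 0), "min_fraction")
  expect_error(filter_valid_values(m, 1.1), "min_fraction")
})

test_that("mitochondrial subsetting respects the confidence tiers", {
  ann <- tibble::tibble(
    feature = sprintf("f%d", 1:10),
    confidence = c(rep("Known Mitochondrial", 3), rep("Predicted Mitochondrial", 2),
                   rep("none", 5)))
  m <- matrix(1, 10, 2, dimnames = list(ann$feature, c("a", "b")))
  expect_equal(nrow(suppressMessages(subset_mitochondrial(m, ann))), 3)
  expect_equal(nrow(suppressMessages(subset_mitochondrial(m, ann, "Known+Predicted"))), 5)
  none_only <- ann[ann$confidence == "none", ]
  expect_error(subset_mitochondrial(m, none_only), "no feature")
})

test_that("filter and subset commute on complete matrices", {
  co <- clean_cohort()
  m <- co$proteins_complete
  a <- suppressMessages(subset_mitochondrial(filter_valid_values(m), co$annotation))
  b <- suppressMessages(filter_valid_values(subset_mitochondrial(m, co$annotation)))
  expect_identical(a, b)
})

test_that("variance calibration removes an exact between-sample scale factor", {
  set.seed(7)
  x <- stats::rlnorm(300, 14, 1.5)
  m <- cbind(s1 = x, s2 = 3.7 * x)
  fit <- vsn_transform(m)
  diffs <- fit$values[, 2] - fit$values[, 1]
  expect_lt(stats::sd(diffs), 1e-6)
})

test_that("the fitted transform is strictly increasing and log2-anchored", {
  co <- small_cohort()
  m <- suppressMessages(subset_mitochondrial(
    filter_valid_values(co$proteins), co$annotation))
  fit <- vsn_transform(m)
  expect_true(fit$converged)
  expect_true(all(fit$b > 0))
  # monotonicity: transform preserves the order of raw values within samples
  for (s in c(1, ncol(m))) {
    ok <- !is.na(m[, s])
    expect_identical(order(m[ok, s]), order(fit$values[ok, s]))
  }
  # anchor: for large intensities the median-scale sample reads as log2(x)
  ref <- which(fit$b == sort(fit$b)[ceiling(length(fit$b) / 2)])[1]
  big <- which(m[, ref] > stats::quantile(m[, ref], 0.9, na.rm = TRUE))
  expect_equal(fit$values[big, ref], log2(m[big, ref]), tolerance = 0.02)
})

test_that("calibration flattens the mean-variance trend of the two-component noise model", {
  cfg <- cohort_config(n_participants = 6, n_features = 500, n_lipids = 60,
                       seed = 31, noise = list(cv = 0.2, sd_a = 10),
                       missingness = list(enabled = FALSE))
  co <- generate_cohort(cfg)
  m <- co$proteins_complete
  rel_slope <- function(vals) {
    sds <- apply(vals, 1, stats::sd)
    mns <- rank(rowMeans(vals))
    unname(stats::coef(stats::lm(I(sds / mean(sds)) ~ mns))[2])
  }
  before <- rel_slope(m)
  after <- rel_slope(vsn_transform(m)$values)
  expect_lt(abs(after), 0.1 * abs(before))
})

test_that("variance calibration rejects degenerate input", {
  expect_error(vsn_transform(matrix(1:5, 5, 1)), ">= 2 samples")
  m <- matrix(c(1, -1, 2, 3), 2, 2)
  expect_error(vsn_transform(m), "positive")
})

test_that("left-censored imputation draws in the censored tail, deterministically", {
  co <- small_cohort()
  m <- suppressMessages(subset_mitochondrial(
    filter_valid_values(co$proteins), co$annotation))
  fit <- vsn_transform(m)

  a <- impute_left_censored(fit, seed = 42)
  b <- impute_left_censored(fit, seed = 42)
  expect_identical(a$values, b$values)
  c <- impute_left_censored(fit, seed = 43)
  expect_false(identical(a$values, c$values))
  expect_identical(a$values[!a$imputed], c$values[!c$imputed])
  expect_false(anyNA(a$values))

  # complete input returned unchanged
  expect_identical(impute_left_censored(a, seed = 1), a)
})

test_that("imputed values fall below the observed lower quartile under 20% censoring", {
  set.seed(5)
  m <- matrix(stats::rnorm(400 * 6, 25, 2.5), 400, 6,
              dimnames = list(sprintf("f%03d", 1:400), sprintf("s%d", 1:6)))
  cens <- apply(m, 2, stats::quantile, probs = 0.2)
  mm <- m
  for (s in 1:6) mm[m[, s] < cens[s], s] <- NA
  frac_below <- vapply(1:20, function(sd) {
    out <- impute_left_censored(mm, seed = sd)
    imp <- attr(out, "imputed")
    mean(vapply(1:6, function(s) {
      q25 <- stats::quantile(mm[!imp[, s], s], 0.25, na.rm = TRUE)
      mean(out[imp[, s], s] < q25)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(frac_below >= 0.95))
})

test_that("imputation refuses samples with too few observed values", {
  m <- matrix(stats::rnorm(40, 20, 2), 20, 2,
              dimnames = list(sprintf("f%d", 1:20), c("ok", "sparse")))
  m[1:15, "sparse"] <- NA
  expect_error(impute_left_censored(m, seed = 1), "sparse")
})

test_that("anchor-class lipid normalisation equalises CL totals and preserves ratios", {
  cls <- c(A = "CL", B = "CL", C = "TG", D = "PC")
  v <- matrix(c(4, 6, 1, 8,
                8, 12, 2, 4), 4, 2,
              dimnames = list(names(cls), c("s1", "s2")))
  lip <- structure(list(values = v, classes = cls), class = "lipid_matrix")
  out <- normalise_lipids_by_class(lip, "CL")

  # pure CL scaling removed: species C had values 1 and 2 under CL totals 10 and 20
  expect_equal(out$values["C", "s1"], out$values["C", "s2"])
  cl_tot <- colSums(out$values[cls == "CL", ])
  expect_lt(diff(range(cl_tot)) / mean(cl_tot), 1e-12)
  # within-sample ratios unchanged
  expect_equal(out$values["D", "s1"] / out$values["C", "s1"], v["D", "s1"] / v["C", "s1"])
  # units kept: rescaled by the cohort-mean anchor total
  expect_equal(mean(cl_tot), mean(colSums(v[cls == "CL", ])))

  v0 <- v
  v0[cls == "CL", "s2"] <- 0
  lip0 <- structure(list(values = v0, classes = cls), class = "lipid_matrix")
  expect_error(normalise_lipids_by_class(lip0), "s2")
  expect_error(normalise_lipids_by_class(lip, "GM3"), "not present")
})

test_that("content normalisation returns per-sample ratios and leaves aggregation to the caller", {
  expect_equal(content_normalise(c(10, 20), c(1, 2)), c(10, 10))
  v <- c(3, 8, 40)
  expect_equal(content_normalise(v, rep(1, 3)), v)
  expect_error(content_normalise(v, c(1, 0, 2)), "positive")
  expect_error(content_normalise(v, c(1, 2)), "length")
  # skewed fixture: mean of ratios differs from ratio of means
  s <- c(1, 2, 10)
  expect_false(isTRUE(all.equal(mean(v / s), mean(v) / mean(s))))
})

test_that("BESt chain removes the global content trend that the raw scale retains", {
  co <- cached("clean10", generate_cohort(
    cohort_config(n_participants = 10, n_features = 600, seed = 77,
                  noise = list(cv = 0.1, sd_a = 0),
                  missingness = list(enabled = FALSE))))
  d <- co$design
  nm <- suppressMessages(best_normalise(co$proteins, co$annotation, seed = 3))
  tp_shift <- function(vals) {
    tpm <- vapply(levels(d$timepoint), function(tp) {
      mean(vals[, d$sample[as.character(d$timepoint) == tp], drop = FALSE])
    }, numeric(1))
    tpm - tpm[1]
  }
  best_shift <- tp_shift(nm$values)
  expect_lt(max(abs(best_shift)), 0.05)

  mito <- co$annotation$feature[co$annotation$confidence == "Known Mitochondrial"]
  raw_shift <- tp_shift(log2(co$proteins[mito, ]))
  ctrend <- log2(co$truth$content_multiplier) +
    as.numeric(log2(tapply(co$truth$closure_factor[d$sample],
                           as.character(d$timepoint), mean)[levels(d$timepoint)]))
  ctrend <- ctrend - ctrend[1]
  expect_equal(unname(raw_shift), unname(ctrend), tolerance = 0.05)
})
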