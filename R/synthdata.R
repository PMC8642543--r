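#' Configuration for a synthetic mitochondrial-isolate cohort
#'
#' Describes a longitudinal cohort of mitochondrial isolates profiled by
#' label-free proteomics and targeted lipidomics: `n_participants` subjects
#' sampled at each timepoint, a per-timepoint global mitochondrial-content
#' multiplier `c_t` acting on every mitochondrial feature, optional
#' feature-class-specific true log2 deviations on top of the global trend,
#' mean-variance-dependent measurement noise, and intensity-dependent
#' left-censored missingness. Equal-protein-loading closure (each sample's
#' column rescaled to a common total intensity) is applied after noise; this
#' closure is what turns a change in mitochondrial protein enrichment into an
#' apparent change of every protein, the artefact the BESt chain removes.
#'
#' When `content_multiplier` is `NULL` the multipliers are calibrated
#' analytically from `mpe_target` (percent mitochondrial protein enrichment
#' per timepoint) and the drawn baseline intensities, so the generated cohort
#' realises the requested enrichment trajectory.
#'
#' @param n_participants number of participants (>= 2).
#' @param timepoints ordered character vector of timepoint labels.
#' @param n_features number of protein features.
#' @param mito_fraction fraction of features annotated mitochondrial, in (0,1).
#' @param mpe_target per-timepoint target mitochondrial protein enrichment in
#'   percent; used to calibrate `content_multiplier` when that is `NULL`.
#' @param content_multiplier optional explicit positive multiplier per
#'   timepoint; overrides `mpe_target` calibration.
#' @param effect_spec list of effect classes, each
#'   `list(name=, fraction=, delta=)` where `fraction` is the fraction of
#'   mitochondrial features assigned to the class and `delta` the true
#'   per-timepoint log2 deviation vector (length = number of timepoints).
#' @param noise list with `cv` (multiplicative coefficient of variation,
#'   lognormal on the raw scale) and `sd_a` (additive background sd on the raw
#'   intensity scale, truncated at zero).
#' @param participant_sd sd of the per-participant lognormal loading factor on
#'   the log2 scale.
#' @param base_mean,base_sd mean and sd of baseline log2 intensities.
#' @param missingness list with `tau_quantile` (per-sample MNAR location as a
#'   quantile of the sample's log2 intensities), `gamma` (logistic scale, > 0)
#'   and `mcar_rate` (uniform missingness rate); set `enabled = FALSE` to
#'   generate complete data.
#' @param n_lipids number of lipid species; `cl_fraction` the fraction in the
#'   cardiolipin (CL) class, which tracks the content multiplier.
#' @param cl_fraction see `n_lipids`.
#' @param seed integer RNG seed; every stochastic component derives its own
#'   stream from it via [stage_seed()].
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 10,
                          timepoints = TIMEPOINTS,
                          n_features = 1500,
                          mito_fraction = 0.40,
                          mpe_target = c(BL = 24.5, PN = 31.5, PH = 39.3, PR = 34.5),
                          content_multiplier = NULL,
                          effect_spec = NULL,
                          noise = list(cv = 0.20, sd_a = 5e4),
                          participant_sd = 0.10,
                          base_mean = 25, base_sd = 2.5,
                          missingness = list(enabled = TRUE, tau_quantile = 0.15,
                                             gamma = 1.0, mcar_rate = 0.01),
                          n_lipids = 200, cl_fraction = 0.08,
                          seed = 1L) {
  if (n_participants < 2) abort_fmt("n_participants must be >= 2")
  if (!(mito_fraction > 0 && mito_fraction < 1)) {
    abort_fmt("mito_fraction must lie strictly inside (0, 1)")
  }
  if (!is.null(content_multiplier)) {
    if (length(content_multiplier) != length(timepoints)) {
      abort_fmt("content_multiplier must have one value per timepoint")
    }
    if (any(content_multiplier <= 0)) abort_fmt("content multipliers must be > 0")
  } else {
    if (length(mpe_target) != length(timepoints)) {
      abort_fmt("mpe_target must have one value per timepoint")
    }
    if (any(mpe_target <= 0 | mpe_target >= 100)) {
      abort_fmt("mpe_target values must lie in (0, 100) percent")
    }
  }
  if (!is.null(effect_spec)) {
    fr <- vapply(effect_spec, function(e) e$fraction, numeric(1))
    if (any(fr < 0 | fr > 1) || sum(fr) > 1) {
      abort_fmt("effect-class fractions must lie in [0,1] and sum to <= 1")
    }
    for (e in effect_spec) {
      if (length(e$delta) != length(timepoints)) {
        abort_fmt("effect class '%s': delta must have one value per timepoint", e$name)
      }
    }
  }
  noise <- utils::modifyList(list(cv = 0.20, sd_a = 5e4), as.list(noise))
  missingness <- utils::modifyList(
    list(enabled = TRUE, tau_quantile = 0.15, gamma = 1.0, mcar_rate = 0.01),
    as.list(missingness))
  if (missingness$gamma <= 0) abort_fmt("missingness gamma must be > 0")
  structure(list(
    n_participants = as.integer(n_participants), timepoints = timepoints,
    n_features = as.integer(n_features), mito_fraction = mito_fraction,
    mpe_target = mpe_target, content_multiplier = content_multiplier,
    effect_spec = effect_spec, noise = noise, participant_sd = participant_sd,
    base_mean = base_mean, base_sd = base_sd, missingness = missingness,
    n_lipids = as.integer(n_lipids), cl_fraction = cl_fraction,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a synthetic multi-omics cohort with recorded ground truth
#'
#' Protein intensity for feature g in the sample of participant p at
#' timepoint t is built as
#' `closure( base_g * f_p * c_t^{mito_g} * 2^{delta_{g,t}} * noise )`:
#' a lognormal baseline intensity, a participant loading factor, the global
#' content multiplier applied to mitochondrial features only, the
#' feature-class true deviation, two-component noise
#' (`y = x * exp(e_m) + e_a`), and finally per-sample closure to a common
#' column total (equal protein loaded on the instrument). Intensity-dependent
#' (MNAR) plus uniform (MCAR) missingness is applied afterwards. A lipid
#' matrix is generated analogously, with the cardiolipin class tied to the
#' content multiplier. All latent quantities are returned in `$truth`.
#'
#' @param config a [cohort_config()].
#' @return object of class `synth_cohort`: list with elements `proteins`
#'   (matrix with `NA` for missing), `proteins_complete` (pre-missingness),
#'   `lfq` (alias of proteins, LFQ-style column), `lipids` (`lipid_matrix`),
#'   `annotation` (tibble feature/confidence), `design` (tibble), `truth`
#'   (list: `content_multiplier`, `delta`, `is_mito`, `effect_class`,
#'   `closure_factor`, `participant_factor`, `base_log2`, `missingness`,
#'   `realised_mpe`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  tp <- config$timepoints
  n_tp <- length(tp)
  n_p <- config$n_participants
  n_g <- config$n_features

  participants <- sprintf("P%02d", seq_len(n_p))
  design <- tidyr::expand_grid(participant = participants, timepoint = tp)
  design <- tibble::tibble(
    sample = paste(design$participant, design$timepoint, sep = "_"),
    participant = design$participant,
    timepoint = as_timepoint(design$timepoint, levels = tp),
    layer = "proteomics")
  n_s <- nrow(design)

  features <- sprintf("PROT%04d", seq_len(n_g))

  # baseline intensities and mitochondrial flags
  set.seed(stage_seed(config$seed, 1))
  base_log2 <- stats::rnorm(n_g, config$base_mean, config$base_sd)
  n_mito <- round(n_g * config$mito_fraction)
  is_mito <- rep(FALSE, n_g)
  is_mito[sample.int(n_g, n_mito)] <- TRUE

  # effect classes are carved out of the mitochondrial features
  effect_class <- rep("stoichiometric", n_g)
  delta <- matrix(0, n_g, n_tp, dimnames = list(features, tp))
  if (!is.null(config$effect_spec)) {
    set.seed(stage_seed(config$seed, 7))
    pool <- which(is_mito)
    for (e in config$effect_spec) {
      n_e <- round(e$fraction * n_mito)
      if (n_e > length(pool)) abort_fmt("effect class '%s' exhausts the mitochondrial features", e$name)
      idx <- sample(pool, n_e)
      pool <- setdiff(pool, idx)
      effect_class[idx] <- e$name
      delta[idx, ] <- matrix(e$delta, n_e, n_tp, byrow = TRUE)
    }
  }

  # content multipliers: explicit, or calibrated so the noise-free enrichment
  # hits mpe_target exactly (participant factors cancel in the ratio)
  base_raw <- 2^base_log2
  if (is.null(config$content_multiplier)) {
    m_t <- config$mpe_target / 100
    c_t <- vapply(seq_len(n_tp), function(j) {
      M <- sum(base_raw[is_mito] * 2^delta[is_mito, j])
      N <- sum(base_raw[!is_mito] * 2^delta[!is_mito, j])
      m_t[j] * N / ((1 - m_t[j]) * M)
    }, numeric(1))
  } else {
    c_t <- as.numeric(config$content_multiplier)
  }
  names(c_t) <- tp

  set.seed(stage_seed(config$seed, 2))
  f_p <- 2^stats::rnorm(n_p, 0, config$participant_sd)
  names(f_p) <- participants

  # expected (noise-free) matrix, then noise, then closure
  j_t <- match(as.character(design$timepoint), tp)
  x <- matrix(0, n_g, n_s, dimnames = list(features, design$sample))
  for (s in seq_len(n_s)) {
    j <- j_t[s]
    scale_g <- ifelse(is_mito, c_t[j], 1) * 2^delta[, j]
    x[, s] <- base_raw * f_p[design$participant[s]] * scale_g
  }
  set.seed(stage_seed(config$seed, 3))
  y <- add_measurement_noise(x, cv = config$noise$cv, sd_a = config$noise$sd_a)

  target_total <- mean(colSums(y))
  closure_factor <- target_total / colSums(y)
  y <- sweep(y, 2, closure_factor, `*`)

  realised_mpe <- 100 * colSums(y[is_mito, , drop = FALSE]) / colSums(y)

  miss <- config$missingness
  if (isTRUE(miss$enabled) && (miss$mcar_rate > 0 || miss$tau_quantile > 0)) {
    masked <- apply_missingness(
      y, mnar_params = list(tau_quantile = miss$tau_quantile, gamma = miss$gamma),
      mcar_rate = miss$mcar_rate, seed = stage_seed(config$seed, 5))
    proteins <- masked$values
    miss_par <- masked$params
  } else {
    proteins <- y
    miss_par <- list(tau = rep(-Inf, n_s), gamma = miss$gamma, mcar_rate = 0)
  }

  lip <- generate_lipids(config, design, c_t, f_p, j_t)

  annotation <- tibble::tibble(
    feature = features,
    confidence = ifelse(is_mito, "Known Mitochondrial", "none"))
  # a small tier of non-enriched "Predicted" entries, as annotation databases have
  set.seed(stage_seed(config$seed, 8))
  nm <- which(!is_mito)
  pred <- sample(nm, max(1L, round(0.05 * length(nm))))
  annotation$confidence[pred] <- "Predicted Mitochondrial"

  truth <- list(
    content_multiplier = c_t,
    delta = delta,
    is_mito = stats::setNames(is_mito, features),
    effect_class = stats::setNames(effect_class, features),
    closure_factor = closure_factor,
    participant_factor = f_p,
    base_log2 = stats::setNames(base_log2, features),
    missingness = miss_par,
    realised_mpe = realised_mpe)

  structure(list(
    proteins = proteins, proteins_complete = y, lipids = lip$matrix,
    annotation = annotation, design = design, lipid_design = lip$design,
    truth = c(truth, list(lipid_cl_species = lip$cl_species)),
    config = config
  ), class = "synth_cohort")
}

# two-component measurement noise: multiplicative lognormal + additive
# background truncated at zero (mean-variance dependence on the raw scale)
add_measurement_noise <- function(x, cv, sd_a) {
  if (cv <= 0 && sd_a <= 0) return(x)
  n <- length(x)
  e_m <- if (cv > 0) exp(stats::rnorm(n, 0, cv)) else 1
  e_a <- if (sd_a > 0) pmax(stats::rnorm(n, 0, sd_a), 0) else 0
  x * e_m + e_a
}

# lipidome: CL species share the content multiplier; concentrations in pmol
generate_lipids <- function(config, design, c_t, f_p, j_t) {
  set.seed(stage_seed(config$seed, 4))
  n_l <- config$n_lipids
  n_cl <- max(2L, round(config$cl_fraction * n_l))
  other_classes <- c("TG", "PC", "PE", "PS", "PI", "PG", "SM", "CE", "DG", "LPC")
  cls <- c(rep("CL", n_cl),
           sample(other_classes, n_l - n_cl, replace = TRUE))
  species <- sprintf("%s(%02d:%d)", cls, 30 + seq_len(n_l) %% 14 * 2, seq_len(n_l) %% 4)
  species <- make.unique(species, sep = "_")
  base <- 2^stats::rnorm(n_l, 6, 1.5)
  n_s <- nrow(design)
  lipid_samples <- paste0(design$sample, "_L")
  x <- matrix(0, n_l, n_s, dimnames = list(species, lipid_samples))
  for (s in seq_len(n_s)) {
    j <- j_t[s]
    x[, s] <- base * f_p[design$participant[s]] * ifelse(cls == "CL", c_t[j], 1)
  }
  y <- add_measurement_noise(x, cv = config$noise$cv, sd_a = 0)
  y <- sweep(y, 2, mean(colSums(y)) / colSums(y), `*`)
  lipid_design <- design
  lipid_design$sample <- lipid_samples
  lipid_design$layer <- "lipidomics"
  list(matrix = new_lipid_matrix(y, stats::setNames(cls, species)),
       design = lipid_design, cl_species = species[cls == "CL"])
}

#' Apply left-censored (MNAR) and uniform (MCAR) missingness
#'
#' Each value is masked with probability
#' `plogis((tau_s - log2(x)) / gamma) + mcar_rate`, capped at 1: low
#' intensities are preferentially censored, emulating the left-censored
#' missingness of label-free proteomics that motivates quantile-based
#' left-censored imputation downstream.
#'
#' @param matrix complete numeric matrix of positive intensities
#'   (features x samples).
#' @param mnar_params list with either `tau` (explicit per-sample logistic
#'   location on the log2 scale, recycled) or `tau_quantile` (per-sample
#'   quantile of the sample's log2 intensities used as tau), plus `gamma > 0`.
#' @param mcar_rate uniform missingness probability added on top.
#' @param seed integer seed; the mask is a deterministic function of it.
#' @return list with `values` (matrix, masked entries `NA`), `mask` (logical
#'   matrix, `TRUE` = missing) and `params` (realised `tau` per sample,
#'   `gamma`, `mcar_rate`).
#' @export
apply_missingness <- function(matrix, mnar_params = list(tau_quantile = 0.15, gamma = 1),
                              mcar_rate = 0, seed = 1L) {
  if (anyNA(matrix)) abort_fmt("apply_missingness expects a complete matrix")
  gamma <- mnar_params[["gamma"]] %||% 1
  if (gamma <= 0) abort_fmt("MNAR gamma must be > 0")
  n_s <- ncol(matrix)
  lx <- log2(pmax(matrix, .Machine$double.xmin))
  if (!is.null(mnar_params[["tau"]])) {
    tau <- rep_len(mnar_params[["tau"]], n_s)
  } else {
    q <- mnar_params[["tau_quantile"]] %||% 0.15
    tau <- apply(lx, 2, stats::quantile, probs = q, names = FALSE)
  }
  p <- stats::plogis(sweep(-lx, 2, tau, `+`) / gamma) + mcar_rate
  p <- pmin(p, 1)
  set.seed(seed)
  mask <- matrix(stats::runif(length(matrix)) < p, nrow(matrix), ncol(matrix),
                 dimnames = dimnames(matrix))
  values <- matrix
  values[mask] <- NA_real_
  list(values = values, mask = mask,
       params = list(tau = stats::setNames(tau, colnames(matrix)),
                     gamma = gamma, mcar_rate = mcar_rate))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-form mitochondrial protein enrichment of the generator
#'
#' With noise off and all true deviations zero, the enrichment at timepoint t
#' depends only on the content multiplier and the baseline mass split:
#' `MPE_t = 100 * M c_t / (M c_t + N)` where `M` and `N` are the summed
#' baseline intensities of mitochondrial and non-mitochondrial features.
#' Closure and participant factors cancel in the ratio. Used as the analytic
#' oracle for the generator and for [compute_mpe()].
#'
#' @param c_t content multiplier (vectorised).
#' @param mito_mass summed baseline intensity of mitochondrial features.
#' @param other_mass summed baseline intensity of the remaining features.
#' @return enrichment in percent.
#' @export
expected_mpe <- function(c_t, mito_mass, other_mass) {
  100 * mito_mass * c_t / (mito_mass * c_t + other_mass)
}

#' Write a synthetic cohort to disk in the external formats
#'
#' Proteins go out in the proteinGroups TSV dialect (via
#' [write_protein_table()]), lipids/design/annotation as CSV, the ground
#' truth as TSV and the configuration as YAML.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    proteins = file.path(dir, "proteinGroups.txt"),
    lipids = file.path(dir, "lipids.csv"),
    design = file.path(dir, "design.csv"),
    annotation = file.path(dir, "annotation.csv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml"))
  write_protein_table(cohort$proteins, paths["proteins"], lfq = cohort$proteins)
  write_lipid_table(cohort$lipids, paths["lipids"])
  readr::write_csv(rbind(cohort$design, cohort$lipid_design), paths["design"])
  readr::write_csv(cohort$annotation, paths["annotation"])
  tr <- tibble::tibble(
    feature = names(cohort$truth$is_mito),
    is_mito = cohort$truth$is_mito,
    effect_class = cohort$truth$effect_class)
  tr <- cbind(tr, tibble::as_tibble(cohort$truth$delta, .name_repair = ~ paste0("delta_", .x)))
  readr::write_tsv(tr, paths["truth"])
  cfg <- cohort$config
  class(cfg) <- NULL
  cfg$effect_spec <- lapply(cfg$effect_spec, function(e) { e$delta <- as.numeric(e$delta); e })
  yaml::write_yaml(cfg, paths["config"])
  invisible(paths)
}
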