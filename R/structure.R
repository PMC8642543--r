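#' Row-wise z-scoring
#'
#' Centres each row to mean 0 and scales to sd 1 using the sample-sd (n-1)
#' convention. Rows with zero variance are dropped with a warning, since
#' they carry no shape information for clustering or profiles.
#'
#' @param matrix numeric matrix.
#' @return z-scored matrix (possibly fewer rows).
#' @export
zscore_rows <- function(matrix) {
  mu <- rowMeans(matrix, na.rm = TRUE)
  sd <- apply(matrix, 1, stats::sd, na.rm = TRUE)
  const <- !is.finite(sd) | sd == 0
  if (any(const)) {
    warn_fmt("dropping %d constant row(s) before z-scoring", sum(const))
    matrix <- matrix[!const, , drop = FALSE]
    mu <- mu[!const]
    sd <- sd[!const]
  }
  (matrix - mu) / sd
}

#' Agglomerative hierarchical clustering with a fixed-k cut
#'
#' Euclidean distances between (typically z-scored) feature rows, merged by
#' complete or average linkage, cut into `k` clusters. The merge tree and
#' the dendrogram leaf order are returned so heatmap row order can follow
#' the tree exactly.
#'
#' @param matrix features x columns matrix (rows are clustered).
#' @param linkage "complete" (proteins/lipids default) or "average".
#' @param k number of clusters, `2 <= k <= nrow`.
#' @return object of class `cluster_result`: `cluster` (named integer),
#'   `tree` (hclust), `order` (leaf order), `linkage`, `k`.
#' @export
hierarchical_cluster <- function(matrix, linkage = c("complete", "average"), k = 6) {
  linkage <- match.arg(linkage)
  if (k > nrow(matrix)) abort_fmt("k = %d exceeds the %d rows", k, nrow(matrix))
  d <- stats::dist(matrix, method = "euclidean")
  tree <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(tree, k = k)
  structure(list(cluster = cl, tree = tree, order = tree$order,
                 linkage = linkage, k = as.integer(k)),
            class = "cluster_result")
}

#' Classical (Torgerson) multidimensional scaling of samples
#'
#' Double-centres the squared Euclidean sample-sample distance matrix and
#' embeds samples on the top eigenvectors scaled by the square root of their
#' eigenvalues. Axis signs are fixed deterministically by making each axis's
#' largest-magnitude coordinate positive. If fewer positive eigenvalues than
#' requested dimensions exist, the available ones are returned with a
#' warning.
#'
#' @param matrix features x samples matrix; samples are the embedded points.
#' @param n_dims number of dimensions requested.
#' @return list with `points` (samples x dims), `eig` (all eigenvalues).
#' @export
classical_mds <- function(matrix, n_dims = 2) {
  if (ncol(matrix) < 3) abort_fmt("MDS needs >= 3 samples")
  d <- stats::dist(t(matrix))
  fit <- stats::cmdscale(d, k = min(n_dims, ncol(matrix) - 1), eig = TRUE)
  pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  if (pos < n_dims) {
    warn_fmt("only %d positive eigenvalue(s); returning %d dimension(s)", pos, pos)
  }
  pts <- fit$points[, seq_len(min(n_dims, max(pos, 1), ncol(fit$points))), drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  list(points = pts, eig = fit$eig)
}

#' Per-set, per-timepoint profile summaries
#'
#' For each feature set and timepoint: the mean over features of the
#' per-feature mean z-score across that timepoint's samples, with the
#' between-feature sd as dispersion. Input rows are z-scored first (the
#' profile-plot convention).
#'
#' @param matrix features x samples matrix (raw or transformed scale).
#' @param design design tibble.
#' @param feature_sets named list of character vectors of feature ids.
#' @return tidy tibble: `set`, `timepoint`, `mean_z`, `sd_z`, `n_features`.
#' @export
profile_summary <- function(matrix, design, feature_sets) {
  z <- zscore_rows(matrix)
  d <- design[match(colnames(z), design$sample), , drop = FALSE]
  tps <- levels(droplevels(d$timepoint))
  out <- list()
  for (nm in names(feature_sets)) {
    fs <- intersect(feature_sets[[nm]], rownames(z))
    if (length(fs) == 0) {
      warn_fmt("feature set '%s' is empty in the matrix", nm)
      out[[nm]] <- tibble::tibble(set = nm, timepoint = tps,
                                  mean_z = NA_real_, sd_z = NA_real_, n_features = 0L)
      next
    }
    per_tp <- vapply(tps, function(tp) {
      cols <- d$sample[as.character(d$timepoint) == tp]
      fm <- rowMeans(z[fs, cols, drop = FALSE])
      c(mean(fm), stats::sd(fm))
    }, numeric(2))
    out[[nm]] <- tibble::tibble(set = nm, timepoint = tps,
                                mean_z = unname(per_tp[1, ]),
                                sd_z = unname(per_tp[2, ]),
                                n_features = length(fs))
  }
  dplyr::bind_rows(out)
}

#' Hypergeometric over-representation of feature sets in pathways
#'
#' Upper-tail hypergeometric p-value for the overlap between a cluster (or
#' any feature set) and each pathway, both intersected with the testing
#' universe, with BH adjustment across pathways. A generic stand-in for
#' external enrichment services.
#'
#' @param cluster_features character vector, must be a subset of `universe`.
#' @param pathway_sets named list of character vectors.
#' @param universe character vector of all testable features.
#' @return tibble: `pathway`, `overlap`, `cluster_size`, `pathway_size`,
#'   `universe_size`, `p`, `adj_p`.
#' @export
overrepresentation_test <- function(cluster_features, pathway_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort_fmt("empty universe")
  extra <- setdiff(cluster_features, universe)
  if (length(extra) > 0) {
    abort_fmt("cluster feature(s) outside the universe: %s", paste(extra, collapse = ", "))
  }
  n_u <- length(universe)
  n_c <- length(cluster_features)
  rows <- lapply(names(pathway_sets), function(nm) {
    pw <- intersect(pathway_sets[[nm]], universe)
    ov <- length(intersect(cluster_features, pw))
    p <- stats::phyper(ov - 1, length(pw), n_u - length(pw), n_c, lower.tail = FALSE)
    tibble::tibble(pathway = nm, overlap = ov, cluster_size = n_c,
                   pathway_size = length(pw), universe_size = n_u, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$adj_p <- adjust_bh(out$p)
  out
}
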