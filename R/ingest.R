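#' Read a proteinGroups-style protein intensity table
#'
#' Parses the tab-separated "proteinGroups" dialect of label-free search
#' output: one row per protein group with `Intensity <sample>` and
#' `LFQ intensity <sample>` columns and `+`-flagged marker columns. Rows
#' flagged "Only identified by site", "Reverse" or "Potential contaminant"
#' are removed and the per-flag removal counts kept in the result. A zero in
#' an intensity column means "not quantified" in this dialect and is
#' converted to `NA`; no other numeric value is altered.
#'
#' Feature identity is the leading entry of the gene-name field, falling back
#' to the protein-group id when the gene name is empty (a message notes the
#' fallback). Duplicate feature ids are an error.
#'
#' @param path TSV file (gzip accepted).
#' @param design sample design tibble from [read_design()]; every proteomics
#'   sample must have a matching intensity column.
#' @param intensity_prefix,lfq_prefix column-header prefixes, configurable
#'   because the dialect varies between search-engine versions.
#' @return object of class `protein_data`: list with `raw` and `lfq` matrices
#'   (features x samples, `NA` = missing), `features` tibble, `design`, and
#'   `removed` (named counts per marker flag).
#' @export
read_protein_table <- function(path, design,
                               intensity_prefix = "Intensity ",
                               lfq_prefix = "LFQ intensity ") {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  prot_design <- design[design$layer == "proteomics", , drop = FALSE]
  samples <- prot_design$sample

  want <- paste0(intensity_prefix, samples)
  missing_cols <- setdiff(want, names(tab))
  if (length(missing_cols) > 0) {
    abort_fmt("protein table is missing intensity column(s): %s",
              paste(missing_cols, collapse = ", "))
  }

  flag_cols <- c("Only identified by site", "Reverse", "Potential contaminant")
  removed <- stats::setNames(integer(length(flag_cols)), flag_cols)
  keep <- rep(TRUE, nrow(tab))
  for (fc in flag_cols) {
    if (fc %in% names(tab)) {
      flagged <- !is.na(tab[[fc]]) & tab[[fc]] == "+"
      removed[fc] <- sum(flagged & keep)
      keep <- keep & !flagged
    }
  }
  tab <- tab[keep, , drop = FALSE]

  gene <- if ("Gene names" %in% names(tab)) {
    vapply(strsplit(as.character(tab[["Gene names"]]), ";", fixed = TRUE),
           function(x) if (length(x) > 0 && nzchar(x[1]) && !is.na(x[1])) x[1] else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(tab))
  pid <- if ("Protein IDs" %in% names(tab)) as.character(tab[["Protein IDs"]])
         else sprintf("group%05d", seq_len(nrow(tab)))
  feature <- ifelse(is.na(gene), pid, gene)
  if (anyNA(gene)) {
    message(sum(is.na(gene)), " feature(s) keyed by protein-group id (no gene name)")
  }
  dup <- unique(feature[duplicated(feature)])
  if (length(dup) > 0) {
    abort_fmt("duplicate feature id(s): %s", paste(dup, collapse = ", "))
  }

  get_matrix <- function(prefix) {
    cols <- paste0(prefix, samples)
    if (!all(cols %in% names(tab))) return(NULL)
    m <- as.matrix(tab[, cols, drop = FALSE])
    dimnames(m) <- list(feature, samples)
    if (any(m < 0, na.rm = TRUE)) abort_fmt("negative intensities in %scolumns", prefix)
    m[m == 0] <- NA_real_   # 0 means missing in this dialect
    m
  }
  raw <- get_matrix(intensity_prefix)
  lfq <- get_matrix(lfq_prefix)

  empty <- colSums(!is.na(raw)) == 0
  if (any(empty)) {
    warn_fmt("sample(s) with no quantified protein: %s",
             paste(samples[empty], collapse = ", "))
  }

  structure(list(
    raw = raw, lfq = lfq,
    features = tibble::tibble(feature = feature, gene = gene, protein_ids = pid),
    design = prot_design, removed = removed
  ), class = "protein_data")
}

#' Write a protein matrix in the proteinGroups TSV dialect
#'
#' Inverse of [read_protein_table()]: `NA` becomes 0, marker columns are
#' written empty (or from `flags`), feature ids go into `Gene names` and
#' `Protein IDs`.
#'
#' @param raw features x samples matrix (`NA` = missing).
#' @param path output TSV path.
#' @param lfq optional LFQ matrix with identical dimensions.
#' @param flags optional tibble with columns among the three marker columns.
#' @return invisibly, `path`.
#' @export
write_protein_table <- function(raw, path, lfq = NULL, flags = NULL) {
  feature <- rownames(raw)
  out <- tibble::tibble(`Protein IDs` = feature, `Gene names` = feature)
  flag_cols <- c("Only identified by site", "Reverse", "Potential contaminant")
  for (fc in flag_cols) {
    out[[fc]] <- if (!is.null(flags) && fc %in% names(flags)) flags[[fc]] else ""
  }
  fill0 <- function(m) { m[is.na(m)] <- 0; m }
  for (s in colnames(raw)) out[[paste0("Intensity ", s)]] <- fill0(raw[, s])
  if (!is.null(lfq)) {
    for (s in colnames(lfq)) out[[paste0("LFQ intensity ", s)]] <- fill0(lfq[, s])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read the sample design table
#'
#' CSV with columns `sample`, `participant`, `timepoint`, `layer`. Timepoint
#' labels must come from the ordered vocabulary (default BL < PN < PH < PR);
#' each (participant, timepoint, layer) may appear at most once.
#'
#' @param path CSV file (gzip accepted).
#' @param timepoints ordered vocabulary of timepoint labels.
#' @return tibble with `timepoint` as an ordered factor.
#' @export
read_design <- function(path, timepoints = TIMEPOINTS) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "participant", "timepoint", "layer")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) abort_fmt("design is missing column(s): %s", paste(miss, collapse = ", "))
  d$timepoint <- as_timepoint(d$timepoint, levels = timepoints)
  key <- paste(d$participant, d$timepoint, d$layer, sep = "/")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    abort_fmt("duplicate (participant, timepoint, layer): %s", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(d$sample)) abort_fmt("duplicate sample ids in design")
  tibble::as_tibble(d[, need])
}

#' Read a mitochondrial annotation table
#'
#' CSV with columns `feature`, `confidence` (free-case labels normalised to
#' "Known Mitochondrial" / "Predicted Mitochondrial" / "none") and optionally
#' `pathway` (semicolon-separated memberships). Feature ids absent from a
#' given intensity matrix are kept: the annotation defines the outer
#' universe.
#'
#' @param path CSV file (gzip accepted).
#' @return tibble, one row per feature id.
#' @export
read_annotation <- function(path) {
  a <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("feature", "confidence") %in% names(a))) {
    abort_fmt("annotation needs 'feature' and 'confidence' columns")
  }
  if (anyDuplicated(a$feature)) {
    abort_fmt("duplicate feature id(s) in annotation: %s",
              paste(unique(a$feature[duplicated(a$feature)]), collapse = ", "))
  }
  a$confidence <- normalise_confidence(a$confidence)
  tibble::as_tibble(a)
}

# internal constructor for the lipid container
new_lipid_matrix <- function(values, classes) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            all(rownames(values) %in% names(classes)))
  structure(list(values = values, classes = classes[rownames(values)]),
            class = "lipid_matrix")
}

#' Read a lipid-species concentration table
#'
#' CSV with columns `species`, `class` and one numeric column per sample.
#' Every species must carry exactly one non-empty class label (cardiolipin is
#' "CL"); species without a class are rejected.
#'
#' @param path CSV file (gzip accepted).
#' @param design design tibble; its lipidomics samples must all be present as
#'   columns.
#' @return object of class `lipid_matrix`: list with `values` (species x
#'   samples) and `classes` (named character vector).
#' @export
read_lipid_table <- function(path, design) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("species", "class") %in% names(tab))) {
    abort_fmt("lipid table needs 'species' and 'class' columns")
  }
  bad <- is.na(tab$class) | !nzchar(trimws(tab$class))
  if (any(bad)) {
    abort_fmt("species without a lipid class: %s",
              paste(tab$species[bad], collapse = ", "))
  }
  lip_design <- design[design$layer == "lipidomics", , drop = FALSE]
  samples <- lip_design$sample
  miss <- setdiff(samples, names(tab))
  if (length(miss) > 0) {
    abort_fmt("lipid table is missing sample column(s): %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab$species)) abort_fmt("duplicate lipid species ids")
  m <- as.matrix(tab[, samples, drop = FALSE])
  rownames(m) <- tab$species
  if (any(m < 0, na.rm = TRUE)) abort_fmt("negative lipid concentrations")
  new_lipid_matrix(m, stats::setNames(tab$class, tab$species))
}

#' Write a lipid matrix as CSV
#' @param lipids a `lipid_matrix`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_lipid_table <- function(lipids, path) {
  out <- tibble::tibble(species = rownames(lipids$values),
                        class = unname(lipids$classes))
  out <- cbind(out, tibble::as_tibble(lipids$values))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
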