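#' Generalised log2
#'
#' `glog2(z) = log2(z + sqrt(z^2 + 1)) - 1`. The `-1` offset makes the
#' transform asymptotically equal to `log2(z)` for large `z`, so values on the
#' transformed scale read as log2 intensities and differences as log2
#' fold-changes. Unlike `log2`, `glog2` is defined and strictly increasing on
#' all of the real line, which is what allows an affine calibration
#' `a + b * x` inside it.
#'
#' @param z numeric vector.
#' @return numeric vector on the glog2 scale.
#' @export
glog2 <- function(z) {
  log2(z + sqrt(z^2 + 1)) - 1
}

#' Derive a stage seed from a global seed
#'
#' Deterministic fan-out of one global seed into per-stage seeds so that
#' stages re-run in isolation reproduce the pipeline run. Kept below 2^31 so
#' the result is a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param offset integer stage offset.
#' @return integer seed.
#' @export
stage_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 77003 * as.double(offset)) %% 2147483629)
}

# stop() with a consistent prefix-free message built by sprintf
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# invert the trigamma function by Newton iteration (monotone, convex target)
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy)) return(NaN)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in seq_len(60)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

# canonical timepoint order used throughout
TIMEPOINTS <- c("BL", "PN", "PH", "PR")

# coerce a timepoint column to an ordered factor, validating labels
as_timepoint <- function(x, levels = TIMEPOINTS) {
  bad <- setdiff(unique(as.character(x)), levels)
  if (length(bad) > 0) {
    abort_fmt("malformed timepoint label(s): %s (expected %s)",
              paste(bad, collapse = ", "), paste(levels, collapse = " < "))
  }
  factor(as.character(x), levels = levels, ordered = TRUE)
}

CONFIDENCE_LEVELS <- c("Known Mitochondrial", "Predicted Mitochondrial", "none")

# map free-case confidence labels onto the canonical vocabulary
normalise_confidence <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("known mitochondrial", "known")] <- "Known Mitochondrial"
  out[key %in% c("predicted mitochondrial", "predicted")] <- "Predicted Mitochondrial"
  out[key %in% c("none", "non-mitochondrial", "not mitochondrial", "")] <- "none"
  bad <- unique(x[is.na(out)])
  if (length(bad) > 0) {
    abort_fmt("unrecognised mitochondrial confidence label(s): %s",
              paste(bad, collapse = ", "))
  }
  out
}
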