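#' Fisher z-transform of a correlation coefficient
#'
#' `atanh(r)` with clipping at `1 - 1e-7` in absolute value so that
#' duplicate patterns (r exactly 1) yield a large finite value rather than
#' infinity; a warning reports the clip.
#'
#' @param r correlations in `[-1, 1]` (vector or matrix).
#' @param clip clipping bound on `|r|` (default `1 - 1e-7`).
#' @return z-values, same shape as `r`.
#' @examples
#' fisher_z(0.5)  # 0.5 * log(3) = 0.5493
#' @export
fisher_z <- function(r, clip = 1 - 1e-7) {
  bad <- !is.na(r) & abs(r) > 1
  if (any(bad)) stop_invalid("|r| > 1 supplied to fisher_z")
  clipped <- !is.na(r) & abs(r) > clip
  if (any(clipped))
    warning("fisher_z: ", sum(clipped), " value(s) clipped at |r| = ", clip)
  r[clipped] <- sign(r[clipped]) * clip
  atanh(r)
}

#' Within-context representational similarity matrix for one ROI
#'
#' Pairwise Fisher-z Pearson similarities between trial-wise voxel patterns,
#' restricted to the requested context. Only pairs of trials from
#' *different* runs are valid (same-run pairs are masked to avoid temporal
#' autocorrelation), both trials must be flagged included, and for the
#' retrieval phase only correct trials enter by default.
#'
#' @param pattern_set a `trial_pattern_set`
#'   (see [generate_pattern_dataset()]) or any list with `meta` and
#'   `patterns` components for the phase.
#' @param roi index of the ROI within the set's ROI list.
#' @param phase `"encoding"` or `"retrieval"`.
#' @param context `"spatial"`, `"temporal"`, or `"all"` (both contexts
#'   pooled; pairs remain cross-run only).
#' @param correct_only restrict to correct trials; defaults to `TRUE` for
#'   retrieval and `FALSE` for encoding.
#' @return object of class `rsm`: list with `z` (n x n Fisher-z matrix over
#'   the selected trials), `valid` (logical mask), `meta` (selected trial
#'   metadata).
#' @export
within_context_rsm <- function(pattern_set, roi, phase = "encoding",
                               context = "all", correct_only = NULL) {
  if (!phase %in% names(pattern_set))
    stop_invalid("phase '%s' not present in pattern set", phase)
  if (is.null(correct_only)) correct_only <- phase == "retrieval"
  ph <- pattern_set[[phase]]
  keep <- ph$meta$included
  if (context != "all") keep <- keep & ph$meta$context == context
  if (correct_only) keep <- keep & ph$meta$correct
  meta <- ph$meta[keep, , drop = FALSE]
  if (nrow(meta) < 2L)
    stop_invalid("fewer than 2 included trials for context '%s'", context)
  if (length(unique(meta$run)) < 2L)
    stop_invalid("no valid cross-run pairs: all selected trials share one run")
  x <- ph$patterns[[roi]][keep, , drop = FALSE]
  r <- suppressWarnings(stats::cor(t(x)))
  valid <- outer(meta$run, meta$run, "!=")
  diag(valid) <- FALSE
  z <- matrix(NA_real_, nrow(meta), nrow(meta))
  z[valid] <- fisher_z(r[valid])
  structure(list(z = z, valid = valid, meta = meta),
            class = "rsm", roi = roi, phase = phase, context = context)
}

#' Vectorize the valid entries of an RSM
#'
#' Deterministic row-major upper-triangle ordering over the valid mask, so
#' that two ROIs built on the same trial selection yield entry-for-entry
#' aligned vectors (the alignment the ICM correlation relies on).
#'
#' @param rsm an [within_context_rsm()] result.
#' @param extra_mask optional logical matrix; entries are dropped where it
#'   is `FALSE`.
#' @return list with `values` (numeric vector) and `pairs` (two-column
#'   integer matrix of trial indices i < j).
#' @export
vectorize_rsm <- function(rsm, extra_mask = NULL) {
  n <- nrow(rsm$z)
  mask <- rsm$valid
  if (!is.null(extra_mask)) mask <- mask & extra_mask
  pairs <- upper_tri_pairs(n)
  ok <- mask[pairs]
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) < 3L)
    stop_invalid("fewer than 3 valid RSM entries")
  list(values = rsm$z[pairs], pairs = pairs)
}

#' Compute RSMs for every ROI of a pattern set
#'
#' @inheritParams within_context_rsm
#' @return list of `rsm` objects, one per ROI, in atlas order.
#' @export
rsm_stack <- function(pattern_set, phase = "encoding", context = "all",
                      correct_only = NULL) {
  n_roi <- length(pattern_set[[phase]]$patterns)
  lapply(seq_len(n_roi), function(r)
    within_context_rsm(pattern_set, r, phase, context, correct_only))
}
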