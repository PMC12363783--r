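#' Distance between an ROI's spatial and temporal connectivity profiles
#'
#' For one ROI, its informational connectivity with every other ROI is read
#' from the spatial and the temporal ICM (self-edge excluded); the distance
#' between the two profiles is `1 - r`, with `r` the Pearson or Spearman
#' correlation over the common unmasked entries.
#'
#' @param icm_spatial,icm_temporal ICMs over the same ROI set
#'   (see [compute_icm()]).
#' @param roi ROI index (row of the ICMs).
#' @param metric `"pearson"` or `"spearman"`.
#' @return object of class `distance_result`: list with `roi`, `metric`,
#'   `distance` (in `[0, 2]`), and `n` (profile entries used).
#' @export
roi_profile_distance <- function(icm_spatial, icm_temporal, roi,
                                 metric = c("pearson", "spearman")) {
  metric <- match.arg(metric)
  if (!identical(dim(icm_spatial), dim(icm_temporal)))
    stop_invalid("ICMs have different ROI sets")
  a <- unclass(icm_spatial)[roi, ]
  b <- unclass(icm_temporal)[roi, ]
  keep <- is.finite(a) & is.finite(b)
  keep[roi] <- FALSE
  if (sum(keep) < 3L)
    stop_invalid("fewer than 3 common profile entries for ROI %d", roi)
  r <- stats::cor(a[keep], b[keep], method = metric)
  structure(list(roi = roi, metric = metric, distance = 1 - r,
                 n = sum(keep)), class = "distance_result")
}

#' Distance profiles for every ROI
#'
#' @inheritParams roi_profile_distance
#' @return numeric vector of `1 - r` distances, one per ROI.
#' @export
profile_distances <- function(icm_spatial, icm_temporal,
                              metric = c("pearson", "spearman")) {
  metric <- match.arg(metric)
  n <- nrow(icm_spatial)
  vapply(seq_len(n), function(r)
    roi_profile_distance(icm_spatial, icm_temporal, r, metric)$distance,
    numeric(1))
}

#' Paired pre/post test of connectivity-profile distances per ROI
#'
#' Paired t-test of the post-minus-pre distance within one group, per ROI,
#' with Benjamini-Hochberg FDR across all ROIs. Positive t means the
#' spatial and temporal connectivity profiles are *further apart* at
#' post-test (note: analyses that order the pair pre minus post print the
#' same effect with a negative t).
#'
#' @param dist_pre,dist_post participants x ROIs matrices of distances
#'   (rows aligned; rows with a missing session are dropped with a message).
#' @param q FDR threshold.
#' @return data.frame with columns `roi`, `mean_change`, `t`, `df`, `p`,
#'   `q`, `significant`.
#' @export
distance_session_test <- function(dist_pre, dist_post, q = 0.05) {
  dist_pre <- as.matrix(dist_pre); dist_post <- as.matrix(dist_post)
  if (!identical(dim(dist_pre), dim(dist_post)))
    stop_invalid("pre and post distance matrices differ in shape")
  complete <- stats::complete.cases(dist_pre) & stats::complete.cases(dist_post)
  if (!all(complete)) {
    message("dropping ", sum(!complete), " participant(s) missing a session")
    dist_pre <- dist_pre[complete, , drop = FALSE]
    dist_post <- dist_post[complete, , drop = FALSE]
  }
  n <- nrow(dist_pre)
  if (n < 2L) stop_invalid("need >= 2 participants with both sessions")
  d <- dist_post - dist_pre
  m <- colMeans(d)
  s <- sqrt(colSums((d - matrix(m, n, ncol(d), byrow = TRUE))^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[s == 0] <- 0
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  p[p == 0] <- .Machine$double.xmin
  fdr <- fdr_bh(p, q)
  data.frame(roi = seq_along(m), mean_change = m, t = t, df = n - 1,
             p = p, q = fdr$qvalues, significant = fdr$reject)
}
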