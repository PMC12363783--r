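#' Informational connectivity matrix from per-ROI RSMs
#'
#' Edge (i, j) is the Fisher-z Pearson correlation between the vectorized
#' RSMs of ROI i and ROI j over their common valid trial pairs. With one
#' RSM stack per context type this yields the spatial, temporal, and
#' combined ("all trials") ICMs.
#'
#' @param rsms list of `rsm` objects with identical trial selections (as
#'   produced by [rsm_stack()]).
#' @return object of class `icm`: symmetric ROI-by-ROI matrix of Fisher-z
#'   correlations, `NA` diagonal; attribute `n_pairs` records the number of
#'   common valid trial pairs.
#' @export
compute_icm <- function(rsms) {
  if (length(rsms) < 2L) stop_invalid("need at least 2 ROIs")
  common <- Reduce(`&`, lapply(rsms, `[[`, "valid"))
  vecs <- lapply(rsms, vectorize_rsm, extra_mask = common)
  v <- vapply(vecs, `[[`, numeric(nrow(vecs[[1]]$pairs)), "values")
  r <- suppressWarnings(stats::cor(v))
  diag(r) <- 0  # self-edges are masked below, keep them off the clip path
  z <- fisher_z(r)
  diag(z) <- NA_real_
  structure(z, class = c("icm", "matrix"), n_pairs = nrow(vecs[[1]]$pairs))
}

#' Per-edge pre-to-post connectivity change
#'
#' @param icm_pre,icm_post ICMs over the same ROI set.
#' @return matrix of `z_post - z_pre`; `NA` where either input is masked.
#' @export
edge_change <- function(icm_pre, icm_post) {
  if (!identical(dim(icm_pre), dim(icm_post)))
    stop_invalid("ICMs have different ROI sets")
  unclass(icm_post) - unclass(icm_pre)
}

#' @noRd
edge_vector <- function(mat) {
  mat[upper_tri_pairs(nrow(mat))]
}

#' Stack per-participant edge-change matrices into a participants x edges matrix
#'
#' Row order follows the input list; column order is the row-major upper
#' triangle of the ROI matrix.
#'
#' @param deltas list of per-participant [edge_change()] matrices.
#' @return numeric matrix, one row per participant, one column per edge.
#' @export
delta_matrix <- function(deltas) {
  do.call(rbind, lapply(deltas, edge_vector))
}

#' @noRd
welch_t <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  t[se2 == 0] <- 0
  t
}

#' Observed group contrast per edge
#'
#' Welch (unequal-variance) two-sample t of the edge-change values: target
#' group versus all remaining participants pooled. Positive t means the
#' target group's pre-to-post change is larger.
#'
#' @param deltas participants x edges matrix (see [delta_matrix()]).
#' @param groups character vector of group labels, one per row of `deltas`.
#' @param target_group label of the group contrasted against the pooled rest.
#' @return numeric vector of t statistics, one per edge. Edges with zero
#'   pooled variance return t = 0 (with a warning).
#' @export
group_edge_contrast <- function(deltas, groups, target_group) {
  deltas <- as.matrix(deltas)
  if (length(groups) != nrow(deltas))
    stop_invalid("groups length must match rows of deltas")
  in_t <- groups == target_group
  n1 <- sum(in_t); n2 <- sum(!in_t)
  if (n1 < 2L || n2 < 2L)
    stop_invalid("need >= 2 participants in target and in pooled-others")
  x1 <- deltas[in_t, , drop = FALSE]
  x2 <- deltas[!in_t, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- (colSums(x1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(x2^2) - n2 * m2^2) / (n2 - 1)
  degenerate <- (v1 / n1 + v2 / n2) == 0
  if (any(degenerate))
    warning(sum(degenerate), " edge(s) with zero pooled variance; t set to 0")
  welch_t(m1, v1, n1, m2, v2, n2)
}

#' Permutation null for the edgewise group contrast
#'
#' Participant group labels are the exchangeable unit under the
#' between-group null: labels are shuffled (preserving group sizes), the
#' Welch contrast is recomputed per draw, and the two-sided per-edge p-value
#' uses the add-one estimator `p = (1 + #\{|t_perm| >= |t_obs|\}) /
#' (1 + n_perm)`. Deterministic given `seed`.
#'
#' @inheritParams group_edge_contrast
#' @param n_perm number of permutation draws (the full-scale analysis uses
#'   10,000).
#' @param seed integer seed.
#' @return list with `t_obs` (per-edge observed t) and `p` (per-edge
#'   permutation p in `(0, 1]`).
#' @export
permutation_null <- function(deltas, groups, target_group, n_perm = 10000L,
                             seed = 1L) {
  if (!is_count(n_perm)) stop_invalid("n_perm must be >= 1")
  deltas <- as.matrix(deltas)
  t_obs <- suppressWarnings(group_edge_contrast(deltas, groups, target_group))
  n <- nrow(deltas)
  n1 <- sum(groups == target_group)
  set.seed(seed_stream(seed, "perm"))
  # all permutations at once: G is n_perm x n indicator of permuted target
  # membership; group sums/sumsq come from two matrix products.
  g <- matrix(0, n_perm, n)
  for (b in seq_len(n_perm)) g[b, sample.int(n, n1)] <- 1
  s1 <- g %*% deltas
  q1 <- g %*% (deltas^2)
  s_all <- matrix(colSums(deltas), n_perm, ncol(deltas), byrow = TRUE)
  q_all <- matrix(colSums(deltas^2), n_perm, ncol(deltas), byrow = TRUE)
  n2 <- n - n1
  m1 <- s1 / n1
  m2 <- (s_all - s1) / n2
  v1 <- (q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (q_all - q1 - n2 * m2^2) / (n2 - 1)
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0
  tp <- welch_t(m1, v1, n1, m2, v2, n2)
  exceed <- colSums(abs(tp) >= matrix(abs(t_obs), n_perm, ncol(deltas),
                                      byrow = TRUE))
  list(t_obs = t_obs, p = (1 + exceed) / (1 + n_perm))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: reject the `k` smallest p-values where `k` is the
#' largest rank with `p_(k) <= k q / m`; q-values are the monotone-adjusted
#' p-values (`cummin` from the largest rank of `p_(k) m / k`, capped at 1).
#'
#' @param p p-values in `(0, 1]`.
#' @param q FDR threshold (default 0.05).
#' @return list with `reject` (logical, original order) and `qvalues`.
#' @examples
#' fdr_bh(c(.01, .02, .04, .2))$reject  # TRUE TRUE FALSE FALSE
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop_invalid("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  qv <- rev(cummin(rev(pmin(ranked * m / seq_len(m), 1))))
  crit <- ranked <= seq_len(m) * q / m
  k <- if (any(crit)) max(which(crit)) else 0L
  reject <- logical(m)
  qvalues <- numeric(m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  qvalues[o] <- qv
  list(reject = reject, qvalues = qvalues)
}

#' Full edgewise contrast table
#'
#' Runs [permutation_null()] and [fdr_bh()] and assembles the per-edge
#' result table: ROI pair, observed Welch t, permutation p, FDR q, and the
#' direction implied by the sign of t (`post > pre` for positive t when
#' deltas are post minus pre changes of the target group relative to the
#' pooled others).
#'
#' @inheritParams permutation_null
#' @param q FDR threshold.
#' @param roi_ids ROI labels (defaults to 1..n inferred from edge count).
#' @return data.frame with columns `roi_i`, `roi_j`, `t`, `p`, `q`,
#'   `direction`, `significant`, sorted by decreasing `|t|`.
#' @export
edge_contrast_table <- function(deltas, groups, target_group,
                                n_perm = 10000L, seed = 1L, q = 0.05,
                                roi_ids = NULL) {
  deltas <- as.matrix(deltas)
  n_edge <- ncol(deltas)
  n_roi <- (1 + sqrt(1 + 8 * n_edge)) / 2
  if (n_roi != floor(n_roi))
    stop_invalid("edge count %d is not a full upper triangle", n_edge)
  if (is.null(roi_ids)) roi_ids <- seq_len(n_roi)
  pairs <- upper_tri_pairs(as.integer(n_roi))
  pn <- permutation_null(deltas, groups, target_group, n_perm, seed)
  fdr <- fdr_bh(pn$p, q)
  out <- data.frame(
    roi_i = roi_ids[pairs[, 1]],
    roi_j = roi_ids[pairs[, 2]],
    t = pn$t_obs,
    p = pn$p,
    q = fdr$qvalues,
    direction = ifelse(pn$t_obs >= 0, "post>pre", "post<pre"),
    significant = fdr$reject
  )
  out[order(-abs(out$t)), ]
}
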