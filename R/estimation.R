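#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with the canonical parameters (peak
#' delay 6 s, undershoot delay 16 s, both dispersions 1, undershoot ratio
#' 1/6), peak-normalized to 1. The kernel value is 0 at t = 0 and peaks
#' near 5 s.
#'
#' @param tr sampling interval in seconds (> 0).
#' @param duration kernel length in seconds (default 32).
#' @param peak_delay,undershoot_delay gamma shape parameters (scale 1).
#' @param ratio undershoot amplitude relative to the peak.
#' @return numeric vector: the kernel sampled at `0, tr, 2 tr, ...`.
#' @export
double_gamma_hrf <- function(tr, duration = 32, peak_delay = 6,
                             undershoot_delay = 16, ratio = 1 / 6) {
  if (tr <= 0) stop_invalid("tr must be positive")
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = peak_delay, scale = 1) -
    ratio * stats::dgamma(t, shape = undershoot_delay, scale = 1)
  h / max(h)
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Power's formula: per frame, the sum of absolute frame-to-frame changes
#' of the three translations (mm) plus the three rotations (rad) converted
#' to arc length on a sphere of `radius_mm`. The first frame has FD 0 by
#' definition.
#'
#' @param motion numeric matrix with 6 columns: 3 translations (mm) then
#'   3 rotations (rad), one row per frame.
#' @param radius_mm rotation-to-translation conversion radius (default 50).
#' @return numeric vector of per-frame FD values (mm).
#' @export
framewise_displacement <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L || nrow(motion) < 1L || any(!is.finite(motion)))
    stop_invalid("motion must be a finite n x 6 matrix")
  if (nrow(motion) == 1L) return(0)
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' @noRd
boxcar_regressor <- function(onsets, durations, n_frames, tr, hrf_fine,
                             dt = 0.1) {
  t_end <- n_frames * tr
  fine <- numeric(ceiling(t_end / dt) + length(hrf_fine))
  for (k in seq_along(onsets)) {
    if (durations[k] <= 0) next
    i0 <- floor(onsets[k] / dt) + 1L
    i1 <- min(length(fine), ceiling((onsets[k] + durations[k]) / dt))
    if (i0 <= i1) fine[i0:i1] <- 1
  }
  conv <- stats::convolve(fine, rev(hrf_fine), type = "open")[seq_along(fine)]
  idx <- pmin(length(conv), floor((seq_len(n_frames) - 1) * tr / dt) + 1L)
  conv[idx]
}

#' @noRd
dct_drift <- function(n_frames, tr, cutoff_s = 100) {
  # discrete-cosine high-pass basis, SPM convention: K = floor(2 T / cutoff)
  t_total <- n_frames * tr
  k_max <- floor(2 * t_total / cutoff_s)
  if (k_max < 1L) return(NULL)
  t <- seq_len(n_frames) - 0.5
  sapply(seq_len(k_max), function(k) cos(pi * k * t / n_frames))
}

#' Build a least-squares-separate single-trial design matrix
#'
#' One design per trial of interest. The encoding design carries the six
#' task regressors of the single-trial model: (1) the 6 s trial of
#' interest, (2) all other trials, (3) rating periods (response time),
#' (4) the post-response remainders (6 s minus RT), (5) ITI fixations,
#' (6) instructions; the odd/even baseline block stays unmodeled. The
#' retrieval design likewise: (1) the source-judgment period of the trial
#' of interest (its RT), (2) all other source periods, (3) source
#' remainders, (4) item-recognition periods, (5) item remainders,
#' (6) instructions; the ITI stays unmodeled. All task columns are
#' HRF-convolved; six motion columns, one spike column per FD-flagged
#' frame, an intercept, and discrete-cosine drift regressors (100 s
#' high-pass, approximating a nonlinear high-pass filter) are appended.
#'
#' @param events run event table: data.frame with columns `onset`,
#'   `duration`, `trial_type`, `trial_index` (NA for non-trial rows).
#'   Recognized `trial_type` values -- encoding: `encode`, `rating`,
#'   `rating_remainder`, `iti`, `instruction`; retrieval: `source`,
#'   `source_remainder`, `item`, `item_remainder`, `instruction`.
#' @param trial_index which trial is the trial of interest.
#' @param phase `"encoding"` or `"retrieval"`.
#' @param n_frames frames in the run.
#' @param tr repetition time (s).
#' @param motion optional n_frames x 6 motion matrix (adds 6 columns).
#' @param fd_flags optional logical vector of FD-flagged frames (adds one
#'   spike column per flagged frame).
#' @param hp_cutoff_s drift high-pass cutoff in seconds (`NULL` disables).
#' @param hrf HRF kernel evaluator; default [double_gamma_hrf()].
#' @return object of class `lss_design`: list with `X` (frame x regressor
#'   matrix), `labels`, and `toi_col` (column of the trial of interest, 1).
#' @export
build_lss_design <- function(events, trial_index, phase = c("encoding", "retrieval"),
                             n_frames, tr, motion = NULL, fd_flags = NULL,
                             hp_cutoff_s = 100, hrf = double_gamma_hrf) {
  phase <- match.arg(phase)
  if (is.unsorted(events$onset)) stop_invalid("events must be sorted by onset")
  main_type <- if (phase == "encoding") "encode" else "source"
  pooled <- if (phase == "encoding")
    c("rating", "rating_remainder", "iti", "instruction")
  else
    c("source_remainder", "item", "item_remainder", "instruction")
  trial_rows <- events$trial_type == main_type
  if (!any(trial_rows & events$trial_index == trial_index, na.rm = TRUE))
    stop_invalid("trial %s not found among '%s' events", trial_index, main_type)

  dt <- 0.1
  hrf_fine <- hrf(dt)
  col <- function(rows) {
    if (!any(rows)) return(NULL)
    boxcar_regressor(events$onset[rows], events$duration[rows],
                     n_frames, tr, hrf_fine, dt)
  }
  toi <- trial_rows & !is.na(events$trial_index) &
    events$trial_index == trial_index
  others <- trial_rows & !toi
  if (all(events$duration[toi] <= 0))
    stop_invalid("trial of interest has zero modeled duration")
  cols <- list(trial_of_interest = col(toi))
  cols$other_trials <- col(others)
  for (ty in pooled) cols[[ty]] <- col(events$trial_type == ty)
  cols <- Filter(Negate(is.null), cols)
  X <- do.call(cbind, cols)
  labels <- names(cols)

  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_frames) stop_invalid("motion rows != n_frames")
    X <- cbind(X, motion)
    labels <- c(labels, paste0("motion_", 1:6))
  }
  if (!is.null(fd_flags) && any(fd_flags)) {
    spikes <- sapply(which(fd_flags), function(f) {
      v <- numeric(n_frames); v[f] <- 1; v
    })
    X <- cbind(X, spikes)
    labels <- c(labels, paste0("spike_", which(fd_flags)))
  }
  X <- cbind(X, 1)
  labels <- c(labels, "intercept")
  if (!is.null(hp_cutoff_s)) {
    dr <- dct_drift(n_frames, tr, hp_cutoff_s)
    if (!is.null(dr)) {
      X <- cbind(X, dr)
      labels <- c(labels, paste0("drift_", seq_len(ncol(dr))))
    }
  }
  colnames(X) <- labels
  structure(list(X = X, labels = labels, toi_col = 1L, tr = tr),
            class = "lss_design")
}

#' Fit one least-squares-separate trial GLM
#'
#' OLS fit of the design to every voxel time course; returns the beta and
#' t (beta / SE) of the trial-of-interest column. The t-map is the
#' recommended input to pattern similarity (noise-normalized); betas are
#' kept for diagnostics.
#'
#' @param series frame x voxel numeric matrix (a single voxel vector is
#'   accepted).
#' @param design an [build_lss_design()] result (or any list with `X` and
#'   `toi_col`).
#' @return object of class `trial_estimate`: list with `beta`, `t`
#'   (per-voxel), `df` (residual degrees of freedom).
#' @export
lss_fit <- function(series, design) {
  y <- as.matrix(series)
  X <- design$X
  if (nrow(y) != nrow(X)) stop_invalid("series frames != design frames")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
    stop_invalid("design is rank deficient; collinear columns: %s",
                 paste(design$labels[drop], collapse = ", "))
  }
  df <- nrow(X) - ncol(X)
  if (df <= 0) stop_invalid("no residual degrees of freedom")
  beta_all <- qr.coef(qx, y)
  resid <- y - X %*% beta_all
  sigma2 <- colSums(resid^2) / df
  xtxi_kk <- chol2inv(qr.R(qx))[design$toi_col, design$toi_col]
  beta <- beta_all[design$toi_col, ]
  se <- sqrt(sigma2 * xtxi_kk)
  t <- beta / se
  t[se == 0] <- 0
  structure(list(beta = unname(beta), t = unname(t), df = df),
            class = "trial_estimate")
}

#' Motion-based trial and run censoring
#'
#' Frames with FD above `fd_threshold` are censored. A trial is excluded
#' when any censored frame falls inside its modeled window
#' `[onset, onset + duration]`. The whole run is excluded when more than
#' `run_fraction` of its volumes are censored, or when the maximum absolute
#' head displacement exceeds half the voxel size.
#'
#' @param events event table; rows with non-NA `trial_index` and the main
#'   trial type define the trial windows.
#' @param fd per-frame framewise displacement (mm),
#'   see [framewise_displacement()].
#' @param motion optional motion matrix for the absolute-displacement rule
#'   (max abs translation, mm).
#' @param tr repetition time (s).
#' @param fd_threshold censoring threshold (default 0.9 mm).
#' @param run_fraction censored-fraction limit for run exclusion
#'   (default 0.20).
#' @param voxel_size_mm voxel size; absolute displacement beyond half of it
#'   excludes the run (default 2.5, so 1.25 mm).
#' @return object of class `censor_report`: list with `censored` (per-frame
#'   logical), `fd`, `trial_included` (named by trial index),
#'   `run_excluded`, `reason`.
#' @export
censor_trials <- function(events, fd, motion = NULL, tr,
                          fd_threshold = 0.9, run_fraction = 0.20,
                          voxel_size_mm = 2.5) {
  if (any(fd < 0)) stop_invalid("FD must be non-negative")
  censored <- fd > fd_threshold
  frame_t <- (seq_along(fd) - 1) * tr
  tr_rows <- !is.na(events$trial_index) &
    events$trial_type %in% c("encode", "source")
  idx <- events$trial_index[tr_rows]
  on <- events$onset[tr_rows]
  du <- events$duration[tr_rows]
  bad_t <- frame_t[censored]
  incl <- vapply(seq_along(idx), function(k)
    !any(bad_t >= on[k] & bad_t <= on[k] + du[k]), logical(1))
  names(incl) <- idx

  frac <- mean(censored)
  max_disp <- if (is.null(motion)) 0 else max(abs(as.matrix(motion)[, 1:3]))
  run_excluded <- FALSE; reason <- NA_character_
  if (frac > run_fraction) {
    run_excluded <- TRUE
    reason <- sprintf("censored fraction %.1f%% > %.0f%%",
                      100 * frac, 100 * run_fraction)
  } else if (max_disp > voxel_size_mm / 2) {
    run_excluded <- TRUE
    reason <- sprintf("absolute displacement %.2f mm > %.2f mm",
                      max_disp, voxel_size_mm / 2)
  }
  if (run_excluded) incl[] <- FALSE
  structure(list(censored = censored, fd = fd, trial_included = incl,
                 run_excluded = run_excluded, reason = reason),
            class = "censor_report")
}
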