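#' Build the event table for one synthetic run
#'
#' Encoding trial layout: 6 s encode period, then a rating window (response
#' at RT, remainder until 12 s), then an ITI; a 4 s instruction block opens
#' the run. Retrieval trial layout: item recognition (RT + remainder over
#' 6 s), then the source judgment (RT + remainder over 6 s), then an
#' unmodeled ITI.
#'
#' @param n_trials trials in the run.
#' @param phase `"encoding"` or `"retrieval"`.
#' @param tr repetition time (s) -- recorded, not used for timing.
#' @param iti_s inter-trial interval (s).
#' @param rt_s response times, recycled over trials (must be < 6).
#' @param instruction_s instruction duration at run start.
#' @param contexts per-trial context labels, recycled.
#' @return events data.frame (`onset`, `duration`, `trial_type`,
#'   `trial_index`, `context`), sorted by onset.
#' @export
make_run_events <- function(n_trials, phase = c("encoding", "retrieval"),
                            tr = 1.56, iti_s = 3, rt_s = 2,
                            instruction_s = 4,
                            contexts = c("spatial", "temporal")) {
  phase <- match.arg(phase)
  rt <- rep_len(rt_s, n_trials)
  if (any(rt <= 0 | rt >= 6)) stop_invalid("response times must be in (0, 6)")
  ctx <- rep_len(contexts, n_trials)
  rows <- list(data.frame(onset = 0, duration = instruction_s,
                          trial_type = "instruction", trial_index = NA_integer_,
                          context = NA_character_))
  t0 <- instruction_s + iti_s
  for (k in seq_len(n_trials)) {
    if (phase == "encoding") {
      rows[[length(rows) + 1L]] <- data.frame(
        onset = c(t0, t0 + 6, t0 + 6 + rt[k], t0 + 12),
        duration = c(6, rt[k], 6 - rt[k], iti_s),
        trial_type = c("encode", "rating", "rating_remainder", "iti"),
        trial_index = c(k, k, k, NA_integer_),
        context = c(ctx[k], ctx[k], ctx[k], NA_character_))
      t0 <- t0 + 12 + iti_s
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        onset = c(t0, t0 + rt[k], t0 + 6, t0 + 6 + rt[k]),
        duration = c(rt[k], 6 - rt[k], rt[k], 6 - rt[k]),
        trial_type = c("item", "item_remainder", "source", "source_remainder"),
        trial_index = c(k, k, k, k),
        context = c(NA_character_, NA_character_, ctx[k], ctx[k]))
      t0 <- t0 + 12 + iti_s
    }
  }
  ev <- do.call(rbind, rows)
  ev[order(ev$onset), ]
}

#' Generate one synthetic BOLD run with events and a motion trace
#'
#' The signal is a sum over trials of `amplitude x HRF-convolved boxcar`
#' on the trial's voxel template, plus a slow sinusoidal drift and white
#' noise, so the least-squares-separate estimator can be validated
#' end-to-end: with zero noise the fitted trial beta equals the planted
#' amplitude exactly. Motion is near zero by default; spike frames can be
#' injected to exercise FD censoring.
#'
#' @param n_trials trials in the run.
#' @param n_voxels voxels.
#' @param phase `"encoding"` or `"retrieval"`.
#' @param tr repetition time (s).
#' @param amplitudes planted per-trial response amplitudes (recycled).
#' @param template_mode `"shared"` (default): all trials in the run share
#'   one voxel response map, the regime in which the LS-S pooled
#'   other-trials column captures the other responses exactly and planted
#'   noiseless betas are recovered to machine precision; `"per_trial"`:
#'   each trial gets its own map, in which case LS-S is an approximation
#'   whose residual trial overlap contaminates the estimate slightly.
#' @param noise_sd voxel noise sd (0 = noiseless).
#' @param drift_amp amplitude of a slow additive drift.
#' @param motion_sd sd of small continuous motion (mm / rad).
#' @param spike_frames frame indices given a large displacement spike.
#' @param spike_mm spike translation size (mm); the default makes
#'   FD = 1.5 at the spiked frame.
#' @param seed integer seed.
#' @param ... passed to [make_run_events()].
#' @return list with `bold` (frame x voxel matrix), `events`, `motion`
#'   (frame x 6), `amplitudes`, `n_frames`, `tr`, `templates`
#'   (trial x voxel planted patterns).
#' @export
generate_bold_session <- function(n_trials = 5L, n_voxels = 30L,
                                  phase = "encoding", tr = 1.56,
                                  amplitudes = 1, noise_sd = 0,
                                  template_mode = c("shared", "per_trial"),
                                  drift_amp = 0, motion_sd = 0,
                                  spike_frames = integer(0), spike_mm = 0.75,
                                  seed = 1L, ...) {
  template_mode <- match.arg(template_mode)
  events <- make_run_events(n_trials, phase, tr = tr, ...)
  main_type <- if (phase == "encoding") "encode" else "source"
  toi <- events[events$trial_type == main_type, ]
  run_end <- max(events$onset + events$duration) + 20  # HRF tail
  n_frames <- ceiling(run_end / tr)
  set.seed(seed_stream(seed, "bold"))
  amps <- rep_len(amplitudes, n_trials)
  templates <- if (template_mode == "shared")
    matrix(stats::rnorm(n_voxels), n_trials, n_voxels, byrow = TRUE)
  else
    matrix(stats::rnorm(n_trials * n_voxels), n_trials, n_voxels)
  hrf_fine <- double_gamma_hrf(0.1)
  bold <- matrix(0, n_frames, n_voxels)
  for (k in seq_len(n_trials)) {
    reg <- boxcar_regressor(toi$onset[k], toi$duration[k], n_frames, tr,
                            hrf_fine)
    bold <- bold + (amps[k] * reg) %*% t(templates[k, ])
  }
  if (drift_amp > 0) {
    t_s <- (seq_len(n_frames) - 1) * tr
    bold <- bold + drift_amp * sin(2 * pi * t_s / 300)
  }
  if (noise_sd > 0)
    bold <- bold + matrix(stats::rnorm(n_frames * n_voxels, sd = noise_sd),
                          n_frames, n_voxels)
  motion <- matrix(stats::rnorm(n_frames * 6, sd = motion_sd), n_frames, 6)
  if (length(spike_frames)) {
    # sustained alternating steps: FD spikes exactly at the listed frames
    # while absolute displacement stays bounded by spike_mm
    bad <- sort(spike_frames[spike_frames >= 2 & spike_frames <= n_frames])
    sgn <- rep_len(c(1, -1), length(bad))
    for (k in seq_along(bad))
      motion[bad[k]:n_frames, 1] <- motion[bad[k]:n_frames, 1] +
        sgn[k] * spike_mm
  }
  list(bold = bold, events = events, motion = motion, amplitudes = amps,
       n_frames = n_frames, tr = tr, templates = templates)
}

#' Estimate every trial of a run with LS-S and censoring
#'
#' Convenience driver: computes FD, builds the censor report, fits one
#' least-squares-separate GLM per trial, and returns the trial-by-voxel
#' t-map and beta matrices with included flags.
#'
#' @param bold frame x voxel matrix.
#' @param events run event table (see [make_run_events()]).
#' @param motion frame x 6 motion matrix (or `NULL`).
#' @param phase `"encoding"` or `"retrieval"`.
#' @param tr repetition time (s).
#' @param ... passed to [censor_trials()] (thresholds) --
#'   `fd_threshold`, `run_fraction`, `voxel_size_mm`.
#' @return list with `t` and `beta` (trial x voxel matrices), `included`
#'   (per-trial flags), `censor` (the [censor_trials()] report).
#' @export
estimate_trials <- function(bold, events, motion = NULL,
                            phase = c("encoding", "retrieval"), tr, ...) {
  phase <- match.arg(phase)
  n_frames <- nrow(bold)
  fd <- if (is.null(motion)) numeric(n_frames)
        else framewise_displacement(motion)
  rep_c <- censor_trials(events, fd, motion, tr, ...)
  main_type <- if (phase == "encoding") "encode" else "source"
  trials <- sort(unique(events$trial_index[events$trial_type == main_type]))
  tmat <- bmat <- matrix(NA_real_, length(trials), ncol(bold))
  for (k in seq_along(trials)) {
    des <- build_lss_design(events, trials[k], phase, n_frames, tr,
                            motion = motion, fd_flags = rep_c$censored)
    fit <- lss_fit(bold, des)
    tmat[k, ] <- fit$t
    bmat[k, ] <- fit$beta
  }
  list(t = tmat, beta = bmat,
       included = unname(rep_c$trial_included[as.character(trials)]),
       censor = rep_c)
}
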