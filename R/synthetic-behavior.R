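#' Generate synthetic behavioral logs for a training study
#'
#' Emulates the four behavioral record types of a pre/post training study:
#'
#' * navigation transfer: exactly 20 trials per session; per-trial shortest
#'   and traveled path lengths with normalized errors following a decaying
#'   learning curve plus noise,
#' * verbal transfer: at most 5 recall trials per session on a 12-word
#'   list, stopping early on perfect recall,
#' * navigation training: per-day trials with shortest/traveled lengths
#'   whose excess error decays across days,
#' * verbal training: per-day adaptive list lengths that grow on success
#'   and shrink after repeated failure, recorded as daily maxima (the real
#'   schedule follows an unspecified power-law rule; here growth/shrink
#'   increments are explicit parameters).
#'
#' A training benefit is planted as a pre-to-post transfer improvement for
#' the trained group only: navigation training lowers the early-trial error
#' amplitude of the navigation transfer curve, verbal training raises the
#' per-trial recall gain of the verbal transfer task.
#'
#' @param design a [study_design()] (groups and n_per_group are used).
#' @param nav_improvement fractional reduction of the post-session
#'   early-error amplitude for the navigation group (0-1).
#' @param verbal_improvement additive increase of per-trial recall gain for
#'   the verbal-memory group at post.
#' @param nav_amp initial amplitude of the navigation transfer error curve
#'   (normalized error units).
#' @param nav_plateau asymptotic normalized error.
#' @param nav_decay per-trial exponential decay rate of the error curve.
#' @param nav_noise_sd trial noise sd on normalized errors (truncated at 0).
#' @param verbal_start mean words recalled on the first transfer trial.
#' @param verbal_gain mean additional words recalled per transfer trial.
#' @param verbal_noise_sd recall-count noise sd.
#' @param list_length transfer word-list length (recall is capped here).
#' @param n_days training days.
#' @param seed integer seed.
#' @return list of four data.frames: `navigation_transfer`
#'   (`participant, group, session, trial, shortest, traveled`),
#'   `verbal_transfer` (`participant, group, session, trial, list_length,
#'   n_correct`), `navigation_training` (`participant, group, day, trial,
#'   shortest, traveled`), `verbal_training` (`participant, group, day,
#'   max_words`).
#' @export
generate_behavior_logs <- function(design = study_design(),
                                   nav_improvement = 0.5,
                                   verbal_improvement = 1.0,
                                   nav_amp = 1.2, nav_plateau = 0.25,
                                   nav_decay = 0.15, nav_noise_sd = 0.15,
                                   verbal_start = 5, verbal_gain = 1,
                                   verbal_noise_sd = 1,
                                   list_length = 12L, n_days = 10L,
                                   seed = 1L) {
  if (nav_amp < 0 || nav_plateau < 0 || nav_decay < 0 || nav_noise_sd < 0 ||
      verbal_noise_sd < 0)
    stop_invalid("curve parameters must be non-negative")
  if (nav_improvement < 0 || nav_improvement > 1)
    stop_invalid("nav_improvement must be in [0, 1]")
  set.seed(seed_stream(seed, "behavior"))
  groups <- rep(design$groups, each = design$n_per_group)
  ids <- seq_along(groups)

  nav_tr <- list(); verb_tr <- list(); nav_day <- list(); verb_day <- list()
  for (p in ids) {
    g <- groups[p]
    # individual baselines
    amp_p <- nav_amp * exp(stats::rnorm(1, 0, 0.2))
    start_p <- max(1, verbal_start + stats::rnorm(1, 0, 1.5))
    for (s in design$sessions) {
      trained_nav <- g == "navigation" && s == "post"
      trained_verb <- g == "verbal_memory" && s == "post"
      amp <- amp_p * (1 - if (trained_nav) nav_improvement else 0)
      shortest <- stats::runif(20, 20, 60)
      err <- nav_plateau + amp * exp(-nav_decay * (0:19)) +
        pmax(stats::rnorm(20, 0, nav_noise_sd), -nav_plateau)
      err <- pmax(err, 0)
      nav_tr[[length(nav_tr) + 1L]] <- data.frame(
        participant = p, group = g, session = s, trial = 1:20,
        shortest = shortest, traveled = shortest * (1 + err))

      gain <- verbal_gain + if (trained_verb) verbal_improvement else 0
      rec <- integer(0)
      for (tr in 1:5) {
        mu <- start_p + gain * (tr - 1)
        nc <- round(mu + stats::rnorm(1, 0, verbal_noise_sd))
        nc <- max(0L, min(as.integer(list_length), as.integer(nc)))
        rec <- c(rec, nc)
        if (nc == list_length) break
      }
      verb_tr[[length(verb_tr) + 1L]] <- data.frame(
        participant = p, group = g, session = s, trial = seq_along(rec),
        list_length = as.integer(list_length), n_correct = rec)
    }
    # training logs only for the trained tasks
    if (g == "navigation") {
      for (d in seq_len(n_days)) {
        n_trial <- 12L
        shortest <- stats::runif(n_trial, 20, 60)
        e <- pmax(0.1 + amp_p * exp(-0.35 * (d - 1)) +
                    stats::rnorm(n_trial, 0, nav_noise_sd), 0)
        nav_day[[length(nav_day) + 1L]] <- data.frame(
          participant = p, group = g, day = d, trial = seq_len(n_trial),
          shortest = shortest, traveled = shortest * (1 + e))
      }
    }
    if (g == "verbal_memory") {
      ability <- start_p
      for (d in seq_len(n_days)) {
        len <- 3L; best <- 0L; fails <- 0L
        for (tr in 1:20) {
          p_success <- stats::plogis((ability - len) / 1.5)
          if (stats::runif(1) < p_success) {
            best <- max(best, len)
            len <- len + 1L
            fails <- 0L
          } else {
            fails <- fails + 1L
            if (fails >= 2L) { len <- max(1L, len - 1L); fails <- 0L }
          }
        }
        verb_day[[length(verb_day) + 1L]] <- data.frame(
          participant = p, group = g, day = d, max_words = best)
        ability <- ability + 0.8
      }
    }
  }
  list(navigation_transfer = do.call(rbind, nav_tr),
       verbal_transfer = do.call(rbind, verb_tr),
       navigation_training = do.call(rbind, nav_day),
       verbal_training = do.call(rbind, verb_day))
}

#' Per-participant transfer learning rates from behavior logs
#'
#' Applies [transfer_normalized_error()] + [navigation_learning_rate()] to
#' the navigation transfer log and [verbal_learning_rate()] to the verbal
#' transfer log, per participant and session.
#'
#' @param logs a [generate_behavior_logs()] result (or data.frames with the
#'   same columns read from CSV).
#' @return tidy data.frame: `participant`, `group`, `session`, `task`,
#'   `metric`, `value`.
#' @export
behavior_metric_table <- function(logs) {
  nav <- logs$navigation_transfer
  verb <- logs$verbal_transfer
  rows <- list()
  for (key in unique(paste(nav$participant, nav$session))) {
    sub <- nav[paste(nav$participant, nav$session) == key, ]
    sub <- sub[order(sub$trial), ]
    err <- transfer_normalized_error(sub$shortest, sub$traveled)
    lr <- navigation_learning_rate(err)
    rows[[length(rows) + 1L]] <- data.frame(
      participant = sub$participant[1], group = sub$group[1],
      session = sub$session[1], task = "navigation_transfer",
      metric = "learning_rate", value = lr$value)
  }
  for (key in unique(paste(verb$participant, verb$session))) {
    sub <- verb[paste(verb$participant, verb$session) == key, ]
    sub <- sub[order(sub$trial), ]
    lr <- verbal_learning_rate(sub$n_correct)
    rows[[length(rows) + 1L]] <- data.frame(
      participant = sub$participant[1], group = sub$group[1],
      session = sub$session[1], task = "verbal_transfer",
      metric = "learning_rate", value = lr$value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
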