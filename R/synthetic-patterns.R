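#' Generate trial-level voxel patterns for one participant (both sessions)
#'
#' Stands in for the single-trial t-maps a real pipeline would estimate.
#' Context templates are drawn once per participant and shared across
#' sessions, so pre/post comparisons are within-participant; session noise
#' and gains are independent draws. Trial gains are sampled per trial as
#' `1 + gain_sd * f`, where `f` across ROIs is `N(0, C)` for coupling matrix
#' `C`; planted effects add a shared latent factor to the two ROIs of an
#' edge, raising their effective gain coupling from `c` to
#' `c (1 - delta) + delta` for the matching (group, session, context) cell.
#'
#' @param design a [study_design()].
#' @param atlas a [generate_atlas()] result.
#' @param model a [generative_model()].
#' @param group this participant's training group.
#' @param participant_id integer id (enters the seed stream).
#' @param seed root seed.
#' @param phases which phases to generate (both by default; generating only
#'   `"encoding"` halves the cost of large simulations).
#' @return list with one `trial_pattern_set` per session, named by session.
#' @export
generate_participant_patterns <- function(design, atlas, model, group,
                                          participant_id, seed,
                                          phases = c("encoding", "retrieval")) {
  phases <- match.arg(phases, c("encoding", "retrieval"), several.ok = TRUE)
  if (!group %in% design$groups)
    stop_invalid("unknown group '%s'", group)
  templates <- make_templates(atlas, design$contexts,
                              seed_stream(seed, "templates", participant_id))
  out <- lapply(design$sessions, function(session) {
    generate_pattern_dataset(design, atlas, model, group, session,
                             templates = templates,
                             seed = seed_stream(seed, "patterns",
                                                participant_id, session),
                             participant_id = participant_id,
                             phases = phases)
  })
  names(out) <- design$sessions
  out
}

#' @noRd
make_templates <- function(atlas, contexts, seed) {
  set.seed(seed)
  lapply(seq_len(nrow(atlas)), function(r) {
    v <- atlas$n_voxels[r]
    tl <- lapply(contexts, function(ctx) {
      u <- stats::rnorm(v)
      u / sqrt(sum(u^2))
    })
    names(tl) <- contexts
    tl
  })
}

#' Generate one participant-session trial pattern set
#'
#' Lower-level entry used by [generate_participant_patterns()]; call it
#' directly to control templates or generate a single session.
#'
#' @inheritParams generate_participant_patterns
#' @param session session label.
#' @param templates per-ROI per-context unit-norm templates, or `NULL` to
#'   draw fresh ones from `seed`.
#' @return object of class `trial_pattern_set`: per phase, a trial metadata
#'   data.frame (`trial`, `run`, `context`, `correct`, `included`) and a
#'   list of trial-by-voxel pattern matrices, one per ROI.
#' @export
generate_pattern_dataset <- function(design, atlas, model, group, session,
                                     seed, templates = NULL,
                                     participant_id = NA_integer_,
                                     phases = c("encoding", "retrieval")) {
  phases <- match.arg(phases, c("encoding", "retrieval"), several.ok = TRUE)
  if (is.null(templates))
    templates <- make_templates(atlas, design$contexts,
                                seed_stream(seed, "templates"))
  if (length(templates) != nrow(atlas))
    stop_invalid("templates do not match the atlas")
  set.seed(seed)
  n_roi <- nrow(atlas)
  chol_c <- chol(model$coupling)
  eff <- active_effects(model$effects, group, session)

  res <- lapply(phases, function(phase) {
    meta <- trial_table(design, phase)
    n_tr <- nrow(meta)
    gains <- draw_gains(n_tr, n_roi, meta$context, chol_c, eff, model$gain_sd)
    pats <- lapply(seq_len(n_roi), function(r) {
      v <- atlas$n_voxels[r]
      tmpl <- do.call(rbind, lapply(meta$context, function(ctx) templates[[r]][[ctx]]))
      sig <- gains[, r] * (model$rho * sqrt(v)) * tmpl
      if (model$noise_sd > 0)
        sig <- sig + matrix(stats::rnorm(n_tr * v, sd = model$noise_sd), n_tr, v)
      sig
    })
    correct <- if (phase == "retrieval")
      stats::runif(n_tr) < model$p_correct else rep(TRUE, n_tr)
    meta$correct <- correct
    meta$included <- TRUE
    list(meta = meta, patterns = pats)
  })
  names(res) <- phases
  structure(res, class = "trial_pattern_set",
            group = group, session = session,
            participant_id = participant_id,
            roi_ids = atlas$roi_id)
}

#' @noRd
active_effects <- function(effects, group, session) {
  if (is.null(effects)) return(NULL)
  sel <- effects$group == group & effects$session == session
  if (!any(sel)) return(NULL)
  effects[sel, , drop = FALSE]
}

# Trial gains: base factor vector f ~ N(0, C) across ROIs (context-agnostic),
# then per planted edge a shared standard-normal latent h is mixed into both
# endpoint ROIs, f' = (f + a h) / sqrt(1 + a^2) with a^2 = delta / (1 - delta),
# which moves the pair correlation from c to c (1 - delta) + delta while
# preserving unit variance. Context-specific effects touch only trials of
# that context.
#' @noRd
draw_gains <- function(n_trials, n_roi, trial_context, chol_c, eff, gain_sd) {
  f <- matrix(stats::rnorm(n_trials * n_roi), n_trials, n_roi) %*% chol_c
  if (!is.null(eff)) {
    for (k in seq_len(nrow(eff))) {
      rows <- if (eff$context[k] == "all") seq_len(n_trials)
              else which(trial_context == eff$context[k])
      if (!length(rows)) next
      a <- sqrt(eff$delta[k] / (1 - eff$delta[k]))
      h <- stats::rnorm(length(rows))
      sc <- sqrt(1 + a^2)
      for (roi in c(eff$roi_i[k], eff$roi_j[k]))
        f[rows, roi] <- (f[rows, roi] + a * h) / sc
    }
  }
  1 + gain_sd * f
}

#' @export
print.trial_pattern_set <- function(x, ...) {
  cat("Trial pattern set: participant", attr(x, "participant_id"),
      sprintf("(%s, %s)\n", attr(x, "group"), attr(x, "session")))
  for (ph in names(x))
    cat(" ", ph, ":", nrow(x[[ph]]$meta), "trials x",
        length(x[[ph]]$patterns), "ROIs\n")
  invisible(x)
}

#' Write a trial pattern set to plain-text files
#'
#' One TSV per phase per ROI (`sub-<id>_ses-<s>_<phase>_roi-<id>.tsv`,
#' trials in rows, voxels in columns) plus a metadata TSV per phase. A
#' plain-text stand-in for a hierarchical array container.
#'
#' @param x a `trial_pattern_set`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_pattern_set <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pid <- attr(x, "participant_id"); ses <- attr(x, "session")
  roi_ids <- attr(x, "roi_ids")
  paths <- character(0)
  for (ph in names(x)) {
    stem <- sprintf("sub-%02d_ses-%s_%s", pid, ses, substr(ph, 1, 3))
    mpath <- file.path(dir, paste0(stem, "_events.tsv"))
    utils::write.table(x[[ph]]$meta, mpath, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, mpath)
    for (k in seq_along(x[[ph]]$patterns)) {
      p <- file.path(dir, sprintf("%s_roi-%03d.tsv", stem, roi_ids[k]))
      utils::write.table(x[[ph]]$patterns[[k]], p, sep = "\t",
                         row.names = FALSE, col.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
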