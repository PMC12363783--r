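#' Describe a pre/post training study design
#'
#' Captures the structure of a three-arm cognitive-training study with a
#' scanned source-memory task: three training groups, two scan sessions
#' (pre/post), and per session four encoding and four retrieval runs of
#' context-labeled trials (spatial vs temporal). Defaults reproduce the
#' full design: 24 participants per group (the power-analysis target),
#' 20 trials per encoding run and 25 per retrieval run, so a complete
#' participant-session contributes 80 encoding and 100 retrieval trials.
#'
#' @param n_per_group participants per training group.
#' @param groups training group labels.
#' @param sessions session labels, pre then post.
#' @param encoding_runs,retrieval_runs runs per phase.
#' @param trials_per_encoding_run,trials_per_retrieval_run trials per run.
#' @param contexts the two encoding contexts.
#' @param tr_seconds repetition time of the functional acquisition.
#' @param trial_duration_seconds modeled duration of the main trial period.
#' @return an object of class `study_design`.
#' @examples
#' d <- study_design()
#' d$encoding_runs * d$trials_per_encoding_run  # 80
#' @export
study_design <- function(n_per_group = 24L,
                         groups = c("navigation", "verbal_memory", "video_control"),
                         sessions = c("pre", "post"),
                         encoding_runs = 4L,
                         retrieval_runs = 4L,
                         trials_per_encoding_run = 20L,
                         trials_per_retrieval_run = 25L,
                         contexts = c("spatial", "temporal"),
                         tr_seconds = 1.56,
                         trial_duration_seconds = 6) {
  if (!is_count(n_per_group)) stop_invalid("n_per_group must be a positive integer")
  if (!is_count(encoding_runs) || !is_count(retrieval_runs))
    stop_invalid("run counts must be positive integers")
  if (!is_count(trials_per_encoding_run) || trials_per_encoding_run < 2)
    stop_invalid("trials_per_encoding_run must be >= 2")
  if (!is_count(trials_per_retrieval_run) || trials_per_retrieval_run < 2)
    stop_invalid("trials_per_retrieval_run must be >= 2")
  if (length(contexts) != 2L) stop_invalid("exactly two contexts are required")
  if (length(sessions) != 2L) stop_invalid("exactly two sessions are required")
  if (tr_seconds <= 0 || trial_duration_seconds <= 0)
    stop_invalid("durations must be positive")
  if (encoding_runs %% 2L != 0L)
    stop_invalid("encoding_runs must be even (runs are context-pure, balanced)")
  if (trials_per_retrieval_run %% 2L != 0L && trials_per_retrieval_run > 2L) {
    # retrieval runs mix contexts; keep them balanced within run where possible
    # (odd counts alternate the extra trial's context across runs)
  }
  structure(list(
    n_per_group = as.integer(n_per_group),
    groups = as.character(groups),
    sessions = as.character(sessions),
    encoding_runs = as.integer(encoding_runs),
    retrieval_runs = as.integer(retrieval_runs),
    trials_per_encoding_run = as.integer(trials_per_encoding_run),
    trials_per_retrieval_run = as.integer(trials_per_retrieval_run),
    contexts = as.character(contexts),
    tr_seconds = tr_seconds,
    trial_duration_seconds = trial_duration_seconds
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", length(x$groups), "groups x", x$n_per_group,
      "participants x", length(x$sessions), "sessions\n")
  cat("  encoding :", x$encoding_runs, "runs x", x$trials_per_encoding_run,
      "trials =", x$encoding_runs * x$trials_per_encoding_run, "trials\n")
  cat("  retrieval:", x$retrieval_runs, "runs x", x$trials_per_retrieval_run,
      "trials =", x$retrieval_runs * x$trials_per_retrieval_run, "trials\n")
  invisible(x)
}

#' Trial table for one phase of a session
#'
#' Encoding runs are context-pure and alternate spatial/temporal (the design
#' divides encoding runs equally between contexts); retrieval runs mix both
#' contexts, balanced within run.
#'
#' @param design a [study_design()].
#' @param phase `"encoding"` or `"retrieval"`.
#' @return data.frame with columns `trial`, `run`, `context`.
#' @export
trial_table <- function(design, phase = c("encoding", "retrieval")) {
  phase <- match.arg(phase)
  if (phase == "encoding") {
    n_runs <- design$encoding_runs
    per_run <- design$trials_per_encoding_run
    run_ctx <- rep(design$contexts, length.out = n_runs)
    ctx <- rep(run_ctx, each = per_run)
  } else {
    n_runs <- design$retrieval_runs
    per_run <- design$trials_per_retrieval_run
    half <- ceiling(per_run / 2)
    one_run <- rep(design$contexts, times = c(half, per_run - half))
    ctx <- rep(one_run, times = n_runs)
  }
  data.frame(
    trial = seq_len(n_runs * per_run),
    run = rep(seq_len(n_runs), each = per_run),
    context = ctx,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic ROI atlas
#'
#' Emulates a study ROI graph: an ordered set of parcels with a guaranteed
#' minimum size. The default full-scale atlas has 242 ROIs of at least 30
#' voxels, matching the node-count contract of a Neurosynth-masked Schaefer
#' parcellation.
#'
#' @param n_rois number of ROIs.
#' @param min_voxels,max_voxels inclusive bounds for per-ROI voxel counts
#'   (drawn uniformly).
#' @param seed integer seed; identical seeds give byte-identical atlases.
#' @return object of class `synthetic_atlas`: a data.frame with columns
#'   `roi_id`, `n_voxels`.
#' @examples
#' atl <- generate_atlas(242, seed = 1)
#' nrow(atl); min(atl$n_voxels)
#' @export
generate_atlas <- function(n_rois = 242L, min_voxels = 30L, max_voxels = 120L,
                           seed = 1L) {
  if (!is_count(n_rois)) stop_invalid("n_rois must be a positive integer")
  if (!is_count(min_voxels)) stop_invalid("min_voxels must be >= 1")
  if (max_voxels < min_voxels) stop_invalid("max_voxels must be >= min_voxels")
  set.seed(seed_stream(seed, "atlas"))
  nv <- if (max_voxels == min_voxels) rep.int(as.integer(min_voxels), n_rois)
        else sample(seq.int(min_voxels, max_voxels), n_rois, replace = TRUE)
  out <- data.frame(roi_id = seq_len(n_rois), n_voxels = as.integer(nv))
  class(out) <- c("synthetic_atlas", "data.frame")
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Render an atlas as an integer label volume
#'
#' Packs each ROI's voxels consecutively into the smallest cubic 3D grid
#' that holds them; 0 marks background. Pattern analyses are voxel-order
#' invariant, so no spatial smoothness is modeled.
#'
#' @param atlas a [generate_atlas()] result.
#' @return a 3D integer array with values in `{0} U roi_id`.
#' @export
atlas_volume <- function(atlas) {
  total <- sum(atlas$n_voxels)
  side <- ceiling(total^(1 / 3))
  vol <- integer(side^3)
  vol[seq_len(total)] <- rep.int(atlas$roi_id, atlas$n_voxels)
  array(vol, dim = c(side, side, side))
}

#' Build a random PSD inter-ROI coupling matrix
#'
#' Couplings control how strongly trial-level gains are shared between ROI
#' pairs. A low-rank factor construction guarantees a valid correlation
#' matrix with heterogeneous non-negative off-diagonal entries.
#'
#' @param n_rois matrix dimension.
#' @param n_factors rank of the shared-factor part.
#' @param strength in `[0, 1)`: overall magnitude of off-diagonal coupling.
#' @param seed integer seed.
#' @return symmetric `n_rois x n_rois` matrix, unit diagonal, entries in `[0, 1]`.
#' @export
random_coupling <- function(n_rois, n_factors = 3L, strength = 0.5, seed = 1L) {
  if (strength < 0 || strength >= 1) stop_invalid("strength must be in [0, 1)")
  if (strength == 0) return(diag(n_rois))
  set.seed(seed_stream(seed, "coupling"))
  lam <- matrix(abs(stats::rnorm(n_rois * n_factors)), n_rois, n_factors)
  s <- lam %*% t(lam)
  c0 <- stats::cov2cor(s + diag(n_rois) * max(diag(s)) * (1 - strength) / strength)
  diag(c0) <- 1
  c0
}

#' Specify the generative model for synthetic voxel patterns
#'
#' Each ROI holds a unit-norm voxel template per context. On trial t the ROI
#' responds with `gain[t] * rho * template * sqrt(n_vox) + noise`, where the
#' trial gains fluctuate around 1 and are correlated across ROIs according
#' to `coupling`; informational connectivity detects exactly this shared
#' trial-to-trial representational fidelity. Planted effects strengthen the
#' gain coupling of chosen edges for chosen (group, session) cells, moving
#' the effective coupling `c` to `c * (1 - delta) + delta`.
#'
#' @param atlas a [generate_atlas()] result.
#' @param coupling symmetric unit-diagonal matrix with entries in `[0, 1]`,
#'   or `NULL` for the identity (independent ROIs).
#' @param rho within-ROI pattern reliability in `[0, 1]`: amplitude of the
#'   context template relative to unit voxel noise.
#' @param gain_sd standard deviation of the multiplicative trial gain.
#' @param noise_sd voxel noise standard deviation (0 gives noiseless
#'   patterns).
#' @param effects `NULL` or data.frame with columns `group`, `session`,
#'   `roi_i`, `roi_j`, `delta` and optionally `context` (default `"all"`);
#'   `delta` in `[0, 1)`.
#' @param p_correct retrieval accuracy probability (Bernoulli per trial).
#' @return object of class `generative_model`.
#' @export
generative_model <- function(atlas, coupling = NULL, rho = 0.7, gain_sd = 0.5,
                             noise_sd = 1, effects = NULL, p_correct = 0.85) {
  n <- nrow(atlas)
  if (is.null(coupling)) coupling <- diag(n)
  coupling <- as.matrix(coupling)
  if (nrow(coupling) != n || ncol(coupling) != n)
    stop_invalid("coupling must be %d x %d to match the atlas", n, n)
  if (max(abs(coupling - t(coupling))) > 1e-12)
    stop_invalid("coupling must be symmetric")
  if (any(abs(diag(coupling) - 1) > 1e-12))
    stop_invalid("coupling must have unit diagonal")
  if (min(coupling) < 0 || max(coupling) > 1)
    stop_invalid("coupling entries must lie in [0, 1]")
  if (rho < 0 || rho > 1) stop_invalid("rho must be in [0, 1]")
  if (gain_sd < 0 || noise_sd < 0) stop_invalid("sds must be non-negative")
  if (p_correct <= 0 || p_correct > 1) stop_invalid("p_correct must be in (0, 1]")
  if (!is.null(effects)) {
    need <- c("group", "session", "roi_i", "roi_j", "delta")
    if (!all(need %in% names(effects)))
      stop_invalid("effects needs columns: %s", paste(need, collapse = ", "))
    if (is.null(effects$context)) effects$context <- "all"
    bad <- !(effects$roi_i %in% atlas$roi_id) | !(effects$roi_j %in% atlas$roi_id)
    if (any(bad))
      stop_invalid("effects reference unknown ROI ids: rows %s",
                   paste(which(bad), collapse = ", "))
    if (any(effects$delta < 0 | effects$delta >= 1))
      stop_invalid("effect delta must lie in [0, 1)")
    base <- coupling[cbind(effects$roi_i, effects$roi_j)]
    if (any(base * (1 - effects$delta) + effects$delta > 1))
      stop_invalid("planted delta pushes a coupling above 1")
  }
  structure(list(
    coupling = coupling, rho = rho, gain_sd = gain_sd, noise_sd = noise_sd,
    effects = effects, p_correct = p_correct
  ), class = "generative_model")
}
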