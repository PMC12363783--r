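#' Simulate a full ICM study and return per-participant edge changes
#'
#' Runs the generative model through the real analysis path -- patterns ->
#' within-context RSMs (cross-run pairs) -> ICMs -> pre-to-post edge
#' changes -- for every participant of every group. This is the engine
#' behind null-calibration and power studies.
#'
#' @param design a [study_design()].
#' @param atlas a [generate_atlas()] result.
#' @param model a [generative_model()].
#' @param phase phase analyzed (`"encoding"` or `"retrieval"`).
#' @param context RSM context type: `"all"` (combined ICM), `"spatial"`,
#'   or `"temporal"`.
#' @param seed root seed.
#' @param keep_icms also return the per-participant ICMs (needed by the
#'   distance analysis); off by default to save memory.
#' @return list with `deltas` (participants x edges matrix of post - pre
#'   Fisher-z changes), `groups` (vector), and optionally `icms` (list per
#'   participant: per session, per context ICM).
#' @export
simulate_icm_study <- function(design, atlas, model, phase = "encoding",
                               context = "all", seed = 1L,
                               keep_icms = FALSE) {
  groups <- rep(design$groups, each = design$n_per_group)
  n <- length(groups)
  contexts <- unique(c(context, if (keep_icms) c("spatial", "temporal")))
  deltas <- vector("list", n)
  icms <- if (keep_icms) vector("list", n) else NULL
  for (p in seq_len(n)) {
    pat <- generate_participant_patterns(design, atlas, model, groups[p], p,
                                         seed, phases = phase)
    per_session <- lapply(pat, function(ps) {
      out <- lapply(contexts, function(ctx)
        compute_icm(rsm_stack(ps, phase = phase, context = ctx)))
      names(out) <- contexts
      out
    })
    deltas[[p]] <- edge_change(per_session[[1]][[context]],
                               per_session[[2]][[context]])
    if (keep_icms) icms[[p]] <- per_session
  }
  out <- list(deltas = delta_matrix(deltas), groups = groups)
  if (keep_icms) out$icms <- icms
  out
}

#' Assemble and validate a pipeline configuration
#'
#' All knobs of the end-to-end synthetic pipeline in one validated object.
#' Defaults mirror the full study design (24 per group, 4 + 4 runs, 80
#' encoding / 100 retrieval trials, FDR q 0.05); scale `n_per_group`,
#' `n_rois` and `n_perm` down for quick runs.
#'
#' @param seed root seed; every stage derives its own substream from it.
#' @param design a [study_design()].
#' @param n_rois,min_voxels,max_voxels synthetic atlas parameters.
#' @param coupling_strength off-diagonal magnitude of the baseline coupling
#'   matrix (0 = independent ROIs).
#' @param rho,gain_sd,noise_sd,p_correct generative-model parameters
#'   (see [generative_model()]).
#' @param effects planted effect table or `NULL`.
#' @param phase,context analysis phase and RSM context type.
#' @param target_group contrast target (vs pooled remaining groups).
#' @param n_perm permutation draws.
#' @param q FDR threshold.
#' @param distance_group group for the profile-distance pre/post test
#'   (`NULL` skips the distance stage).
#' @param distance_metric `"pearson"`, `"spearman"`, or `"both"`.
#' @param behavior `TRUE` to generate behavior logs and metrics.
#' @param output_dir directory for result files (`NULL` = in-memory only).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            design = study_design(),
                            n_rois = 242L, min_voxels = 30L, max_voxels = 120L,
                            coupling_strength = 0, rho = 0.7, gain_sd = 0.5,
                            noise_sd = 1, p_correct = 0.85,
                            effects = NULL,
                            phase = "encoding", context = "all",
                            target_group = "verbal_memory",
                            n_perm = 10000L, q = 0.05,
                            distance_group = NULL,
                            distance_metric = "both",
                            behavior = TRUE,
                            output_dir = NULL) {
  if (!inherits(design, "study_design")) stop_invalid("design must be a study_design")
  if (!is_count(n_rois) || !is_count(n_perm))
    stop_invalid("n_rois and n_perm must be positive integers")
  if (q <= 0 || q > 1) stop_invalid("q must be in (0, 1]")
  if (!target_group %in% design$groups)
    stop_invalid("target_group '%s' not among design groups", target_group)
  if (!is.null(distance_group) && !distance_group %in% design$groups)
    stop_invalid("distance_group '%s' not among design groups", distance_group)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Keys mirror the arguments of [pipeline_config()]; a `design` sub-object
#' holds [study_design()] arguments; an `effects` sub-array holds planted
#' effect rows.
#'
#' @param path JSON file path.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  if (!is.null(raw$design)) raw$design <- do.call(study_design, raw$design)
  if (!is.null(raw$effects)) raw$effects <- as.data.frame(raw$effects)
  do.call(pipeline_config, raw)
}

#' Run the end-to-end synthetic pipeline
#'
#' Stages: atlas + model construction, pattern generation for every
#' participant and session, RSM and ICM computation, pre-to-post edgewise
#' group contrast with permutation null and FDR, optional connectivity-
#' profile distance test, optional behavior metrics -- plus a manifest
#' recording seeds and counts at every stage. When `config$output_dir` is
#' set, result tables are written as CSV and the manifest as JSON.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_result`: list with `edge_table`,
#'   `distance_table` (or NULL), `behavior_table` (or NULL), `deltas`,
#'   `groups`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_invalid("config must be a pipeline_config (see pipeline_config())")
  design <- config$design
  atlas <- generate_atlas(config$n_rois, config$min_voxels, config$max_voxels,
                          seed = seed_stream(config$seed, "atlas"))
  coupling <- if (config$coupling_strength > 0)
    random_coupling(config$n_rois, strength = config$coupling_strength,
                    seed = seed_stream(config$seed, "coupling"))
  else NULL
  model <- generative_model(atlas, coupling, rho = config$rho,
                            gain_sd = config$gain_sd,
                            noise_sd = config$noise_sd,
                            effects = config$effects,
                            p_correct = config$p_correct)
  need_icms <- !is.null(config$distance_group)
  sim <- simulate_icm_study(design, atlas, model, phase = config$phase,
                            context = config$context,
                            seed = seed_stream(config$seed, "patterns"),
                            keep_icms = need_icms)
  deltas <- sim$deltas
  edge_table <- edge_contrast_table(deltas, sim$groups, config$target_group,
                                    n_perm = config$n_perm,
                                    seed = seed_stream(config$seed, "perm"),
                                    q = config$q, roi_ids = atlas$roi_id)

  distance_table <- NULL
  if (need_icms) {
    in_g <- sim$groups == config$distance_group
    metrics <- if (config$distance_metric == "both") c("pearson", "spearman")
               else config$distance_metric
    distance_table <- do.call(rbind, lapply(metrics, function(met) {
      dmat <- lapply(c(1, 2), function(si)
        do.call(rbind, lapply(which(in_g), function(p)
          profile_distances(sim$icms[[p]][[si]]$spatial,
                            sim$icms[[p]][[si]]$temporal, met))))
      tab <- distance_session_test(dmat[[1]], dmat[[2]], q = config$q)
      tab$metric <- met
      tab
    }))
  }

  behavior_table <- NULL
  if (isTRUE(config$behavior)) {
    logs <- generate_behavior_logs(design,
                                   seed = seed_stream(config$seed, "behavior"))
    behavior_table <- behavior_metric_table(logs)
  }

  enc_n <- design$encoding_runs * design$trials_per_encoding_run
  ret_n <- design$retrieval_runs * design$trials_per_retrieval_run
  manifest <- list(
    package = "icnet",
    version = as.character(utils::packageVersion("icnet")),
    seed = config$seed,
    n_participants = length(sim$groups),
    groups = as.list(table(sim$groups)),
    n_rois = nrow(atlas),
    trials_per_participant_session = list(encoding = enc_n, retrieval = ret_n),
    phase = config$phase, context = config$context,
    edges_tested = nrow(edge_table),
    n_perm = config$n_perm, q = config$q,
    edges_significant = sum(edge_table$significant),
    distance_rois_significant =
      if (is.null(distance_table)) NA else sum(distance_table$significant),
    behavior_rows = if (is.null(behavior_table)) NA else nrow(behavior_table)
  )

  res <- structure(list(edge_table = edge_table,
                        distance_table = distance_table,
                        behavior_table = behavior_table,
                        deltas = deltas, groups = sim$groups,
                        atlas = atlas, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) write_results(res, config$output_dir)
  res
}

#' Write pipeline result tables and manifest to a directory
#'
#' @param res a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths written.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "edge_table.csv")
  utils::write.csv(res$edge_table, paths[1], row.names = FALSE)
  if (!is.null(res$distance_table)) {
    p <- file.path(dir, "distance_table.csv")
    utils::write.csv(res$distance_table, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(res$behavior_table)) {
    p <- file.path(dir, "behavior_metrics.csv")
    utils::write.csv(res$behavior_table, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(res$manifest, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

#' Human-readable pipeline report
#'
#' @param res a `pipeline_result` from [run_pipeline()].
#' @param max_edges maximum edges listed.
#' @return character vector of Markdown lines (also usable with
#'   `writeLines`).
#' @export
pipeline_report <- function(res, max_edges = 10L) {
  m <- res$manifest
  lines <- c(
    "# Informational connectivity pipeline report", "",
    sprintf("- participants: %d (%s)", m$n_participants,
            paste(names(m$groups), unlist(m$groups), sep = "=",
                  collapse = ", ")),
    sprintf("- ROIs: %d; edges tested: %d; permutations: %d; FDR q: %g",
            m$n_rois, m$edges_tested, m$n_perm, m$q),
    sprintf("- trial estimates per participant-session: %d encoding, %d retrieval",
            m$trials_per_participant_session$encoding,
            m$trials_per_participant_session$retrieval),
    "", "## Edgewise group contrast", "")
  sig <- res$edge_table[res$edge_table$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    lines <- c(lines, "no edges survive FDR")
  } else {
    top <- utils::head(sig, max_edges)
    lines <- c(lines,
               "| roi_i | roi_j | t | p | q | direction |",
               "|---|---|---|---|---|---|",
               sprintf("| %d | %d | %.3f | %.4g | %.4g | %s |",
                       top$roi_i, top$roi_j, top$t, top$p, top$q,
                       top$direction))
  }
  if (!is.null(res$distance_table)) {
    lines <- c(lines, "", "## Connectivity-profile distance (pre vs post)", "")
    sigd <- res$distance_table[res$distance_table$significant, , drop = FALSE]
    if (nrow(sigd) == 0) {
      lines <- c(lines, "no ROIs survive FDR")
    } else {
      lines <- c(lines,
                 "| roi | metric | mean change | t | q |", "|---|---|---|---|---|",
                 sprintf("| %d | %s | %.4f | %.3f | %.4g |",
                         sigd$roi, sigd$metric, sigd$mean_change, sigd$t,
                         sigd$q))
    }
  }
  if (!is.null(res$behavior_table)) {
    bt <- res$behavior_table
    agg <- stats::aggregate(value ~ group + session + task, bt, mean)
    agg <- agg[order(agg$task, agg$group, agg$session), ]
    lines <- c(lines, "", "## Behavioral learning rates (group means)", "",
               "| task | group | session | mean learning rate |",
               "|---|---|---|---|",
               sprintf("| %s | %s | %s | %.4f |",
                       agg$task, agg$group, agg$session, agg$value))
  }
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  writeLines(pipeline_report(x))
  invisible(x)
}
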