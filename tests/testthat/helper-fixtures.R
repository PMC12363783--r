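# Shared fixtures and independent oracles (built in code, no stored data).

# Hand-built pattern set: n_runs runs, trials split evenly, contexts
# alternating within run, random patterns. Phase defaults to encoding.
toy_pattern_set <- function(n_roi = 5, n_runs = 3, n_trials = 6, n_vox = 8,
                            seed = 42, phase = "encoding") {
  set.seed(seed)
  per_run <- n_trials / n_runs
  meta <- data.frame(
    trial = seq_len(n_trials),
    run = rep(seq_len(n_runs), each = per_run),
    context = rep_len(c("spatial", "temporal"), n_trials),
    correct = TRUE, included = TRUE)
  pats <- lapply(seq_len(n_roi), function(r)
    matrix(rnorm(n_trials * n_vox), n_trials, n_vox))
  out <- list(list(meta = meta, patterns = pats))
  names(out) <- phase
  class(out) <- "trial_pattern_set"
  attr(out, "roi_ids") <- seq_len(n_roi)
  out
}

# Brute-force RSM oracle: explicit double loop over all trial pairs.
rsm_oracle <- function(x, meta, context = "all") {
  keep <- meta$included
  if (context != "all") keep <- keep & meta$context == context
  x <- x[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  n <- nrow(meta)
  z <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && meta$run[i] != meta$run[j])
        z[i, j] <- atanh(cor(x[i, ], x[j, ]))
    }
  }
  z
}

# Brute-force ICM oracle from a list of oracle RSM z-matrices: nested loop
# over ROI pairs, values collected over the common valid mask in row-major
# upper-triangle order.
icm_oracle <- function(zs) {
  n_roi <- length(zs)
  n <- nrow(zs[[1]])
  valid <- !is.na(zs[[1]])
  for (z in zs) valid <- valid & !is.na(z)
  icm <- matrix(NA_real_, n_roi, n_roi)
  for (a in seq_len(n_roi - 1)) {
    for (b in (a + 1):n_roi) {
      va <- vb <- numeric(0)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (valid[i, j]) {
            va <- c(va, zs[[a]][i, j])
            vb <- c(vb, zs[[b]][i, j])
          }
        }
      }
      icm[a, b] <- icm[b, a] <- atanh(cor(va, vb))
    }
  }
  icm
}

# Minimal encoding events table: k trials of 6 s spaced `gap_s` apart,
# starting after a 4 s instruction block.
toy_events <- function(n_trials, gap_s = 15, rt = 2) {
  make_run_events(n_trials, "encoding", iti_s = gap_s - 12, rt_s = rt)
}

# Edge column index in the package's row-major upper-triangle edge order.
edge_index <- function(n_roi, i, j) {
  ut <- upper_tri_idx(n_roi)
  which(ut[, 1] == i & ut[, 2] == j)
}
upper_tri_idx <- function(n) {
  cbind(rep(seq_len(n - 1), times = (n - 1):1),
        unlist(lapply(seq_len(n - 1), function(k) (k + 1):n)))
}
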