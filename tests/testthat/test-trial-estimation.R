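test_that("double-gamma HRF has the canonical shape", {
  h <- double_gamma_hrf(tr = 0.01)
  t <- seq(0, 32, by = 0.01)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  expect_lt(abs(t[which.max(h)] - 5), 0.02)   # canonical peak near 5 s
  # exactly one sign change: positive lobe then undershoot
  s <- sign(h[abs(h) > 1e-10])
  expect_equal(sum(diff(s) != 0), 1)
  expect_error(double_gamma_hrf(0), "positive")
})

test_that("framewise displacement follows Power's formula", {
  z <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(z), rep(0, 10))
  # single 0.5 mm x-translation step at frame 4
  m <- z; m[4:10, 1] <- 0.5
  expect_equal(framewise_displacement(m), c(rep(0, 3), 0.5, rep(0, 6)))
  # 0.01 rad pitch step only -> 0.01 * 50 = 0.5
  m <- z; m[6:10, 4] <- 0.01
  expect_equal(framewise_displacement(m)[6], 0.5)
  # combined: sums of absolute differences
  m <- z; m[2, ] <- c(0.1, -0.2, 0.3, 0.001, -0.002, 0.003)
  expect_equal(framewise_displacement(m)[2], 0.6 + 50 * 0.006)
  expect_error(framewise_displacement(matrix(0, 5, 5)), "n x 6")
})

test_that("LS-S designs carry the six task regressors and split only the trial columns", {
  ev <- make_run_events(6, "encoding", rt_s = 2)
  n_frames <- 80
  d1 <- build_lss_design(ev, 1, "encoding", n_frames, tr = 1.56)
  d3 <- build_lss_design(ev, 3, "encoding", n_frames, tr = 1.56)
  expect_identical(d1$labels[1:6],
                   c("trial_of_interest", "other_trials", "rating",
                     "rating_remainder", "iti", "instruction"))
  # two designs differ only in the 1/2 column split; their sum is identical
  expect_equal(d1$X[, 1] + d1$X[, 2], d3$X[, 1] + d3$X[, 2],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(d1$X[, 1], d3$X[, 1])))
  # remaining columns identical
  expect_equal(d1$X[, -(1:2)], d3$X[, -(1:2)], tolerance = 1e-12)
  # retrieval layout
  evr <- make_run_events(4, "retrieval", rt_s = 1.5)
  dr <- build_lss_design(evr, 2, "retrieval", n_frames, tr = 1.56)
  expect_identical(dr$labels[1:6],
                   c("trial_of_interest", "other_trials", "source_remainder",
                     "item", "item_remainder", "instruction"))
  # no FD flags -> no spike columns; flags add exactly one column each
  expect_false(any(grepl("spike", d1$labels)))
  flags <- rep(FALSE, n_frames); flags[c(10, 40)] <- TRUE
  dspk <- build_lss_design(ev, 1, "encoding", n_frames, tr = 1.56,
                           fd_flags = flags)
  expect_equal(sum(grepl("spike", dspk$labels)), 2)
  expect_error(build_lss_design(ev, 99, "encoding", n_frames, 1.56),
               "not found")
})

test_that("lss_fit recovers planted amplitudes and is scale-equivariant", {
  # shared response map: the pooled other-trials column captures the other
  # responses exactly, so noiseless recovery is exact
  run <- generate_bold_session(n_trials = 4, n_voxels = 12, noise_sd = 0,
                               amplitudes = 2, seed = 8)
  est <- estimate_trials(run$bold, run$events, motion = NULL,
                         phase = "encoding", tr = run$tr)
  planted <- run$amplitudes * run$templates
  expect_lt(max(abs(est$beta - planted)), 1e-8)
  # single trial: exact recovery holds with a trial-specific map too
  one <- generate_bold_session(n_trials = 1, n_voxels = 8, noise_sd = 0,
                               amplitudes = 1, template_mode = "per_trial",
                               seed = 12)
  est1 <- estimate_trials(one$bold, one$events, phase = "encoding",
                          tr = one$tr)
  expect_lt(max(abs(est1$beta - one$templates)), 1e-8)
  # doubling the series doubles beta, leaves t unchanged
  ev <- run$events
  noisy <- generate_bold_session(n_trials = 4, n_voxels = 12, noise_sd = 0.5,
                                 seed = 9)
  des <- build_lss_design(noisy$events, 2, "encoding", noisy$n_frames,
                          noisy$tr)
  f1 <- lss_fit(noisy$bold, des)
  f2 <- lss_fit(2 * noisy$bold, des)
  expect_equal(f2$beta, 2 * f1$beta, tolerance = 1e-10)
  expect_equal(f2$t, f1$t, tolerance = 1e-10)
})

test_that("pure-noise t-values are centred near zero", {
  set.seed(21)
  ev <- make_run_events(5, "encoding")
  n_frames <- 75
  des <- build_lss_design(ev, 2, "encoding", n_frames, tr = 1.56)
  y <- matrix(rnorm(n_frames * 500), n_frames, 500)
  f <- lss_fit(y, des)
  expect_lt(abs(mean(f$t)), 0.15)
})

test_that("LS-S equals the all-trials GLM when trial columns are orthogonal", {
  # hand-built designs with disjoint (hence orthogonal) trial supports
  set.seed(13)
  n <- 120; k <- 4
  r <- matrix(0, n, k)
  for (j in 1:k) r[((j - 1) * 30 + 1):((j - 1) * 30 + 10), j] <- 1
  y <- matrix(rnorm(n * 30), n, 30)
  all_fit <- qr.coef(qr(r), y)
  for (j in 1:k) {
    xs <- cbind(r[, j], rowSums(r[, -j, drop = FALSE]))
    fit <- lss_fit(y, list(X = xs, toi_col = 1L, labels = c("toi", "other")))
    expect_equal(fit$beta, unname(all_fit[j, ]), tolerance = 1e-6)
  }
})

test_that("beta RMSE scales linearly with noise sd", {
  sds <- c(0.5, 1, 2, 4)
  rmse <- sapply(sds, function(s) {
    errs <- sapply(1:8, function(k) {
      run <- generate_bold_session(n_trials = 3, n_voxels = 10, noise_sd = s,
                                   amplitudes = 1.5,
                                   seed = 100 * s + k)
      est <- estimate_trials(run$bold, run$events, phase = "encoding",
                             tr = run$tr)
      mean((est$beta - run$amplitudes * run$templates)^2)
    })
    sqrt(mean(errs))
  })
  expect_gt(cor(rmse, sds), 0.99)
})

test_that("censoring excludes trials and runs per the motion rules", {
  ev <- make_run_events(5, "encoding", iti_s = 3)
  n_frames <- 70
  tr <- 1.56
  fd <- rep(0, n_frames)
  rep0 <- censor_trials(ev, fd, tr = tr)
  expect_true(all(rep0$trial_included))
  expect_false(rep0$run_excluded)
  # one censored frame inside trial 3's window only
  toi <- ev[ev$trial_type == "encode", ]
  frame_in_3 <- floor((toi$onset[3] + 2) / tr) + 1
  fd1 <- fd; fd1[frame_in_3] <- 1.2
  rep1 <- censor_trials(ev, fd1, tr = tr)
  expect_identical(unname(rep1$trial_included), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_false(rep1$run_excluded)
  # monotone: extra censored frames never un-exclude a trial
  fd2 <- fd1; fd2[frame_in_3 + 30] <- 1.2
  rep2 <- censor_trials(ev, fd2, tr = tr)
  expect_true(all(rep2$trial_included[!rep1$trial_included] == FALSE))
  # 21% of frames censored -> run excluded, all trials flagged
  fd3 <- fd; fd3[seq_len(ceiling(0.21 * n_frames))] <- 1.0
  rep3 <- censor_trials(ev, fd3, tr = tr)
  expect_true(rep3$run_excluded)
  expect_match(rep3$reason, "censored fraction")
  expect_false(any(rep3$trial_included))
  # absolute displacement beyond half a voxel excludes the run
  motion <- matrix(0, n_frames, 6); motion[50, 1] <- 1.3
  rep4 <- censor_trials(ev, fd, motion, tr = tr)
  expect_true(rep4$run_excluded)
  expect_match(rep4$reason, "absolute displacement")
})

test_that("injected motion spikes are flagged at the right frames", {
  run <- generate_bold_session(n_trials = 3, n_voxels = 5,
                               spike_frames = c(20, 35), spike_mm = 1.5,
                               seed = 4)
  fd <- framewise_displacement(run$motion)
  expect_equal(which(fd > 0.9), c(20, 35))
  expect_equal(fd[20], 1.5, tolerance = 1e-12)
})
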