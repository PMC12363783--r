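test_that("atlas generation honours bounds, determinism, and errors", {
  atl <- generate_atlas(242, 30, 120, seed = 1)
  expect_equal(nrow(atl), 242)
  expect_gte(min(atl$n_voxels), 30)
  expect_lte(max(atl$n_voxels), 120)
  expect_identical(atl, generate_atlas(242, 30, 120, seed = 1))
  expect_false(identical(atl$n_voxels,
                         generate_atlas(242, 30, 120, seed = 2)$n_voxels))
  one <- generate_atlas(1, 30, 30, seed = 0)
  expect_identical(one$n_voxels, 30L)
  expect_error(generate_atlas(0), "positive")
  expect_error(generate_atlas(5, 40, 30), ">= min_voxels")
  vol <- atlas_volume(one)
  expect_setequal(unique(as.vector(vol)), c(0L, 1L))
  expect_equal(sum(vol == 1), 30)
})

test_that("study design counts and trial tables match the full design", {
  d <- study_design()
  expect_equal(d$encoding_runs * d$trials_per_encoding_run, 80)
  expect_equal(d$retrieval_runs * d$trials_per_retrieval_run, 100)
  tt <- trial_table(d, "encoding")
  expect_equal(nrow(tt), 80)
  # encoding runs are context-pure and balanced across runs
  by_run <- table(tt$run, tt$context)
  expect_true(all(rowSums(by_run > 0) == 1))
  expect_equal(sum(tt$context == "spatial"), 40)
  # retrieval runs mix contexts
  tr <- trial_table(d, "retrieval")
  expect_equal(nrow(tr), 100)
  expect_true(all(table(tr$run, tr$context) > 0))
  expect_error(study_design(trials_per_encoding_run = 1), ">= 2")
})

test_that("noiseless patterns with full reliability correlate perfectly within context", {
  atlas <- generate_atlas(3, 10, 12, seed = 5)
  design <- study_design(n_per_group = 1, trials_per_encoding_run = 4,
                         trials_per_retrieval_run = 4)
  model <- generative_model(atlas, rho = 1, gain_sd = 0.2, noise_sd = 0)
  ps <- generate_pattern_dataset(design, atlas, model, "navigation", "pre",
                                 seed = 3)
  meta <- ps$encoding$meta
  for (r in 1:3) {
    x <- ps$encoding$patterns[[r]]
    same_ctx <- outer(meta$context, meta$context, "==")
    cc <- cor(t(x))
    expect_true(all(abs(cc[same_ctx & upper.tri(cc)] - 1) < 1e-10))
  }
})

test_that("pattern generation is deterministic and validates its effect table", {
  atlas <- generate_atlas(4, 10, 12, seed = 5)
  design <- study_design(trials_per_encoding_run = 4,
                         trials_per_retrieval_run = 4)
  model <- generative_model(atlas)
  a <- generate_participant_patterns(design, atlas, model, "navigation", 1, 7)
  b <- generate_participant_patterns(design, atlas, model, "navigation", 1, 7)
  expect_identical(a, b)
  expect_error(
    generative_model(atlas, effects = data.frame(
      group = "navigation", session = "post", roi_i = 1, roi_j = 9,
      delta = 0.3)),
    "unknown ROI")
  expect_error(
    generative_model(atlas, effects = data.frame(
      group = "navigation", session = "post", roi_i = 1, roi_j = 2,
      delta = 1.2)),
    "delta")
})

test_that("observed edge change grows monotonically with planted coupling", {
  # property: Spearman rho > 0.9 between planted coupling level and the
  # seed-averaged ICM edge z across 5 levels x 20 seeds
  atlas <- generate_atlas(6, 25, 35, seed = 2)
  design <- study_design(trials_per_encoding_run = 10)
  levels <- c(0, 0.2, 0.4, 0.6, 0.8)
  mean_z <- sapply(levels, function(d) {
    model <- if (d == 0) generative_model(atlas) else
      generative_model(atlas, effects = data.frame(
        group = "verbal_memory", session = "post",
        roi_i = 2, roi_j = 5, delta = d))
    zs <- sapply(1:20, function(s) {
      ps <- generate_pattern_dataset(design, atlas, model, "verbal_memory",
                                     "post", seed = 1000 + s,
                                     phases = "encoding")
      icm <- compute_icm(rsm_stack(ps, "encoding", "all"))
      icm[2, 5]
    })
    mean(zs)
  })
  expect_gt(cor(mean_z, levels, method = "spearman"), 0.9)
})

test_that("behavior logs obey their construction contracts", {
  d <- study_design(n_per_group = 3)
  logs <- generate_behavior_logs(d, seed = 5)
  nav <- logs$navigation_transfer
  expect_true(all(table(nav$participant, nav$session) == 20))
  expect_true(all(nav$traveled >= 0))
  verb <- logs$verbal_transfer
  expect_lte(max(table(verb$participant, verb$session)), 5)
  expect_true(all(verb$n_correct <= verb$list_length))
  # zero-noise improving navigator: errors monotonically non-increasing
  quiet <- generate_behavior_logs(d, nav_noise_sd = 0, seed = 6)
  one <- quiet$navigation_transfer
  one <- one[one$participant == 1 & one$session == "pre", ]
  err <- transfer_normalized_error(one$shortest, one$traveled)
  expect_true(all(diff(err) <= 1e-12))
  # flat verbal learner: learning rate exactly 0
  flat <- generate_behavior_logs(d, verbal_gain = 0, verbal_improvement = 0,
                                 verbal_noise_sd = 0, seed = 7)
  fv <- flat$verbal_transfer
  fv1 <- fv[fv$participant == 1 & fv$session == "pre", ]
  expect_equal(verbal_learning_rate(fv1$n_correct)$value, 0)
  expect_error(generate_behavior_logs(d, nav_amp = -1), "non-negative")
  # determinism
  expect_identical(logs, generate_behavior_logs(d, seed = 5))
})

test_that("planted training benefit yields the group x session interaction", {
  d <- study_design()  # full 24/group, the size the planted effect is stated at
  hits_nav <- hits_verb <- logical(100)
  for (s in seq_len(100)) {
    logs <- generate_behavior_logs(d, seed = 300 + s)
    tab <- behavior_metric_table(logs)
    for (task in c("navigation_transfer", "verbal_transfer")) {
      sub <- tab[tab$task == task, ]
      wide <- merge(sub[sub$session == "pre", c("participant", "group", "value")],
                    sub[sub$session == "post", c("participant", "value")],
                    by = "participant")
      delta <- wide$value.y - wide$value.x
      trained <- wide$group == if (task == "navigation_transfer")
        "navigation" else "verbal_memory"
      tt <- t.test(delta[trained], delta[!trained])
      hit <- tt$p.value < 0.05 && mean(delta[trained]) > mean(delta[!trained])
      if (task == "navigation_transfer") hits_nav[s] <- hit else hits_verb[s] <- hit
    }
  }
  expect_gte(mean(hits_nav), 0.8)
  expect_gte(mean(hits_verb), 0.8)
})

test_that("pattern sets round-trip through plain-text files", {
  atlas <- generate_atlas(2, 8, 8, seed = 1)
  design <- study_design(trials_per_encoding_run = 3,
                         trials_per_retrieval_run = 3)
  model <- generative_model(atlas)
  ps <- generate_pattern_dataset(design, atlas, model, "navigation", "pre",
                                 seed = 1, participant_id = 1L)
  dir <- withr::local_tempdir()
  paths <- write_pattern_set(ps, dir)
  expect_true(all(file.exists(paths)))
  back <- as.matrix(read.delim(grep("enc_roi-001", paths, value = TRUE),
                               header = FALSE))
  expect_equal(unname(back), unname(ps$encoding$patterns[[1]]),
               tolerance = 1e-10)
})
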