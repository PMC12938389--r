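test_that("cohort spec validation names the offending field", {
  expect_error(cohort_spec(n_exercise = 0), "n_exercise")
  expect_error(cohort_spec(effect_size_d = -1), "effect_size_d")
  expect_error(cohort_spec(sampling_rate_hz = 0), "sampling_rate_hz")
  expect_error(cohort_spec(effect_conditions = "nope"),
               "effect_conditions")
  expect_error(cohort_spec(effect_regions = "occipital"),
               "effect_regions")
})

test_that("cohort counts, labels and epoch geometry follow the cohort specification", {
  sp <- tiny_spec(seed = 1)
  co <- generate_cohort(sp)
  expect_length(co, 14)
  g <- vapply(co, `[[`, "", "group_label")
  expect_equal(sum(g == "exercise"), 8)
  expect_equal(sum(g == "non_exercise"), 6)
  es <- co[[1]]$epoch_sets[["affective_compatible"]]
  expect_equal(dim(es$data)[3], round(1.5 * 64))
  expect_equal(es$channel_names, unlist(region_map(), use.names = FALSE))
  expect_setequal(names(co[[1]]$epoch_sets), iat_conditions())
  # epochs are artifact-free and in a plausible microvolt range
  peaks <- vapply(co, function(p)
    max(abs(p$epoch_sets[[1]]$data)), numeric(1))
  expect_true(all(peaks <= 100))
  expect_true(all(peaks > 5))
})

test_that("same seed reproduces a bit-identical cohort; participants are stable under enlargement", {
  a <- generate_cohort(tiny_spec(seed = 42))
  b <- generate_cohort(tiny_spec(seed = 42))
  expect_identical(a, b)
  c2 <- generate_cohort(tiny_spec(seed = 43))
  expect_false(identical(a[[1]]$epoch_sets, c2[[1]]$epoch_sets))
  # enlarging the cohort leaves existing participants untouched
  big <- cohort_spec(n_exercise = 10, n_nonexercise = 6,
                     effect_size_d = 0, sampling_rate_hz = 64,
                     n_trials_per_block = 3, n_practice_per_block = 2,
                     seed = 42)
  d <- generate_cohort(big)
  expect_identical(a[[1]], d[[1]])
  expect_identical(a[[5]], d[[5]])
})

test_that("condition-subset cohorts reproduce the matching full-cohort epochs", {
  full <- generate_cohort(tiny_spec(seed = 7))
  sub <- generate_cohort(tiny_spec(
    seed = 7, conditions = "affective_incompatible"))
  expect_named(sub[[1]]$epoch_sets, "affective_incompatible")
  expect_identical(sub[[3]]$epoch_sets$affective_incompatible,
                   full[[3]]$epoch_sets$affective_incompatible)
})

test_that("group labels are reproduced from the exercise reports by the MET rule", {
  co <- generate_cohort(tiny_spec(seed = 3))
  for (p in co)
    expect_equal(assign_group(p$exercise_report)$label, p$group_label)
})

test_that("trial logs have the configured block structure", {
  sp <- cohort_spec(seed = 2, sampling_rate_hz = 64)
  prof <- c(sp$behavior, list(n_trials_per_block = 72,
                              n_practice_per_block = 24))
  tl <- generate_trial_log(prof, seed = 11)
  for (it in c("affective", "instrumental"))
    for (b in c("compatible", "incompatible")) {
      blk <- tl[tl$iat_type == it & tl$block == b, ]
      expect_equal(nrow(blk), 96)
      expect_equal(sum(!blk$practice), 72)
    }
  # error_rate = 0, fast_rate = 0, miss_rate = 0: nothing filtered
  prof0 <- modifyList(prof, list(error_rate = 0, fast_rate = 0,
                                 miss_rate = 0))
  tl0 <- generate_trial_log(prof0, seed = 12)
  f <- filter_trials(tl0[tl0$iat_type == "affective", ])
  expect_true(f$participant_ok)
  expect_equal(nrow(f$retained), 144)
})

test_that("a zero block shift yields near-zero mean D-scores", {
  prof <- modifyList(behavior_defaults(),
                     list(rt_shift = 0, n_trials_per_block = 36,
                          n_practice_per_block = 0))
  ds <- vapply(1:200, function(i) {
    tl <- generate_trial_log(prof, seed = 5000 + i)
    score_iat(tl[tl$iat_type == "affective", ])$d_score
  }, numeric(1))
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.05)
  # and the default positive shift gives positive D on average
  ds2 <- vapply(1:50, function(i) {
    tl <- generate_trial_log(modifyList(prof, list(rt_shift = 80)),
                             seed = 6000 + i)
    score_iat(tl[tl$iat_type == "affective", ])$d_score
  }, numeric(1))
  expect_gt(mean(ds2, na.rm = TRUE), 0.2)
})

test_that("exercise reports respect the group definition", {
  for (i in 1:20) {
    rn <- generate_exercise_report("non_exercise", seed = i)
    expect_equal(compute_met_minutes(rn)$mvpa_total, 0)
    re <- generate_exercise_report("exercise", seed = i)
    expect_gt(compute_met_minutes(re)$mvpa_total, 0)
  }
})

test_that("unknown condition labels are rejected", {
  prof <- c(signal_defaults(),
            list(sampling_rate_hz = 64, n_epochs = 1,
                 mod_depth = matrix(0.5, 4, 5,
                                    dimnames = list(iat_conditions(),
                                                    names(region_map())))))
  expect_error(generate_eeg_epochs(prof, "weird", 1), "condition")
})

test_that("pure constant-envelope tone reaches the envelope-entropy maximum", {
  prof <- c(modifyList(signal_defaults(),
                       list(amp_theta = 0, amp_beta = 0, noise_sd = 0,
                            ch_noise_sd = 0, mod_epoch_sd = 0)),
            list(sampling_rate_hz = 500, n_epochs = 1,
                 mod_depth = matrix(0, 4, 5,
                                    dimnames = list(iat_conditions(),
                                                    names(region_map())))))
  es <- generate_eeg_epochs(prof, "affective_compatible", seed = 9)
  h <- envelope_entropy(es$data[1, 1, ])
  expect_gt(h, 0.99 * log(750))
})

test_that("envelope entropy decreases with the burstiness (modulation depth) parameter", {
  cfg <- entropy_config()
  hs <- vapply(c(0.1, 0.5, 0.9), function(m) {
    prof <- c(signal_defaults(),
              list(sampling_rate_hz = 64, n_epochs = 30,
                   mod_depth = matrix(m, 4, 5,
                                      dimnames = list(iat_conditions(),
                                                      names(region_map())))))
    es <- generate_eeg_epochs(prof, "affective_compatible", seed = 77)
    mean(vapply(seq_len(30), function(e)
      envelope_entropy(es$data[e, 1, ], cfg), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(hs) < 0))
})

test_that("generator calibration: realized standardized envelope-entropy difference tracks the nominal effect size", {
  # effect-region-averaged envelope entropy per participant,
  # standardized difference pooled over Monte-Carlo cohorts
  reps <- 60
  ds <- vapply(seq_len(reps), function(r) {
    sp <- cohort_spec(effect_size_d = 1.5, sampling_rate_hz = 64,
                      n_trials_per_block = 6, seed = 7000 + r,
                      conditions = "affective_incompatible")
    co <- generate_cohort(sp)
    ft <- compute_feature_table(co, metrics = "envelope")
    eff <- ft[ft$region %in% c("frontal", "fronto_central", "central"), ]
    v <- tapply(eff$value, eff$participant_id, mean)
    g <- setNames(vapply(co, `[[`, "", "group_label"),
                  vapply(co, `[[`, "", "participant_id"))[names(v)]
    n1 <- sum(g == "exercise"); n2 <- sum(g == "non_exercise")
    (mean(v[g == "exercise"]) - mean(v[g == "non_exercise"])) /
      sqrt(((n1 - 1) * var(v[g == "exercise"]) +
              (n2 - 1) * var(v[g == "non_exercise"])) / (n1 + n2 - 2))
  }, numeric(1))
  expect_lt(abs(mean(ds) - 1.5), 0.3)
})

test_that("planted effect raises exercise-group envelope entropy only in effect cells", {
  # monotonicity of the realized group difference in effect_size_d,
  # pooled over several small cohorts per grid point
  cfg <- entropy_config()
  gap <- function(d) {
    diffs <- vapply(1:6, function(r) {
      sp <- tiny_spec(seed = 800 + r, d = d,
                      conditions = "affective_incompatible")
      co <- generate_cohort(sp)
      ft <- compute_feature_table(co, metrics = "envelope")
      eff <- ft[ft$region %in% c("frontal", "fronto_central", "central"), ]
      v <- tapply(eff$value, eff$participant_id, mean)
      g <- vapply(co, `[[`, "", "group_label")
      names(g) <- vapply(co, `[[`, "", "participant_id")
      mean(v[g[names(v)] == "exercise"]) -
        mean(v[g[names(v)] == "non_exercise"])
    }, numeric(1))
    mean(diffs)
  }
  gaps <- vapply(c(0, 1, 2.5), gap, numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_lt(abs(gaps[1]), 0.02) # null case: no group difference
  # no planted difference in a non-effect condition
  sp <- tiny_spec(seed = 901, d = 2.5,
                  conditions = "instrumental_compatible")
  co <- generate_cohort(sp)
  ft <- compute_feature_table(co, metrics = "envelope")
  v <- tapply(ft$value, ft$participant_id, mean)
  g <- vapply(co, `[[`, "", "group_label")
  names(g) <- vapply(co, `[[`, "", "participant_id")
  expect_lt(abs(mean(v[g[names(v)] == "exercise"]) -
                mean(v[g[names(v)] == "non_exercise"])), 0.03)
})
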