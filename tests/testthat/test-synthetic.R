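test_that("default design yields the full session layout", {
  des <- synthetic_design()
  eff <- group_effects()
  s <- generate_subject(des, eff, "HC", seed = 7)
  expect_equal(n_trials(s), 416)                      # 13 runs x 32 stimuli
  expect_true(all(table(s$stimulus_id) == 13))        # 13 repetition trials
  expect_equal(dim(s$data)[2], 63)
  expect_equal(length(s$times_ms), 1080)              # [-100, 800) at 1200 Hz
  expect_equal(s$times_ms[1], -100)
  expect_equal(sum(s$class_label == "animate"), 16 * 13)
})

test_that("generation is deterministic given the seed", {
  des <- small_design()
  eff <- group_effects()
  a <- generate_subject(des, eff, "MCI", seed = 11)
  b <- generate_subject(des, eff, "MCI", seed = 11)
  expect_identical(a$data, b$data)
  expect_identical(a$stimulus_id, b$stimulus_id)
  c <- generate_subject(des, eff, "MCI", seed = 12)
  expect_false(identical(a$data, c$data))
})

test_that("generator validates latencies and noise", {
  des <- small_design()
  expect_error(group_effects(onset_ms = 300, peak_ms = 200))
  expect_error(group_effects(noise_sd = 0))
  bad <- group_effects(onset_ms = 700, peak_ms = 900)
  expect_error(generate_subject(des, bad, "HC", 1), "window")
})

test_that("zero-amplitude effects produce pure noise at chance decoding", {
  des <- small_design(n_runs = 4, n_stim = 8, n_ch = 8)
  s <- generate_subject(des, no_signal_effects(), "HC", seed = 3)
  # noise statistics
  expect_lt(abs(mean(s$data)), 0.02)      # ~5 SE of the mean of N(0,1) noise
  expect_equal(sd(s$data), 1, tolerance = 0.01)
  acc <- decode_timepoint(s, 250, decoder_config(n_repetitions = 40, seed = 5))
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("cohorts have the requested composition and derived seeds", {
  des <- small_design(n_runs = 2, n_stim = 4, n_ch = 4)
  cohort <- generate_cohort(des, group_effects(), n_hc = 22, n_mci = 18,
                            seed = 1)
  expect_length(cohort, 40)
  groups <- vapply(cohort, `[[`, "", "group")
  expect_equal(sum(groups == "HC"), 22)
  expect_equal(sum(groups == "MCI"), 18)
  # reproducible and distinct per subject
  cohort2 <- generate_cohort(des, group_effects(), 22, 18, seed = 1)
  expect_identical(cohort[[5]]$data, cohort2[[5]]$data)
  expect_false(identical(cohort[[1]]$data, cohort[[2]]$data))
  expect_error(generate_cohort(des, group_effects(), n_hc = 1, n_mci = 5))
})

test_that("run dropout shortens sessions for four subjects", {
  des <- small_design(n_runs = 13, n_stim = 4, n_ch = 4)
  cohort <- generate_cohort(des, group_effects(), 4, 4, seed = 2,
                            run_dropout = TRUE)
  runs <- vapply(cohort, function(s) n_trials(s) / 4, numeric(1))
  expect_equal(sort(runs), sort(c(rep(13, 4), 10, 10, 12, 12)))
})

test_that("mean-matched effects equalise the mean evoked response exactly", {
  des <- small_design()
  # stimulus-level patterns are shared between groups but do not cancel in
  # the per-class contrast, so measure the divergence angle without them
  eff <- group_effects(mean_matched = TRUE, pattern_divergence = 0.7,
                       stimulus_amplitude = 0)
  hc <- evoked_template(des, eff, "HC")
  mci <- evoked_template(des, eff, "MCI")
  expect_lt(max(abs(hc - mci)), 1e-10)
  # ... while the class-contrast patterns differ by the requested angle
  con_hc <- evoked_template(des, eff, "HC", "animate") -
    evoked_template(des, eff, "HC", "inanimate")
  con_mci <- evoked_template(des, eff, "MCI", "animate") -
    evoked_template(des, eff, "MCI", "inanimate")
  pk <- which.max(colSums(con_hc^2))
  v1 <- con_hc[, pk]; v2 <- con_mci[, pk]
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(ang, 0.7 * 90, tolerance = 1e-6)
})

test_that("peak decoding accuracy is non-decreasing in signal amplitude", {
  des <- small_design(n_runs = 5, n_stim = 8, n_ch = 8)
  peaks <- vapply(c(0, 0.6, 2), function(a) {
    s <- generate_subject(des, quiet_effects(amplitude = c(HC = a, MCI = a)),
                          "HC", seed = 21)
    decode_timepoint(s, 250, decoder_config(n_repetitions = 25, seed = 4))
  }, numeric(1))
  expect_true(all(diff(peaks) >= -0.05))
  expect_gt(peaks[3], peaks[1] + 0.2)
})

test_that("continuous sessions carry events, blinks and the design layout", {
  des <- small_design(n_runs = 2, n_stim = 8, n_ch = 16)
  eff <- quiet_effects()
  raw <- generate_continuous_session(des, eff, "HC", blink_rate = 10,
                                     seed = 6)
  expect_equal(nrow(raw$data), 16 + 1 + 3)
  expect_equal(nrow(raw$events), 2 * 8)
  expect_equal(sum(raw$channel_types == "ref"), 1)
  # blink transients dominate the EOG channels
  eog <- raw$data[raw$channel_types == "eog", ]
  expect_gt(max(abs(eog)), 8)
  # blink_rate 0: EOG contains only noise
  raw0 <- generate_continuous_session(des, eff, "HC", blink_rate = 0,
                                      seed = 6)
  eog0 <- raw0$data[raw0$channel_types == "eog", ]
  expect_lt(max(abs(eog0)), 6)
  expect_equal(sd(eog0), 1, tolerance = 0.05)
  # epoching the continuous output reproduces the epoched trial count
  ep <- extract_epochs(raw, window_ms = c(-100, 800))
  expect_equal(n_trials(ep), n_trials(generate_subject(des, eff, "HC", 6)))
})

test_that("AR(1) noise keeps its marginal SD and adds autocorrelation", {
  des <- small_design(n_runs = 2, n_stim = 4, n_ch = 4)
  s <- generate_subject(des, no_signal_effects(), "HC", 1)
  sa <- generate_subject(des, quiet_effects(amplitude = c(HC = 0, MCI = 0),
                                            stimulus_amplitude = 0, ar1 = 0.8),
                         "HC", 1)
  expect_equal(sd(sa$data), 1, tolerance = 0.05)
  ac <- function(x) mean(apply(x$data[, 1, ], 1, function(v)
    cor(v[-1], v[-length(v)])))
  expect_lt(abs(ac(s)), 0.1)
  expect_gt(ac(sa), 0.6)
})
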