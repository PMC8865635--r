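test_that("average re-reference zeroes the scalp-channel sum and drops the reference", {
  des <- small_design(n_runs = 1, n_stim = 4, n_ch = 16)
  raw <- generate_continuous_session(des, quiet_effects(), "HC",
                                     blink_rate = 0, seed = 1)
  expect_equal(nrow(raw$data), 20)                     # 16 + ref + 3 EOG
  rr <- rereference_average(raw)
  expect_equal(nrow(rr$data), 19)
  expect_false(any(rr$channel_types == "ref"))
  sums <- colSums(rr$data[rr$channel_types == "eeg", ])
  expect_lt(max(abs(sums)), 1e-9)
  # constant-valued channels collapse to zero
  raw$data[raw$channel_types == "eeg", ] <- 3
  expect_lt(max(abs(rereference_average(raw)$data[1:16, ])), 1e-12)
  raw$channel_types[raw$channel_types == "ref"] <- "eeg"
  expect_error(rereference_average(raw), "reference")
})

test_that("ICA removes the blink component and spares blink-free data", {
  des <- small_design(n_runs = 3, n_stim = 8, n_ch = 16)
  eff <- quiet_effects()
  raw <- generate_continuous_session(des, eff, "HC", blink_rate = 20,
                                     seed = 2)
  rr <- rereference_average(raw)
  front <- which(rr$channel_types == "eeg")[1:5]
  eog <- which(rr$channel_types == "eog")
  max_cor <- function(r) max(abs(cor(t(r$data[front, ]), t(r$data[eog, ]))))
  pre <- max_cor(rr)
  cleaned <- remove_eog_component(rr, seed = 3)
  expect_lt(max_cor(cleaned), pre)
  expect_gt(pre, 0.5)                                  # blinks were there
  info <- attr(cleaned, "eog_component")
  expect_gt(info$max_abs_cor, 0.8)

  # blink-free input: removing one component barely changes the data
  raw0 <- generate_continuous_session(des, eff, "HC", blink_rate = 0,
                                      seed = 2)
  rr0 <- rereference_average(raw0)
  cl0 <- remove_eog_component(rr0, seed = 3)
  rel <- sd(cl0$data[rr0$channel_types == "eeg", ] -
              rr0$data[rr0$channel_types == "eeg", ]) /
    sd(rr0$data[rr0$channel_types == "eeg", ])
  expect_lt(rel, 0.35)

  # zero-variance EOG: warn and no-op
  rr0$data[eog, ] <- 0
  expect_warning(same <- remove_eog_component(rr0, seed = 3), "EOG")
  expect_identical(same$data, rr0$data)
})

test_that("epoching follows the half-open window convention", {
  des <- small_design(n_runs = 2, n_stim = 8, n_ch = 8)
  raw <- generate_continuous_session(des, quiet_effects(), "HC", 0, seed = 4)
  ep <- extract_epochs(rereference_average(raw), window_ms = c(-100, 800))
  expect_equal(n_trials(ep), 16)
  expect_equal(length(ep$times_ms), 90)                # [-100, 800) at 100 Hz
  expect_equal(ep$times_ms[1], -100)
  expect_lt(max(ep$times_ms), 800)
  expect_true(any(ep$times_ms == 0))                   # t = 0 on the post side
  # empty event list -> empty dataset
  e0 <- extract_epochs(raw, events = raw$events[0, ], window_ms = c(-100, 800))
  expect_equal(n_trials(e0), 0)
  # out-of-bounds events are dropped with a message
  ev <- raw$events
  ev$sample[1] <- 2
  expect_message(e1 <- extract_epochs(raw, ev, c(-100, 800)), "dropped")
  expect_equal(n_trials(e1), 15)
  # acquisition/target-rate arithmetic over [-100, 800)
  expect_length(epoch_sample_range(c(-100, 800), 1200)$times_ms, 1080)
  expect_length(epoch_sample_range(c(-100, 800), 1000)$times_ms, 900)
})

test_that("baseline normalisation is exact and idempotent", {
  set.seed(9)
  ep <- manual_epochs(array(rnorm(20 * 4 * 50, mean = 3, sd = 2),
                            c(20, 4, 50)))
  bn <- baseline_normalize(ep)
  bl <- bn$times_ms < 0
  mus <- apply(bn$data[, , bl], c(1, 2), mean)
  sds <- apply(bn$data[, , bl], c(1, 2), sd)
  expect_lt(max(abs(mus)), 1e-12)
  expect_lt(max(abs(sds - 1)), 1e-12)
  bn2 <- baseline_normalize(bn)
  expect_equal(bn2$data, bn$data, tolerance = 1e-12)
  # constant epochs: SD guard kicks in, output all zero
  cep <- manual_epochs(array(5, c(2, 2, 30)))
  expect_warning(cz <- baseline_normalize(cep), "zero baseline SD")
  expect_true(all(cz$data == 0))
})

test_that("the 50 Hz low-pass has the right pass/stop behaviour and zero phase", {
  f <- 1200; nt <- 1200
  t_s <- (0:(nt - 1)) / f
  mk <- function(sig) {
    d <- array(0, c(1, 1, nt)); d[1, 1, ] <- sig
    eeg_epochs(d, (t_s - 0.1) * 1000, f, "Ch01", 1L, "animate")
  }
  amp <- function(x) diff(range(x$data[1, 1, 200:1000]))
  s10 <- lowpass_filter(mk(sin(2 * pi * 10 * t_s)), 50)
  expect_equal(amp(s10) / 2, 1, tolerance = 0.01)
  s100 <- lowpass_filter(mk(sin(2 * pi * 100 * t_s)), 50)
  expect_lt(amp(s100) / 2, 0.1)
  dc <- lowpass_filter(mk(rep(1, nt)), 50)
  expect_lt(max(abs(dc$data - 1)), 1e-3)   # unit DC gain up to edge residue
  # zero phase: a smooth pulse keeps its peak sample (+- 1)
  pulse <- exp(-((t_s - 0.5)^2) / (2 * 0.02^2))
  pf <- lowpass_filter(mk(pulse), 50)
  expect_lt(abs(which.max(pf$data[1, 1, ]) - which.max(pulse)), 2)
  expect_error(lowpass_filter(mk(pulse), 700), "Nyquist")
})

test_that("resampling preserves band-limited waveforms on the new grid", {
  f <- 1200
  grid <- epoch_sample_range(c(-100, 800), f)
  nt <- length(grid$times_ms)
  t_s <- grid$times_ms / 1000
  d <- array(0, c(1, 1, nt)); d[1, 1, ] <- sin(2 * pi * 17 * t_s)
  ep <- eeg_epochs(d, grid$times_ms, f, "Ch01", 1L, "animate")
  rs <- resample_epochs(ep, 1000)
  expect_equal(length(rs$times_ms), 900)
  expect_equal(rs$sfreq, 1000)
  ref <- sin(2 * pi * 17 * rs$times_ms / 1000)
  expect_lt(max(abs(rs$data[1, 1, ] - ref)) / 2, 0.01)
  expect_identical(resample_epochs(ep, f)$data, ep$data)
  expect_error(resample_epochs(ep, 2400), "upsampling")
})

test_that("the full pipeline is consistent with direct epoched simulation", {
  des <- small_design(n_runs = 2, n_stim = 8, n_ch = 16)
  eff <- quiet_effects()
  raw <- generate_continuous_session(des, eff, "HC", blink_rate = 6, seed = 8)
  ep <- preprocess_pipeline(raw, config = list(cutoff_hz = 20, target_hz = 50,
                                               ica_seed = 1))
  expect_equal(n_trials(ep), n_trials(generate_subject(des, eff, "HC", 8)))
  expect_equal(dim(ep$data)[2], 16)                  # scalp only
  expect_equal(ep$sfreq, 50)
  steps <- vapply(ep$provenance, `[[`, "", "step")
  expect_equal(steps, c("rereference_average", "remove_eog_component",
                        "epoch", "baseline_normalize", "lowpass_filter",
                        "resample"))
  # normalisation precedes filtering, matching the stated stage order
  expect_lt(match("baseline_normalize", steps), match("lowpass_filter", steps))
  # determinism given the ICA seed
  ep2 <- preprocess_pipeline(raw, config = list(cutoff_hz = 20, target_hz = 50,
                                                ica_seed = 1))
  expect_identical(ep$data, ep2$data)
})
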