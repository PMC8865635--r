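# Shared reduced-scale fixtures. The full session design (13 runs, 32
# stimuli, 63 channels, 1200 Hz) is exercised where the checked property is
# structural; simulation-heavy checks use these smaller designs.

small_design <- function(n_runs = 6, n_stim = 8, n_ch = 16, sfreq = 100) {
  synthetic_design(n_runs = n_runs, n_animate = n_stim / 2,
                   n_inanimate = n_stim / 2, sfreq_acquisition = sfreq,
                   n_scalp_channels = n_ch, n_eog = 3,
                   reference_index = min(9, n_ch + 1))
}

quiet_effects <- function(...) {
  # no between-subject variability unless a test asks for it
  group_effects(latency_jitter_sd_ms = 0, amplitude_jitter_sd = 0, ...)
}

no_signal_effects <- function() {
  quiet_effects(amplitude = c(HC = 0, MCI = 0), stimulus_amplitude = 0)
}

# epochs with fully hand-controlled content
manual_epochs <- function(data, sfreq = 100, stimulus_id = NULL,
                          class_label = NULL) {
  d <- dim(data)
  nt <- d[3]
  t0 <- -round(nt / 10)
  eeg_epochs(data, times_ms = ((t0:(t0 + nt - 1)) / sfreq) * 1000,
             sfreq = sfreq,
             channel_names = sprintf("Ch%02d", seq_len(d[2])),
             stimulus_id = stimulus_id %||% rep_len(seq_len(max(2, d[1] %/% 2)), d[1]),
             class_label = class_label %||%
               rep_len(c("animate", "inanimate"), d[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
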