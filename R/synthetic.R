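#' Study design constants for synthetic EEG sessions
#'
#' Captures the session layout emulated by the simulator: 13 runs in which
#' each of 32 natural-image stimuli (16 animals, 16 non-animals) appears
#' once, recorded from 63 scalp electrodes plus one reference (electrode 33)
#' and three EOG channels at 1200 Hz, epoched from 100 ms before to 800 ms
#' after stimulus onset.
#'
#' @param n_runs runs per session; every stimulus appears once per run, so
#'   this is also the repetition-trial count per stimulus.
#' @param n_animate,n_inanimate stimuli per class.
#' @param sfreq_acquisition acquisition sampling rate, Hz.
#' @param epoch_window_ms c(start, end) of the epoch in ms relative to
#'   stimulus onset; start < 0 < end.
#' @param n_scalp_channels scalp electrodes (after reference removal).
#' @param n_eog EOG channels.
#' @param reference_index position of the reference electrode among the
#'   head channels of the continuous recording.
#' @param soa_s stimulus-onset asynchrony within a run, seconds
#'   (continuous simulation only).
#' @return an object of class \code{synthetic_design}.
#' @export
synthetic_design <- function(n_runs = 13, n_animate = 16, n_inanimate = 16,
                             sfreq_acquisition = 1200,
                             epoch_window_ms = c(-100, 800),
                             n_scalp_channels = 63, n_eog = 3,
                             reference_index = 33, soa_s = 2) {
  stopifnot(n_runs >= 1, n_animate + n_inanimate >= 2,
            epoch_window_ms[1] < 0, epoch_window_ms[2] > 0,
            sfreq_acquisition > 0, n_scalp_channels >= 1, n_eog >= 0,
            reference_index >= 1,
            reference_index <= n_scalp_channels + 1)
  structure(list(
    n_runs = as.integer(n_runs),
    n_animate = as.integer(n_animate),
    n_inanimate = as.integer(n_inanimate),
    sfreq_acquisition = sfreq_acquisition,
    epoch_window_ms = epoch_window_ms,
    n_scalp_channels = as.integer(n_scalp_channels),
    n_eog = as.integer(n_eog),
    reference_index = as.integer(reference_index),
    soa_s = soa_s
  ), class = "synthetic_design")
}

#' Group-level effect specification for the simulator
#'
#' Parameterises how the two groups differ.  The class-discriminative
#' signal of a trial is \code{amplitude * (class pattern + stimulus_amplitude
#' * stimulus pattern) * k(t)}, where \code{k} is a raised-cosine kernel
#' rising from \code{onset_ms} to a maximum of 1 at \code{peak_ms} and
#' decaying symmetrically, and the patterns are fixed unit-norm channel
#' vectors derived from \code{pattern_seed}.  The two class patterns are
#' \code{(m +/- d)/sqrt(2)} for orthonormal \code{m} (shared class mean)
#' and \code{d} (class contrast), both orthogonal to the all-ones channel
#' vector.  \code{pattern_divergence} rotates the MCI contrast away from
#' the HC contrast by \code{pattern_divergence * 90} degrees inside the
#' subspace orthogonal to the all-ones vector and to \code{m}, so response
#' patterns diverge between groups while the across-stimulus mean evoked
#' response stays identical.
#'
#' Defaults encode the study conditions the package emulates: an MCI onset
#' and peak delayed by about 40 ms relative to HC, a modest MCI amplitude
#' deficit, and amplitudes at which healthy-control decoding is reliably
#' above chance at SNR ~1 per sample.
#'
#' @param onset_ms named numeric c(HC=, MCI=): signal onset latency, ms.
#' @param peak_ms named numeric c(HC=, MCI=): signal peak latency, ms.
#' @param amplitude named numeric c(HC=, MCI=): evoked amplitude in
#'   baseline-SD units.
#' @param pattern_divergence scalar in [0, 1]; angle between the groups'
#'   class-contrast patterns as a fraction of 90 degrees.
#' @param mean_matched logical; when TRUE the MCI latencies and amplitude
#'   are forced equal to HC's so that the across-stimulus mean evoked
#'   response is identical between groups by construction and only
#'   \code{pattern_divergence} distinguishes them.
#' @param noise_sd per-sample Gaussian noise SD (baseline-SD units); > 0.
#' @param stimulus_amplitude strength of the per-stimulus idiosyncratic
#'   pattern relative to the class pattern (drives pairwise decodability).
#' @param latency_jitter_sd_ms between-subject SD of a common onset/peak
#'   latency shift.
#' @param amplitude_jitter_sd between-subject relative SD of amplitude.
#' @param ar1 lag-one autocorrelation of the temporal noise (0 = white).
#' @param pattern_seed integer seed fixing the spatial patterns (shared by
#'   all subjects of a cohort).
#' @return an object of class \code{group_effects}.
#' @export
group_effects <- function(onset_ms = c(HC = 110, MCI = 150),
                          peak_ms = c(HC = 250, MCI = 290),
                          amplitude = c(HC = 1, MCI = 0.85),
                          pattern_divergence = 0,
                          mean_matched = FALSE,
                          noise_sd = 1,
                          stimulus_amplitude = 0.5,
                          latency_jitter_sd_ms = 12,
                          amplitude_jitter_sd = 0.1,
                          ar1 = 0,
                          pattern_seed = 1L) {
  onset_ms <- expand_group(onset_ms); peak_ms <- expand_group(peak_ms)
  amplitude <- expand_group(amplitude)
  if (mean_matched) {
    onset_ms["MCI"] <- onset_ms["HC"]
    peak_ms["MCI"] <- peak_ms["HC"]
    amplitude["MCI"] <- amplitude["HC"]
  }
  stopifnot(all(onset_ms < peak_ms),
            pattern_divergence >= 0, pattern_divergence <= 1,
            noise_sd > 0, stimulus_amplitude >= 0,
            latency_jitter_sd_ms >= 0, amplitude_jitter_sd >= 0,
            abs(ar1) < 1)
  structure(list(
    onset_ms = onset_ms, peak_ms = peak_ms, amplitude = amplitude,
    pattern_divergence = pattern_divergence, mean_matched = mean_matched,
    noise_sd = noise_sd, stimulus_amplitude = stimulus_amplitude,
    latency_jitter_sd_ms = latency_jitter_sd_ms,
    amplitude_jitter_sd = amplitude_jitter_sd,
    ar1 = ar1, pattern_seed = as.integer(pattern_seed)
  ), class = "group_effects")
}

expand_group <- function(x) {
  if (length(x) == 1L) x <- c(HC = unname(x), MCI = unname(x))
  stopifnot(all(c("HC", "MCI") %in% names(x)))
  x[c("HC", "MCI")]
}

# Orthonormal basis vectors (m, d_hc, e), all orthogonal to the all-ones
# channel vector, plus per-stimulus unit-norm patterns; deterministic given
# the pattern seed.
spatial_patterns <- function(effects, n_channels, n_stimuli) {
  with_seed(effects$pattern_seed, {
    ones <- rep(1, n_channels) / sqrt(n_channels)
    basis <- cbind(ones, matrix(stats::rnorm(n_channels * 3), n_channels))
    q <- qr.Q(qr(basis))
    m <- q[, 2]; d_hc <- q[, 3]; e <- q[, 4]
    a <- effects$pattern_divergence * pi / 2
    d_mci <- cos(a) * d_hc + sin(a) * e
    stim <- matrix(stats::rnorm(n_channels * n_stimuli), n_channels)
    stim <- sweep(stim, 2, sqrt(colSums(stim^2)), "/")
    list(class_pattern = list(
           HC = list(animate = (m + d_hc) / sqrt(2),
                     inanimate = (m - d_hc) / sqrt(2)),
           MCI = list(animate = (m + d_mci) / sqrt(2),
                      inanimate = (m - d_mci) / sqrt(2))),
         stimulus_pattern = stim)
  })
}

# Raised-cosine temporal kernel: 0 before onset, half-cosine ramp to 1 at
# the peak, symmetric decay back to 0 over the same duration.
evoked_kernel <- function(times_ms, onset_ms, peak_ms) {
  w <- peak_ms - onset_ms
  k <- numeric(length(times_ms))
  up <- times_ms >= onset_ms & times_ms <= peak_ms
  dn <- times_ms > peak_ms & times_ms <= peak_ms + w
  k[up] <- 0.5 * (1 - cos(pi * (times_ms[up] - onset_ms) / w))
  k[dn] <- 0.5 * (1 + cos(pi * (times_ms[dn] - peak_ms) / w))
  k
}

# Sample index arithmetic for the half-open epoch window [start, end):
# the sample at t = 0 belongs to the post-stimulus side.
epoch_sample_range <- function(window_ms, sfreq) {
  s0 <- round(window_ms[1] * sfreq / 1000)
  s1 <- round(window_ms[2] * sfreq / 1000) - 1
  list(offsets = s0:s1, times_ms = (s0:s1) / sfreq * 1000)
}

#' Noiseless evoked template of a synthetic group
#'
#' Returns the deterministic (noise-free, jitter-free) evoked response of
#' one group, averaged over the stimuli of one class or over all stimuli.
#' With \code{mean_matched} effects, the all-stimulus template is identical
#' between the two groups by construction.
#'
#' @param design a \code{\link{synthetic_design}}.
#' @param effects a \code{\link{group_effects}}.
#' @param group \code{"HC"} or \code{"MCI"}.
#' @param class \code{"animate"}, \code{"inanimate"}, or NULL for the
#'   average over all stimuli.
#' @return channels x time matrix.
#' @export
evoked_template <- function(design, effects, group, class = NULL) {
  ns <- design$n_animate + design$n_inanimate
  pat <- spatial_patterns(effects, design$n_scalp_channels, ns)
  tm <- epoch_sample_range(design$epoch_window_ms,
                           design$sfreq_acquisition)$times_ms
  k <- evoked_kernel(tm, effects$onset_ms[group], effects$peak_ms[group])
  cls <- rep(c("animate", "inanimate"),
             c(design$n_animate, design$n_inanimate))
  keep <- if (is.null(class)) seq_len(ns) else which(cls == class)
  p <- rowMeans(vapply(keep, function(s)
    pat$class_pattern[[group]][[cls[s]]] +
      effects$stimulus_amplitude * pat$stimulus_pattern[, s],
    numeric(design$n_scalp_channels)))
  effects$amplitude[group] * outer(p, k)
}

#' Simulate one subject's epoched EEG session
#'
#' Generates an \code{\link{eeg_epochs}} dataset following the session
#' design (every stimulus once per run, in random order within each run)
#' with the group's class-discriminative evoked signal plus Gaussian noise
#' (optionally AR(1)-correlated in time).  Deterministic given the seed.
#'
#' @param design a \code{\link{synthetic_design}}.
#' @param effects a \code{\link{group_effects}}.
#' @param group \code{"HC"} or \code{"MCI"}.
#' @param seed integer seed.
#' @param subject_id subject identifier.
#' @param n_runs optional override of \code{design$n_runs} (run dropout).
#' @return an \code{eeg_epochs} with \code{n_runs * n_stimuli} trials on
#'   the scalp channels.
#' @export
generate_subject <- function(design, effects, group = "HC", seed = 1L,
                             subject_id = sprintf("S%03d", seed %% 1000L),
                             n_runs = design$n_runs) {
  stopifnot(inherits(design, "synthetic_design"),
            inherits(effects, "group_effects"),
            group %in% c("HC", "MCI"))
  w <- design$epoch_window_ms
  if (effects$onset_ms[group] <= 0 || effects$onset_ms[group] >= w[2] ||
      effects$peak_ms[group] >= w[2])
    stop("onset/peak latency outside the post-stimulus epoch window")
  ns <- design$n_animate + design$n_inanimate
  nc <- design$n_scalp_channels
  grid <- epoch_sample_range(w, design$sfreq_acquisition)
  tm <- grid$times_ms; nt <- length(tm)
  cls <- rep(c("animate", "inanimate"),
             c(design$n_animate, design$n_inanimate))
  pat <- spatial_patterns(effects, nc, ns)

  with_seed(seed, {
    # subject-level variability: common latency shift, amplitude scaling
    jit <- stats::rnorm(1, 0, effects$latency_jitter_sd_ms)
    width <- effects$peak_ms[group] - effects$onset_ms[group]
    onset <- min(max(effects$onset_ms[group] + jit, 1000 / design$sfreq_acquisition),
                 w[2] - width - 1)
    peak <- onset + width
    amp <- effects$amplitude[group] *
      max(0.1, 1 + stats::rnorm(1, 0, effects$amplitude_jitter_sd))
    k <- evoked_kernel(tm, onset, peak)

    stim_order <- as.vector(vapply(seq_len(n_runs),
                                   function(r) sample.int(ns), integer(ns)))
    n_tr <- n_runs * ns

    noise <- stats::rnorm(n_tr * nc * nt, 0, effects$noise_sd)
    x <- array(noise, c(n_tr, nc, nt))
    if (effects$ar1 != 0) {
      # stationary AR(1): first sample at full SD, innovations scaled so the
      # marginal SD stays noise_sd at every lag
      phi <- effects$ar1
      m2 <- matrix(x, n_tr * nc, nt)
      isc <- sqrt(1 - phi^2)
      for (t in 2:nt) m2[, t] <- phi * m2[, t - 1] + isc * m2[, t]
      x <- array(m2, c(n_tr, nc, nt))
    }
    for (s in seq_len(ns)) {
      p <- amp * (pat$class_pattern[[group]][[cls[s]]] +
                    effects$stimulus_amplitude * pat$stimulus_pattern[, s])
      idx <- which(stim_order == s)
      ev <- outer(p, k)
      for (i in idx) x[i, , ] <- x[i, , ] + ev
    }
    eeg_epochs(x, tm, design$sfreq_acquisition,
               channel_names = default_channel_names(nc),
               stimulus_id = stim_order, class_label = cls[stim_order],
               subject_id = subject_id, group = group,
               provenance = list(list(step = "simulate",
                                      params = list(seed = seed, group = group,
                                                    n_runs = n_runs))))
  })
}

#' Simulate a two-group cohort
#'
#' Per-subject seeds are derived reproducibly from the master seed, so a
#' cohort is fully determined by (design, effects, sizes, seed).
#'
#' @inheritParams generate_subject
#' @param n_hc,n_mci subjects per group (each >= 2; group tests are
#'   undefined below that).
#' @param run_dropout logical; when TRUE, two random subjects complete only
#'   10 runs and two others only 12, mirroring sessions cut short.
#' @return list of \code{eeg_epochs}, one per subject, HC first.
#' @export
generate_cohort <- function(design, effects, n_hc = 22, n_mci = 18,
                            seed = 1L, run_dropout = FALSE) {
  stopifnot(n_hc >= 2, n_mci >= 2)
  n <- n_hc + n_mci
  seeds <- derive_seeds(seed, n)
  groups <- rep(c("HC", "MCI"), c(n_hc, n_mci))
  runs <- rep(design$n_runs, n)
  if (run_dropout && n >= 4) {
    pick <- with_seed(seed + 1L, sample.int(n, 4))
    runs[pick[1:2]] <- 10L
    runs[pick[3:4]] <- 12L
  }
  lapply(seq_len(n), function(i)
    generate_subject(design, effects, groups[i], seeds[i],
                     subject_id = sprintf("%s%03d", groups[i], i),
                     n_runs = runs[i]))
}

#' Simulate a continuous recording with events and blink artifacts
#'
#' Produces the raw input of the preprocessing chain: a continuous
#' multichannel record (63 scalp + 1 reference + EOG channels) containing
#' the evoked responses at listed stimulus onsets, plus eye-blink
#' transients projected onto the EOG channels and, attenuated, onto the
#' frontal scalp channels.
#'
#' @inheritParams generate_subject
#' @param blink_rate blink events per minute (>= 0).
#' @param blink_amplitude blink transient amplitude in noise-SD units.
#' @return an \code{\link{eeg_raw}} whose \code{events} table has one row
#'   per stimulus presentation.
#' @export
generate_continuous_session <- function(design, effects, group = "HC",
                                        blink_rate = 5, seed = 1L,
                                        blink_amplitude = 15) {
  stopifnot(blink_rate >= 0)
  ns <- design$n_animate + design$n_inanimate
  nc <- design$n_scalp_channels
  f <- design$sfreq_acquisition
  run_len_s <- 1 + ns * design$soa_s + 2
  n_samp <- ceiling(design$n_runs * run_len_s * f)
  n_head <- nc + 1L
  n_all <- n_head + design$n_eog
  cls <- rep(c("animate", "inanimate"),
             c(design$n_animate, design$n_inanimate))
  pat <- spatial_patterns(effects, nc, ns)
  scalp_idx <- setdiff(seq_len(n_head), design$reference_index)

  with_seed(seed, {
    k_t <- seq(0, (effects$peak_ms[group] - effects$onset_ms[group]) +
                 effects$peak_ms[group], by = 1000 / f)
    k <- evoked_kernel(k_t, effects$onset_ms[group], effects$peak_ms[group])
    amp <- effects$amplitude[group]

    x <- matrix(stats::rnorm(n_all * n_samp, 0, effects$noise_sd),
                n_all, n_samp)

    ev <- do.call(rbind, lapply(seq_len(design$n_runs), function(r) {
      t0 <- (r - 1) * run_len_s + 1
      ord <- sample.int(ns)
      data.frame(sample = round((t0 + (seq_len(ns) - 1) * design$soa_s) * f) + 1L,
                 stimulus_id = ord, class_label = cls[ord])
    }))
    for (i in seq_len(nrow(ev))) {
      s <- ev$stimulus_id[i]
      p <- amp * (pat$class_pattern[[group]][[cls[s]]] +
                    effects$stimulus_amplitude * pat$stimulus_pattern[, s])
      rng <- ev$sample[i] + seq_along(k) - 1L
      ok <- rng <= n_samp
      x[scalp_idx, rng[ok]] <- x[scalp_idx, rng[ok]] + outer(p, k[ok])
    }

    if (blink_rate > 0 && design$n_eog > 0) {
      dur_min <- n_samp / f / 60
      n_blink <- stats::rpois(1, blink_rate * dur_min)
      if (n_blink > 0) {
        bl_t <- sort(sample.int(n_samp - f, n_blink))
        bk <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = round(0.4 * f))))
        eog_gain <- blink_amplitude * 0.8^(seq_len(design$n_eog) - 1)
        n_front <- min(10L, nc)
        front_gain <- 0.5 * blink_amplitude * 0.8^(0:(n_front - 1))
        eog_rows <- n_head + seq_len(design$n_eog)
        front_rows <- scalp_idx[seq_len(n_front)]
        for (b in bl_t) {
          rng <- b + seq_along(bk) - 1L
          x[eog_rows, rng] <- x[eog_rows, rng] + outer(eog_gain, bk)
          x[front_rows, rng] <- x[front_rows, rng] + outer(front_gain, bk)
        }
      }
    }

    nm <- character(n_all); ty <- character(n_all)
    nm[scalp_idx] <- default_channel_names(nc); ty[scalp_idx] <- "eeg"
    nm[design$reference_index] <- "REF"; ty[design$reference_index] <- "ref"
    if (design$n_eog > 0) {
      nm[n_head + seq_len(design$n_eog)] <- paste0("EOG", seq_len(design$n_eog))
      ty[n_head + seq_len(design$n_eog)] <- "eog"
    }
    eeg_raw(x, f, nm, ty, events = ev)
  })
}

#' Write a cohort manifest table
#'
#' @param cohort list of \code{eeg_epochs} from \code{\link{generate_cohort}}.
#' @param path output TSV path.
#' @return the manifest data frame, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  man <- do.call(rbind, lapply(cohort, function(s) {
    sim <- s$provenance[[1]]$params
    data.frame(subject_id = s$subject_id, group = s$group,
               seed = sim$seed %||% NA, n_runs = sim$n_runs %||% NA)
  }))
  utils::write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(man)
}
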