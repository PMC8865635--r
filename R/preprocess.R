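#' Average re-reference and reference-channel removal
#'
#' Subtracts the across-scalp-channel mean from every scalp channel at each
#' sample and drops the reference channel, so the scalp channels sum to
#' zero per sample afterwards.  EOG channels are left untouched.
#'
#' @param raw an \code{\link{eeg_raw}} with a channel of type \code{"ref"}.
#' @return an \code{eeg_raw} without the reference channel.
#' @export
rereference_average <- function(raw) {
  stopifnot(inherits(raw, "eeg_raw"))
  ref <- which(raw$channel_types == "ref")
  if (length(ref) == 0L) stop("no reference channel present")
  eeg <- which(raw$channel_types == "eeg")
  m <- colMeans(raw$data[eeg, , drop = FALSE])
  raw$data[eeg, ] <- sweep(raw$data[eeg, , drop = FALSE], 2, m)
  keep <- setdiff(seq_len(nrow(raw$data)), ref)
  raw$data <- raw$data[keep, , drop = FALSE]
  raw$channel_names <- raw$channel_names[keep]
  raw$channel_types <- raw$channel_types[keep]
  raw
}

#' Remove the EOG-correlated independent component
#'
#' Runs FastICA on the scalp channels (at most 20 components), finds the
#' component whose time course is most correlated (absolute Pearson r) with
#' any EOG channel, and subtracts that component's back-projection from the
#' scalp data.  Exactly one component is removed.  If the decomposition
#' fails the input is returned unchanged with a warning.
#'
#' @param raw an \code{\link{eeg_raw}} containing EOG channels.
#' @param max_components maximum number of independent components.
#' @param seed seed for the FastICA initialisation.
#' @return an \code{eeg_raw} with the blink component removed; the selected
#'   component index and its EOG correlation are attached as attribute
#'   \code{"eog_component"}.
#' @export
remove_eog_component <- function(raw, max_components = 20, seed = 1L) {
  stopifnot(inherits(raw, "eeg_raw"))
  eeg <- which(raw$channel_types == "eeg")
  eog <- which(raw$channel_types == "eog")
  if (length(eog) == 0L) stop("no EOG channel present")
  eog_dat <- raw$data[eog, , drop = FALSE]
  if (any(apply(eog_dat, 1, stats::sd) == 0)) {
    warning("zero-variance EOG channel; skipping ICA cleanup")
    return(raw)
  }
  X <- t(raw$data[eeg, , drop = FALSE])          # time x channels
  # average re-referencing removes one degree of freedom, so ask for at
  # most n_channels - 1 components to keep the data full rank for ICA
  nc <- min(length(eeg) - 1L, max_components)
  dec <- with_seed(seed, tryCatch(ica::icafast(X, nc = nc, center = TRUE,
                                               maxit = 200),
                                  error = function(e) NULL))
  if (is.null(dec)) {
    warning("ICA decomposition failed; returning data unchanged")
    return(raw)
  }
  r <- abs(stats::cor(dec$S, t(eog_dat)))        # nc x n_eog
  k <- which.max(apply(r, 1, max))
  X_clean <- X - dec$S[, k, drop = FALSE] %*% t(dec$M[, k, drop = FALSE])
  raw$data[eeg, ] <- t(X_clean)
  attr(raw, "eog_component") <- list(component = k, max_abs_cor = max(r[k, ]))
  raw
}

#' Epoch a continuous recording around stimulus events
#'
#' Cuts one epoch per event over the half-open window
#' \code{[window_ms[1], window_ms[2])}; the sample at t = 0 belongs to the
#' post-stimulus side.  Events whose window exceeds the recording bounds
#' are dropped with a message.
#'
#' @param raw an \code{\link{eeg_raw}}.
#' @param events data frame with columns \code{sample}, \code{stimulus_id},
#'   \code{class_label}; defaults to \code{raw$events}.
#' @param window_ms c(start, end) in ms relative to onset, start < 0 < end.
#' @param drop_eog drop EOG channels from the epochs (default TRUE; they
#'   are only needed for artifact removal).
#' @return an \code{\link{eeg_epochs}}.
#' @export
extract_epochs <- function(raw, events = raw$events,
                           window_ms = c(-100, 800), drop_eog = TRUE) {
  stopifnot(inherits(raw, "eeg_raw"))
  keep_ch <- if (drop_eog) which(raw$channel_types != "eog")
             else seq_len(nrow(raw$data))
  grid <- epoch_sample_range(window_ms, raw$sfreq)
  nt <- length(grid$offsets)
  if (is.null(events) || nrow(events) == 0L) {
    return(eeg_epochs(array(0, c(0, length(keep_ch), nt)), grid$times_ms,
                      raw$sfreq, raw$channel_names[keep_ch],
                      integer(0), character(0)))
  }
  ok <- events$sample + grid$offsets[1] >= 1 &
        events$sample + grid$offsets[nt] <= ncol(raw$data)
  if (any(!ok))
    message(sum(!ok), " event(s) dropped: epoch window outside the recording")
  events <- events[ok, , drop = FALSE]
  x <- array(0, c(nrow(events), length(keep_ch), nt))
  for (i in seq_len(nrow(events)))
    x[i, , ] <- raw$data[keep_ch, events$sample[i] + grid$offsets]
  eeg_epochs(x, grid$times_ms, raw$sfreq, raw$channel_names[keep_ch],
             events$stimulus_id, events$class_label)
}

#' Baseline z-normalisation of epochs
#'
#' Per trial and channel, subtracts the mean and divides by the SD of the
#' pre-stimulus baseline (samples with t < 0).  Zero baseline SDs are
#' replaced by 1 with a warning.  Idempotent.
#'
#' @param epochs an \code{\link{eeg_epochs}}.
#' @return baseline-normalised \code{eeg_epochs}.
#' @export
baseline_normalize <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  bl <- epochs$times_ms < 0
  if (!any(bl)) stop("no pre-stimulus baseline samples")
  d <- dim(epochs$data)
  base <- epochs$data[, , bl, drop = FALSE]
  mu <- apply(base, c(1, 2), mean)
  sd_ <- apply(base, c(1, 2), stats::sd)
  if (any(sd_ == 0)) {
    warning("zero baseline SD in ", sum(sd_ == 0),
            " trial/channel(s); SD of 1 substituted")
    sd_[sd_ == 0] <- 1
  }
  epochs$data <- (epochs$data - array(mu, d)) / array(sd_, d)
  add_provenance(epochs, "baseline_normalize")
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth low-pass applied forward and backward
#' (\code{signal::filtfilt}), hence zero phase shift: a pulse's peak sample
#' is not displaced.
#'
#' @param epochs an \code{\link{eeg_epochs}}.
#' @param cutoff_hz cutoff frequency; must be below Nyquist.
#' @param order filter order.
#' @return filtered \code{eeg_epochs}.
#' @export
lowpass_filter <- function(epochs, cutoff_hz = 50, order = 4) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (cutoff_hz >= epochs$sfreq / 2)
    stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff_hz / (epochs$sfreq / 2), type = "low")
  d <- dim(epochs$data)
  n <- d[3]
  # odd-reflection padding suppresses the start/end transients that
  # zero-initial-state forward-backward filtering would otherwise leave
  pad <- min(n - 1L, as.integer(ceiling(3 * epochs$sfreq / cutoff_hz)))
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2])) {
      x <- epochs$data[i, j, ]
      xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
      epochs$data[i, j, ] <- signal::filtfilt(bf, xp)[(pad + 1):(pad + n)]
    }
  add_provenance(epochs, "lowpass_filter",
                 list(cutoff_hz = cutoff_hz, order = order))
}

#' Resample epochs to a lower sampling rate
#'
#' Cubic-spline interpolation onto the uniform grid of the target rate over
#' the same half-open epoch window.  Intended to follow the 50 Hz low-pass,
#' which guarantees the signal is band-limited far below the new Nyquist
#' frequency; upsampling is rejected.
#'
#' @param epochs an \code{\link{eeg_epochs}}.
#' @param target_hz target sampling rate (<= current).
#' @return resampled \code{eeg_epochs}.
#' @export
resample_epochs <- function(epochs, target_hz = 1000) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (target_hz > epochs$sfreq) stop("upsampling not supported")
  if (target_hz == epochs$sfreq) return(epochs)
  dt <- 1000 / epochs$sfreq
  window <- c(epochs$times_ms[1], epochs$times_ms[length(epochs$times_ms)] + dt)
  grid <- epoch_sample_range(window, target_hz)
  d <- dim(epochs$data)
  out <- array(0, c(d[1], d[2], length(grid$times_ms)))
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      out[i, j, ] <- stats::spline(epochs$times_ms, epochs$data[i, j, ],
                                   xout = grid$times_ms)$y
  epochs$data <- out
  epochs$times_ms <- grid$times_ms
  epochs$sfreq <- target_hz
  add_provenance(epochs, "resample", list(target_hz = target_hz))
}

#' Full preprocessing chain
#'
#' Applies, in order: average re-reference with reference removal,
#' ICA-based removal of the EOG-correlated component, epoching, baseline
#' z-normalisation, 50 Hz zero-phase low-pass, and resampling to 1000 Hz.
#' Normalisation deliberately precedes filtering, matching the stage order
#' this pipeline reproduces.
#'
#' @param raw an \code{\link{eeg_raw}} with reference and EOG channels.
#' @param events event table; defaults to \code{raw$events}.
#' @param config named list overriding defaults: \code{window_ms},
#'   \code{cutoff_hz}, \code{target_hz}, \code{ica_seed},
#'   \code{max_components}, \code{verbose}.
#' @return a preprocessed \code{\link{eeg_epochs}} (scalp channels only)
#'   with a six-entry provenance log.
#' @export
preprocess_pipeline <- function(raw, events = raw$events, config = list()) {
  cfg <- utils::modifyList(list(window_ms = c(-100, 800), cutoff_hz = 50,
                                target_hz = 1000, ica_seed = 1L,
                                max_components = 20, verbose = FALSE), config)
  say <- function(...) if (isTRUE(cfg$verbose)) message(...)
  say("1/6 average re-reference")
  raw <- rereference_average(raw)
  say("2/6 ICA EOG-component removal")
  raw <- remove_eog_component(raw, cfg$max_components, cfg$ica_seed)
  say("3/6 epoching")
  ep <- extract_epochs(raw, events, cfg$window_ms)
  ep$provenance <- c(list(list(step = "rereference_average", params = list()),
                          list(step = "remove_eog_component",
                               params = list(seed = cfg$ica_seed))),
                     list(list(step = "epoch",
                               params = list(window_ms = cfg$window_ms))))
  say("4/6 baseline normalisation")
  ep <- baseline_normalize(ep)
  say("5/6 low-pass filter")
  ep <- lowpass_filter(ep, cfg$cutoff_hz)
  say("6/6 resampling")
  resample_epochs(ep, cfg$target_hz)
}
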