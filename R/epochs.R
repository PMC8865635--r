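#' Epoched EEG container
#'
#' Constructs the package's container for epoched multichannel EEG: a
#' trials x channels x time numeric array plus the metadata every analysis
#' stage needs (time axis, sampling rate, channel names, stimulus identity
#' and animacy class per trial, subject/group labels, and a provenance log
#' of the processing stages applied).
#'
#' @param data numeric array, trials x channels x time.
#' @param times_ms numeric vector of per-sample timestamps in milliseconds
#'   relative to stimulus onset; must be strictly increasing and uniform.
#' @param sfreq sampling rate in Hz.
#' @param channel_names character vector, one per channel.
#' @param stimulus_id integer vector, one per trial.
#' @param class_label factor or character per trial, levels
#'   \code{c("animate", "inanimate")}.
#' @param subject_id optional subject identifier.
#' @param group optional group label (\code{"HC"} or \code{"MCI"}).
#' @param provenance list of processing-stage records (appended to, never
#'   overwritten, by pipeline stages).
#' @return an object of class \code{eeg_epochs}.
#' @export
eeg_epochs <- function(data, times_ms, sfreq, channel_names,
                       stimulus_id, class_label,
                       subject_id = NA_character_, group = NA_character_,
                       provenance = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  d <- dim(data)
  if (length(times_ms) != d[3])
    stop("times_ms length must equal the time dimension")
  if (length(channel_names) != d[2])
    stop("channel_names length must equal the channel dimension")
  if (length(stimulus_id) != d[1] || length(class_label) != d[1])
    stop("per-trial metadata must match the trial dimension")
  dt <- diff(times_ms)
  if (any(dt <= 0) || (length(dt) > 1 && max(abs(dt - dt[1])) > 1e-6))
    stop("time axis must be strictly increasing and uniform")
  structure(list(
    data = data,
    times_ms = as.numeric(times_ms),
    sfreq = sfreq,
    channel_names = as.character(channel_names),
    stimulus_id = as.integer(stimulus_id),
    class_label = factor(class_label, levels = c("animate", "inanimate")),
    subject_id = subject_id,
    group = group,
    provenance = provenance
  ), class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples\n",
              d[1], d[2], d[3]))
  cat(sprintf("  time %g..%g ms @ %g Hz; %d stimuli (%d animate, %d inanimate)\n",
              min(x$times_ms), max(x$times_ms), x$sfreq,
              length(unique(x$stimulus_id)),
              length(unique(x$stimulus_id[x$class_label == "animate"])),
              length(unique(x$stimulus_id[x$class_label == "inanimate"]))))
  if (!is.na(x$subject_id))
    cat(sprintf("  subject %s (%s)\n", x$subject_id, x$group))
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "step"),
                               collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

#' Number of trials in an epoched dataset
#' @param epochs an \code{eeg_epochs} object.
#' @return integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Subset the channels of an epoched dataset
#'
#' @param epochs an \code{eeg_epochs} object.
#' @param channels integer indices or channel names to keep.
#' @return an \code{eeg_epochs} with only the requested channels.
#' @export
select_channels <- function(epochs, channels) {
  if (is.character(channels))
    channels <- match(channels, epochs$channel_names)
  if (length(channels) == 0L || anyNA(channels))
    stop("unknown or empty channel selection")
  epochs$data <- epochs$data[, channels, , drop = FALSE]
  epochs$channel_names <- epochs$channel_names[channels]
  epochs
}

#' Index of the sample nearest a requested latency
#' @param epochs an \code{eeg_epochs} object.
#' @param time_ms latency in ms.
#' @return integer sample index.
#' @export
nearest_sample <- function(epochs, time_ms) {
  which.min(abs(epochs$times_ms - time_ms))
}

add_provenance <- function(epochs, step, params = list()) {
  epochs$provenance <- c(epochs$provenance,
                         list(list(step = step, params = params,
                                   time = format(Sys.time()))))
  epochs
}

#' Continuous EEG container
#'
#' Container for a continuous multichannel recording (channels x samples)
#' with channel types (\code{"eeg"}, \code{"ref"}, \code{"eog"}) and a
#' stimulus-onset event table, as produced by
#' \code{\link{generate_continuous_session}} or read from disk.
#'
#' @param data numeric matrix, channels x samples.
#' @param sfreq sampling rate in Hz.
#' @param channel_names character per channel.
#' @param channel_types character per channel: "eeg", "ref" or "eog".
#' @param events data frame with columns \code{sample}, \code{stimulus_id},
#'   \code{class_label}.
#' @return an object of class \code{eeg_raw}.
#' @export
eeg_raw <- function(data, sfreq, channel_names, channel_types,
                    events = NULL) {
  stopifnot(is.matrix(data),
            nrow(data) == length(channel_names),
            length(channel_types) == length(channel_names),
            all(channel_types %in% c("eeg", "ref", "eog")))
  structure(list(
    data = data, sfreq = sfreq,
    channel_names = as.character(channel_names),
    channel_types = as.character(channel_types),
    events = events
  ), class = "eeg_raw")
}

#' @export
print.eeg_raw <- function(x, ...) {
  cat(sprintf("<eeg_raw> %d channels x %d samples @ %g Hz (%d eeg, %d ref, %d eog); %d events\n",
              nrow(x$data), ncol(x$data), x$sfreq,
              sum(x$channel_types == "eeg"), sum(x$channel_types == "ref"),
              sum(x$channel_types == "eog"),
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}
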