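#' Decoder configuration
#'
#' Fixed classifier settings used throughout: linear SVM (libsvm) with cost
#' C = 1 and equal class weights; stimuli are randomly grouped into bins of
#' 2, 3 or 4 stimuli whose trials are sub-averaged before classification,
#' and the whole assignment/classification procedure is repeated
#' \code{n_repetitions} times (10,000 by default; reduce for quick runs).
#'
#' @param cost SVM cost parameter C.
#' @param bin_sizes candidate bin sizes (stimuli per bin).
#' @param n_repetitions random bin assignments averaged per time-point.
#' @param mode \code{"mixed"}: each repetition draws one bin size uniformly
#'   from \code{bin_sizes}; \code{"per_size"}: repetitions are split evenly
#'   across the sizes.
#' @param seed RNG seed for the repetition stream.
#' @return an object of class \code{decoder_config}.
#' @export
decoder_config <- function(cost = 1, bin_sizes = c(2, 3, 4),
                           n_repetitions = 10000,
                           mode = c("mixed", "per_size"), seed = NULL) {
  stopifnot(cost > 0, all(bin_sizes >= 2), n_repetitions >= 1)
  structure(list(cost = cost, bin_sizes = as.integer(bin_sizes),
                 n_repetitions = as.integer(n_repetitions),
                 mode = match.arg(mode), seed = seed),
            class = "decoder_config")
}

#' Random bin assignment of stimuli within each class
#'
#' Partitions the stimuli of each class into disjoint bins of
#' \code{bin_size} stimuli.  A stimulus -- and therefore all of its
#' repetition trials -- belongs to exactly one bin, which is what prevents
#' train/test leakage in the leave-one-bin-out scheme.  When the class size
#' is not divisible by \code{bin_size}, a random remainder subset of
#' stimuli is left out of this assignment.
#'
#' @param stimulus_ids integer stimulus id per trial (or per stimulus).
#' @param class_labels class label aligned with \code{stimulus_ids}.
#' @param bin_size stimuli per bin (each class must have at least this
#'   many stimuli).
#' @return data frame (\code{stimulus_id}, \code{class_label}, \code{bin})
#'   covering the assigned stimuli; bins are numbered within class.
#' @export
assign_bins <- function(stimulus_ids, class_labels, bin_size) {
  u <- !duplicated(stimulus_ids)
  stim <- stimulus_ids[u]; cls <- as.character(class_labels)[u]
  out <- lapply(split(stim, cls), function(s) {
    if (length(s) < bin_size)
      stop("class has fewer stimuli (", length(s), ") than the bin size")
    s <- sample(s)
    n_keep <- (length(s) %/% bin_size) * bin_size
    s <- s[seq_len(n_keep)]
    data.frame(stimulus_id = s,
               bin = rep(seq_len(n_keep / bin_size), each = bin_size))
  })
  res <- do.call(rbind, Map(function(d, cl) {
    d$class_label <- cl; d
  }, out, names(out)))
  rownames(res) <- NULL
  res[, c("stimulus_id", "class_label", "bin")]
}

#' Sub-average trials within bins
#'
#' For every bin of the assignment, averages all repetition trials of its
#' member stimuli across the full time axis, yielding one exemplar
#' (channels x time) per bin and class.
#'
#' @param epochs an \code{\link{eeg_epochs}}.
#' @param assignment data frame from \code{\link{assign_bins}}.
#' @return named list (one entry per class) of arrays bins x channels x
#'   time.
#' @export
subaverage_bins <- function(epochs, assignment) {
  d <- dim(epochs$data)
  flat <- matrix(epochs$data, d[1], d[2] * d[3])
  lapply(split(assignment, assignment$class_label), function(a) {
    nb <- max(a$bin)
    ex <- array(0, c(nb, d[2], d[3]))
    for (b in seq_len(nb)) {
      tr <- which(epochs$stimulus_id %in% a$stimulus_id[a$bin == b])
      if (length(tr) == 0L) stop("empty bin")
      ex[b, , ] <- colMeans(flat[tr, , drop = FALSE])
    }
    ex
  })
}

#' Leave-one-bin-out SVM accuracy on exemplar matrices
#'
#' One cross-validation pass at a single time-point: fold f holds out the
#' f-th exemplar of each class, a linear SVM is trained on the remaining
#' exemplars, and the two held-out exemplars are classified.  Degenerate
#' training sets score the fold at chance (0.5).
#'
#' @param xa,xi exemplar matrices (bins x features) of the two classes.
#' @param cost SVM cost.
#' @return mean accuracy over the folds.
#' @export
lobo_cv_accuracy <- function(xa, xi, cost = 1) {
  nf <- min(nrow(xa), nrow(xi))
  if (nf < 2) stop("need at least 2 bins per class for leave-one-bin-out CV")
  acc <- numeric(nf)
  for (f in seq_len(nf)) {
    train_x <- rbind(xa[-f, , drop = FALSE], xi[-f, , drop = FALSE])
    train_y <- rep(c("animate", "inanimate"), c(nrow(xa) - 1, nrow(xi) - 1))
    test_x <- rbind(xa[f, , drop = FALSE], xi[f, , drop = FALSE])
    p <- svm_predict(train_x, train_y, test_x, cost)
    acc[f] <- mean(ifelse(is.na(p), 0.5,
                          as.numeric(p == c("animate", "inanimate"))))
  }
  mean(acc)
}

#' Time-resolved animacy decoding of one subject
#'
#' At each time-point the features are the scalp-channel values of the
#' bin-sub-averaged exemplars at that single sample.  Each repetition draws
#' a bin size and a random assignment of stimuli to bins (shared across
#' time-points of that repetition), and the reported accuracy per
#' time-point is the average leave-one-bin-out CV accuracy over
#' repetitions.
#'
#' @param epochs a preprocessed \code{\link{eeg_epochs}}.
#' @param config a \code{\link{decoder_config}}.
#' @param times_ms optional latencies to decode (nearest samples); default
#'   all samples.
#' @param channels optional channel restriction (names or indices, e.g. a
#'   channel-group's channels); an empty selection is an error.
#' @return object of class \code{decoding_timecourse}: \code{times_ms},
#'   \code{accuracy}, peak annotations, metadata.
#' @export
decode_timecourse <- function(epochs, config = decoder_config(),
                              times_ms = NULL, channels = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!is.null(channels)) epochs <- select_channels(epochs, channels)
  t_idx <- if (is.null(times_ms)) seq_along(epochs$times_ms)
           else vapply(times_ms, function(t) nearest_sample(epochs, t),
                       integer(1))
  tms <- epochs$times_ms[t_idx]
  n_rep <- config$n_repetitions
  # a bin size is usable only if each class still yields >= 2 bins
  min_class <- min(table(unique(data.frame(s = epochs$stimulus_id,
                                           c = epochs$class_label))$c))
  config$bin_sizes <- config$bin_sizes[min_class %/% config$bin_sizes >= 2]
  if (length(config$bin_sizes) == 0L)
    stop("too few stimuli per class for leave-one-bin-out decoding")
  sizes <- if (config$mode == "mixed")
    with_seed(config$seed,
              sample(config$bin_sizes, n_rep, replace = TRUE))
  else rep_len(rep(config$bin_sizes,
                   each = ceiling(n_rep / length(config$bin_sizes))), n_rep)
  acc <- matrix(0, n_rep, length(t_idx))
  with_seed(if (is.null(config$seed)) NULL else config$seed + 1L, {
    for (r in seq_len(n_rep)) {
      a <- assign_bins(epochs$stimulus_id, epochs$class_label, sizes[r])
      ex <- subaverage_bins(epochs, a)
      slice <- function(a, tt) matrix(a[, , tt], nrow = dim(a)[1])
      for (j in seq_along(t_idx)) {
        tt <- t_idx[j]
        acc[r, j] <- lobo_cv_accuracy(slice(ex$animate, tt),
                                      slice(ex$inanimate, tt),
                                      config$cost)
      }
    }
  })
  res <- structure(list(times_ms = tms, accuracy = colMeans(acc),
                        n_repetitions = n_rep,
                        subject_id = epochs$subject_id, group = epochs$group,
                        onset_time_ms = NA_real_),
                   class = "decoding_timecourse")
  pk <- find_peak(res)
  res$peak_time_ms <- pk["peak_time_ms"]
  res$peak_accuracy <- pk["peak_accuracy"]
  res
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat(sprintf("<decoding_timecourse> %s (%s): %d time-points, %d repetitions\n",
              x$subject_id, x$group, length(x$times_ms), x$n_repetitions))
  cat(sprintf("  peak %.1f%% at %g ms\n", 100 * x$peak_accuracy,
              x$peak_time_ms))
  invisible(x)
}

#' Decoding accuracy at a single latency
#'
#' @inheritParams decode_timecourse
#' @param time_ms latency of interest (nearest sample used).
#' @return scalar accuracy.
#' @export
decode_timepoint <- function(epochs, time_ms, config = decoder_config(),
                             channels = NULL) {
  decode_timecourse(epochs, config, times_ms = time_ms,
                    channels = channels)$accuracy
}

#' Cohort-level significance of a decoding time course
#'
#' At each time-point, a one-sided bootstrap test (subsampling of
#' participants) of the across-subject mean accuracy against chance (0.5),
#' FDR-corrected across time-points.
#'
#' @param acc subjects x time accuracy matrix.
#' @param n_boot bootstrap resamples.
#' @param alpha FDR level.
#' @param seed RNG seed.
#' @return list with \code{p}, \code{p_adjusted}, \code{flags}.
#' @export
decoding_significance <- function(acc, n_boot = 10000, alpha = 0.05,
                                  seed = NULL) {
  stopifnot(is.matrix(acc), nrow(acc) >= 2)
  seeds <- derive_seeds(seed %||% stats::runif(1, 1, 1e6), ncol(acc))
  p <- vapply(seq_len(ncol(acc)), function(j)
    bootstrap_test(acc[, j], mean, baseline = 0.5, n = n_boot,
                   side = "greater", seed = seeds[j])$p_value,
    numeric(1))
  fc <- fdr_correct(p, alpha)
  list(p = p, p_adjusted = fc$adjusted, flags = fc$flags)
}

#' Peak of a decoding time course
#'
#' The post-stimulus time-point of maximum accuracy (earliest sample on
#' ties) and the accuracy there.
#'
#' @param course a \code{decoding_timecourse}, or a list with
#'   \code{times_ms} and \code{accuracy}.
#' @return named numeric c(peak_time_ms, peak_accuracy).
#' @export
find_peak <- function(course) {
  post <- which(course$times_ms > 0)
  if (length(post) == 0L) stop("no post-stimulus samples")
  i <- post[which.max(course$accuracy[post])]
  c(peak_time_ms = course$times_ms[i], peak_accuracy = course$accuracy[i])
}

#' Onset of significant decoding
#'
#' First FDR-significant post-stimulus time-point; \code{NA} when no
#' time-point is significant.
#'
#' @param course a \code{decoding_timecourse} (or list with
#'   \code{times_ms}).
#' @param flags logical significance flags aligned with
#'   \code{course$times_ms}.
#' @return onset latency in ms, or \code{NA_real_}.
#' @export
find_onset <- function(course, flags) {
  stopifnot(length(flags) == length(course$times_ms))
  i <- which(flags & course$times_ms > 0)
  if (length(i) == 0L) return(NA_real_)
  course$times_ms[min(i)]
}

#' Group comparison of decoding peak latencies
#'
#' Bootstrap (participant subsampling) test of the difference of group
#' median peak latencies (MCI minus HC), one-sided for a delay in MCI by
#' default, with percentile 95\% CI and bootstrap SE.
#'
#' @param hc_courses,mci_courses lists of \code{decoding_timecourse} (or
#'   numeric vectors of peak latencies).
#' @param n_boot bootstrap resamples.
#' @param side test direction; default \code{"greater"} (MCI delayed).
#' @param seed RNG seed.
#' @return an \code{\link{eeg_test}}; \code{estimate} is the observed
#'   median difference in ms.
#' @export
compare_peak_latency <- function(hc_courses, mci_courses, n_boot = 10000,
                                 side = "greater", seed = NULL) {
  peaks <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(cc) find_peak(cc)[["peak_time_ms"]], numeric(1))
  }
  hc <- peaks(hc_courses); mci <- peaks(mci_courses)
  stopifnot(length(hc) >= 2, length(mci) >= 2)
  res <- bootstrap_test(list(HC = hc, MCI = mci),
                        function(s) stats::median(s$MCI) - stats::median(s$HC),
                        baseline = 0, n = n_boot, side = side, seed = seed)
  res$method <- "bootstrap (median peak-latency difference, MCI - HC)"
  res
}
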