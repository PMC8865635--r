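#' Per-stimulus activation pattern at one latency
#'
#' The channels x stimuli matrix whose column j is the scalp-channel
#' response to stimulus j at the requested latency, averaged over all of
#' its repetition trials (63 x 32 under the default design).
#'
#' @param epochs a preprocessed \code{\link{eeg_epochs}}.
#' @param time_ms latency (nearest sample used).
#' @param channels optional channel restriction (rows become the subset).
#' @return numeric matrix channels x stimuli; columns ordered by stimulus
#'   id.
#' @export
activation_pattern <- function(epochs, time_ms, channels = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!is.null(channels)) epochs <- select_channels(epochs, channels)
  tt <- nearest_sample(epochs, time_ms)
  X <- epochs$data[, , tt]                       # trials x channels
  stim <- sort(unique(epochs$stimulus_id))
  out <- vapply(stim, function(s)
    colMeans(X[epochs$stimulus_id == s, , drop = FALSE]),
    numeric(ncol(X)))
  dimnames(out) <- list(epochs$channel_names, stim)
  out
}

# Leave-one-subject-out CV accuracy for features x labels, stratified by
# group (each fold holds out one subject of each group where possible, so
# training folds stay balanced); held-out subjects contribute nothing to
# training.
loso_accuracy <- function(features, labels, cost = 1) {
  loo_cv_accuracy(features, labels, cost)
}

# Shared resampling engine: repeated subsampling (ceiling(frac * n) per
# group, without replacement), LOSO CV accuracy per resample.
boot_loso <- function(features, labels, n_boot, frac, cost, seed) {
  g <- split(seq_along(labels), labels)
  stopifnot(length(g) == 2L, all(lengths(g) >= 2))
  with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- unlist(lapply(g, function(i)
      i[sample.int(length(i), ceiling(frac * length(i)))]))
    loso_accuracy(features[idx, , drop = FALSE], labels[idx], cost)
  }, numeric(1)))
}

#' HC vs MCI classification from activation patterns at one latency
#'
#' Each subject's flattened activation pattern is one observation.  The
#' procedure repeatedly subsamples participants (without replacement,
#' \code{frac} of each group per draw), runs leave-one-subject-out CV with
#' a linear SVM (C = 1) on each subsample, and reports the mean accuracy
#' over resamples with a bootstrap p-value against chance.
#'
#' @param patterns list of per-subject activation-pattern matrices (all of
#'   equal dimension), or a subjects x features matrix.
#' @param groups character group label per subject ("HC"/"MCI").
#' @param n_boot number of resamples.
#' @param frac subsample fraction per group.
#' @param cost SVM cost.
#' @param seed RNG seed.
#' @return an \code{\link{eeg_test}}: \code{estimate} = mean resample
#'   accuracy, \code{statistic} = full-sample LOSO accuracy, percentile CI
#'   over resamples, \code{p_value} vs 0.5.
#' @export
classify_groups_timepoint <- function(patterns, groups, n_boot = 10000,
                                      frac = 0.8, cost = 1, seed = NULL) {
  features <- if (is.list(patterns))
    t(vapply(patterns, as.vector, numeric(length(patterns[[1]]))))
  else patterns
  stopifnot(nrow(features) == length(groups))
  acc_full <- loso_accuracy(features, groups, cost)
  boot <- boot_loso(features, groups, n_boot, frac, cost, seed)
  p <- (sum(boot <= 0.5) + 1) / (n_boot + 1)
  eeg_test(acc_full, p, "bootstrap LOSO SVM (HC vs MCI, patterns)",
           n_resamples = n_boot, side = "greater", seed = seed,
           estimate = mean(boot),
           ci = unname(stats::quantile(boot, c(0.025, 0.975))),
           se = stats::sd(boot), boot = boot)
}

#' HC vs MCI classification time course
#'
#' Convenience wrapper running \code{\link{classify_groups_timepoint}} at
#' several latencies with FDR correction across them.
#'
#' @param cohort list of per-subject \code{\link{eeg_epochs}}.
#' @param times_ms latencies to classify at.
#' @param channels optional channel restriction.
#' @inheritParams classify_groups_timepoint
#' @param alpha FDR level.
#' @return list: \code{times_ms}, \code{accuracy} (mean resample accuracy),
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{p_adjusted},
#'   \code{flags}, \code{n_bootstrap}.
#' @export
classify_groups_timecourse <- function(cohort, times_ms, channels = NULL,
                                       n_boot = 1000, frac = 0.8, cost = 1,
                                       alpha = 0.05, seed = NULL) {
  groups <- vapply(cohort, `[[`, "", "group")
  seeds <- derive_seeds(seed %||% stats::runif(1, 1, 1e6), length(times_ms))
  tests <- lapply(seq_along(times_ms), function(j) {
    pats <- lapply(cohort, activation_pattern, time_ms = times_ms[j],
                   channels = channels)
    classify_groups_timepoint(pats, groups, n_boot, frac, cost, seeds[j])
  })
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  fc <- fdr_correct(p, alpha)
  list(times_ms = times_ms,
       accuracy = vapply(tests, `[[`, numeric(1), "estimate"),
       ci_low = vapply(tests, function(t) t$ci[1], numeric(1)),
       ci_high = vapply(tests, function(t) t$ci[2], numeric(1)),
       p = p, p_adjusted = fc$adjusted, flags = fc$flags,
       n_bootstrap = n_boot)
}

#' HC vs MCI classification from RDMs
#'
#' Features are the upper-triangle vector of each subject's RDM at the
#' tested latency; accuracy is leave-one-subject-out CV with a linear SVM,
#' and the p-value comes from the same participant-subsampling bootstrap
#' as the pattern classifier.
#'
#' @param rdms list of per-subject RDM matrices (or \code{rdm_series};
#'   \code{time_ms} then selects the slice).
#' @param groups character group label per subject.
#' @param time_ms latency when series are supplied.
#' @inheritParams classify_groups_timepoint
#' @return an \code{\link{eeg_test}}; \code{statistic} is the full-sample
#'   LOSO accuracy.
#' @export
classify_groups_from_rdms <- function(rdms, groups, time_ms = NULL,
                                      n_boot = 10000, frac = 0.8, cost = 1,
                                      seed = NULL) {
  slice <- function(x) {
    if (inherits(x, "rdm_series")) {
      stopifnot(!is.null(time_ms))
      x$rdm[, , which.min(abs(x$times_ms - time_ms))]
    } else x
  }
  features <- t(vapply(rdms, function(r) upper_tri_vec(slice(r)),
                       numeric(sum(upper.tri(slice(rdms[[1]]))))))
  acc_full <- loso_accuracy(features, groups, cost)
  boot <- boot_loso(features, groups, n_boot, frac, cost, seed)
  p <- (sum(boot <= 0.5) + 1) / (n_boot + 1)
  eeg_test(acc_full, p, "bootstrap LOSO SVM (HC vs MCI, RDM)",
           n_resamples = n_boot, side = "greater", seed = seed,
           estimate = acc_full,
           ci = unname(stats::quantile(boot, c(0.025, 0.975))),
           se = stats::sd(boot), boot = boot)
}
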