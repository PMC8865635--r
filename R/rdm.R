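#' Pairwise-decoding RDM at one time-point
#'
#' For every pair of stimuli, the stratified leave-one-trial-out CV
#' accuracy (each fold holds out one trial of each stimulus, keeping the
#' training fold balanced) of a linear SVM discriminating the pair from
#' the scalp-channel patterns of their repetition trials at the requested
#' latency.  The result is a
#' symmetric stimulus x stimulus dissimilarity matrix with a zero
#' diagonal.
#'
#' @param epochs a preprocessed \code{\link{eeg_epochs}}; every stimulus
#'   needs at least 2 repetition trials.
#' @param time_ms latency (nearest sample used).
#' @param cost SVM cost.
#' @param channels optional channel restriction.
#' @return symmetric matrix, dimnames = stimulus ids.
#' @export
compute_rdm <- function(epochs, time_ms, cost = 1, channels = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!is.null(channels)) epochs <- select_channels(epochs, channels)
  tt <- nearest_sample(epochs, time_ms)
  X <- epochs$data[, , tt]                     # trials x channels
  stim <- sort(unique(epochs$stimulus_id))
  counts <- table(epochs$stimulus_id)
  if (any(counts < 2)) stop("every stimulus needs at least 2 trials")
  ns <- length(stim)
  rdm <- matrix(0, ns, ns, dimnames = list(stim, stim))
  trials_of <- lapply(stim, function(s) which(epochs$stimulus_id == s))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      ti <- trials_of[[i]]; tj <- trials_of[[j]]
      x <- X[c(ti, tj), , drop = FALSE]
      y <- rep(c("a", "b"), c(length(ti), length(tj)))
      rdm[i, j] <- rdm[j, i] <- loo_cv_accuracy(x, y, cost)
    }
  }
  rdm
}

#' RDM series over time for one subject
#'
#' @inheritParams compute_rdm
#' @param times_ms latencies at which to compute RDMs.
#' @return object of class \code{rdm_series}: array stimuli x stimuli x
#'   time plus \code{times_ms}, subject metadata.
#' @export
compute_rdm_series <- function(epochs, times_ms, cost = 1, channels = NULL) {
  rdms <- lapply(times_ms, function(t) compute_rdm(epochs, t, cost, channels))
  a <- array(unlist(rdms), c(dim(rdms[[1]]), length(times_ms)),
             dimnames = c(dimnames(rdms[[1]]), list(NULL)))
  structure(list(rdm = a, times_ms = times_ms,
                 subject_id = epochs$subject_id, group = epochs$group),
            class = "rdm_series")
}

upper_tri_vec <- function(m) m[upper.tri(m)]

group_mean_rdm <- function(series_list, j) {
  Reduce(`+`, lapply(series_list, function(s) s$rdm[, , j])) /
    length(series_list)
}

#' Time course of the distance between group-mean RDMs
#'
#' At each time-point, the Euclidean distance between the upper triangles
#' of the HC-mean and MCI-mean RDMs.  The maximum over time is located and
#' tested with a permutation test that shuffles subjects between groups;
#' distances are also rescaled to [0, 1] by \code{\link{scale_distance}}
#' using (0, mean pre-stimulus distance, maximum distance) as anchors.
#' The raw distance is authoritative; the scaled value is a monotone
#' convenience.
#'
#' @param hc_series,mci_series lists of \code{rdm_series} with identical
#'   stimulus sets and time axes.
#' @param n_perm permutations for the p-value at the maximum.
#' @param baseline_image target image of the baseline anchor under the
#'   scaling map.
#' @param seed RNG seed.
#' @return list: \code{times_ms}, \code{distance}, \code{scaled},
#'   \code{anchors}, \code{max_time_ms}, \code{d_max}, \code{p_value},
#'   \code{test}.
#' @export
rdm_distance_timecourse <- function(hc_series, mci_series, n_perm = 1000,
                                    baseline_image = 0.5, seed = NULL) {
  tms <- hc_series[[1]]$times_ms
  stopifnot(identical(tms, mci_series[[1]]$times_ms),
            identical(dim(hc_series[[1]]$rdm)[1:2],
                      dim(mci_series[[1]]$rdm)[1:2]))
  nt <- length(tms)
  d <- vapply(seq_len(nt), function(j)
    sqrt(sum((upper_tri_vec(group_mean_rdm(hc_series, j)) -
                upper_tri_vec(group_mean_rdm(mci_series, j)))^2)),
    numeric(1))
  jmax <- which.max(d)
  # permutation p at the maximum-distance time-point
  all_rdms <- c(lapply(hc_series, function(s) upper_tri_vec(s$rdm[, , jmax])),
                lapply(mci_series, function(s) upper_tri_vec(s$rdm[, , jmax])))
  n_hc <- length(hc_series); n_all <- length(all_rdms)
  dist_stat <- function(idx) {
    m1 <- Reduce(`+`, all_rdms[idx]) / length(idx)
    m2 <- Reduce(`+`, all_rdms[-idx]) / (n_all - length(idx))
    sqrt(sum((m1 - m2)^2))
  }
  obs <- dist_stat(seq_len(n_hc))
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    dist_stat(sample.int(n_all, n_hc)), numeric(1)))
  p <- (sum(null >= obs - 1e-12) + 1) / (n_perm + 1)
  base <- if (any(tms < 0)) mean(d[tms < 0]) else stats::median(d)
  anchors <- c(min = 0, baseline = base, max = max(d))
  # degenerate anchor layouts (e.g. all distances zero, or the maximum in
  # the baseline) cannot support the anchored map; fall back to linear
  scaled <- if (anchors[["min"]] < anchors[["baseline"]] &&
                anchors[["baseline"]] < anchors[["max"]])
    scale_distance(d, anchors, baseline_image)
  else if (max(d) > min(d)) (d - min(d)) / (max(d) - min(d))
  else rep(0, length(d))
  list(times_ms = tms, distance = d, scaled = scaled, anchors = anchors,
       max_time_ms = tms[jmax], d_max = d[jmax], p_value = p,
       test = eeg_test(obs, p, "permutation (group RDM distance)",
                       n_resamples = n_perm, side = "greater", seed = seed))
}

#' Monotone rescaling of RDM distances to [0, 1]
#'
#' Logarithmic family \code{f(d) = log(1 + (d - min)/k) /
#' log(1 + (max - min)/k)} mapping the minimum anchor to 0 and the maximum
#' anchor to 1, with the curvature parameter \code{k} solved so the
#' baseline anchor maps to \code{baseline_image}.  The family is concave,
#' so images at or below the linear map \code{(d - min)/(max - min)} are
#' unattainable; in that case the linear map is used with a warning.
#' Distances outside [min, max] are clamped with a warning.
#'
#' @param d numeric distances.
#' @param anchors named numeric c(min, baseline, max), min < baseline <
#'   max.
#' @param baseline_image requested image of the baseline anchor in (0, 1).
#' @return rescaled values in [0, 1].
#' @export
scale_distance <- function(d, anchors, baseline_image = 0.5) {
  a_min <- anchors[["min"]]; a_base <- anchors[["baseline"]]
  a_max <- anchors[["max"]]
  stopifnot(a_min < a_base, a_base < a_max,
            baseline_image > 0, baseline_image < 1)
  if (any(d < a_min - 1e-12 | d > a_max + 1e-12)) {
    warning("distances outside the anchor range clamped")
    d <- pmin(pmax(d, a_min), a_max)
  }
  lin_base <- (a_base - a_min) / (a_max - a_min)
  f <- function(k) log1p((d - a_min) / k) / log1p((a_max - a_min) / k)
  if (baseline_image <= lin_base + 1e-9) {
    if (baseline_image < lin_base - 1e-9)
      warning("baseline image below the linear map is unattainable with a ",
              "concave log scaling; using the linear map")
    return((d - a_min) / (a_max - a_min))
  }
  g <- function(logk) {
    k <- exp(logk)
    log1p((a_base - a_min) / k) / log1p((a_max - a_min) / k) - baseline_image
  }
  sol <- stats::uniroot(g, c(-30, 30), extendInt = "yes")
  f(exp(sol$root))
}

#' Cell-wise group comparison of RDMs at one latency
#'
#' Rank-sum test between groups for every upper-triangle cell across
#' subjects, FDR-corrected over the cells (496 for 32 stimuli).
#'
#' @param hc_rdms,mci_rdms lists of per-subject RDM matrices at the tested
#'   latency (or \code{rdm_series}, in which case \code{time_ms} selects
#'   the slice).
#' @param time_ms latency when series are supplied.
#' @param alpha FDR level.
#' @return list with symmetric matrices \code{p}, \code{p_adjusted} and
#'   logical \code{flags}.
#' @export
rdm_cellwise_comparison <- function(hc_rdms, mci_rdms, time_ms = NULL,
                                    alpha = 0.05) {
  slice <- function(x) {
    if (inherits(x, "rdm_series")) {
      stopifnot(!is.null(time_ms))
      x$rdm[, , which.min(abs(x$times_ms - time_ms))]
    } else x
  }
  hc <- lapply(hc_rdms, slice); mci <- lapply(mci_rdms, slice)
  ns <- nrow(hc[[1]])
  ut <- which(upper.tri(matrix(0, ns, ns)))
  hv <- vapply(hc, upper_tri_vec, numeric(length(ut)))
  mv <- vapply(mci, upper_tri_vec, numeric(length(ut)))
  p_ut <- vapply(seq_along(ut), function(i) {
    x <- hv[i, ]; y <- mv[i, ]
    if (length(unique(c(x, y))) == 1L) return(NA_real_)
    ranksum_test(x, y)$p_value
  }, numeric(1))
  fc <- fdr_correct(p_ut, alpha)
  mk <- function(v, fill = NA) {
    m <- matrix(fill, ns, ns, dimnames = dimnames(hc[[1]]))
    m[ut] <- v; m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  list(p = mk(p_ut), p_adjusted = mk(fc$adjusted),
       flags = mk(fc$flags, FALSE))
}

#' Metric MDS embedding of an RDM
#'
#' Classical scaling initialisation refined by Sammon's metric-stress
#' mapping; the achieved stress is reported.  Stimuli with identical
#' dissimilarity profiles are separated by a tiny jitter before
#' refinement (Sammon mapping requires positive off-diagonal distances).
#'
#' @param rdm symmetric dissimilarity matrix, zero diagonal.
#' @param dims embedding dimension.
#' @param seed RNG seed (jitter only).
#' @return list with \code{points} (stimuli x dims) and \code{stress}.
#' @export
mds_embed <- function(rdm, dims = 2, seed = 1L) {
  if (!isSymmetric(unname(rdm), tol = 1e-8))
    stop("RDM must be symmetric")
  d <- as.matrix(rdm); diag(d) <- 0
  off <- d[upper.tri(d)]
  if (any(off <= 0)) {
    eps <- max(1e-6, 1e-3 * stats::median(off[off > 0], na.rm = TRUE))
    d[upper.tri(d)] <- pmax(off, eps)
    d[lower.tri(d)] <- t(d)[lower.tri(d)]
  }
  init <- stats::cmdscale(d, k = dims, add = TRUE)$points
  init <- init + with_seed(seed, matrix(stats::rnorm(length(init), 0, 1e-8),
                                        nrow(init)))
  fit <- tryCatch(MASS::sammon(stats::as.dist(d), y = init, trace = FALSE),
                  error = function(e) NULL)
  if (is.null(fit)) {
    emb <- init
    dd <- as.matrix(stats::dist(emb))
    stress <- sum((d - dd)[upper.tri(d)]^2 / d[upper.tri(d)]) /
      sum(d[upper.tri(d)])
    return(list(points = emb, stress = stress))
  }
  list(points = fit$points, stress = fit$stress)
}
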