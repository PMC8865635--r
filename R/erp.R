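# 63-electrode montage (10-10 names) partitioned into the 23 named scalp
# regions used for region-level summaries. Frontal channels come first so
# frontally-projected blink artifacts land on the leading rows.
montage_63 <- list(
  Fp  = c("Fp1", "Fpz", "Fp2"),
  AFL = c("AF7", "AF3"),
  AFR = c("AF4", "AF8"),
  FL  = c("F7", "F5", "F3"),
  Fz  = c("F1", "Fz", "F2"),
  FR  = c("F4", "F6", "F8"),
  FCL = c("FC5", "FC3", "FC1"),
  FCR = c("FC2", "FC4", "FC6"),
  TL  = c("T9", "FT7", "T7"),
  TR  = c("FT8", "T8", "T10"),
  CL  = c("C5", "C3", "C1"),
  Cz  = "Cz",
  CR  = c("C2", "C4", "C6"),
  TPL = "TP7",
  TPR = "TP8",
  CPL = c("CP5", "CP3", "CP1"),
  CPR = c("CP2", "CP4", "CP6"),
  PL  = c("P9", "P7", "P5", "P3", "P1"),
  PR  = c("P2", "P4", "P6", "P8", "P10"),
  Pz  = c("CPz", "Pz"),
  POL = c("PO7", "PO3"),
  POR = c("PO4", "PO8"),
  O   = c("POz", "O1", "Oz", "O2")
)

#' Default scalp channel names
#'
#' The packaged 63-electrode montage names when \code{n = 63}; generic
#' \code{Ch01..ChNN} otherwise (reduced simulated designs).
#'
#' @param n number of scalp channels.
#' @return character vector of length \code{n}.
#' @export
default_channel_names <- function(n = 63) {
  if (n == 63) unname(unlist(montage_63))
  else sprintf("Ch%02d", seq_len(n))
}

#' Default channel-group map
#'
#' Named list mapping each of the 23 scalp regions (Fp, AFL, AFR, FL, Fz,
#' FR, FCL, FCR, TL, CL, Cz, CR, TR, TPL, CPL, CPR, TPR, PL, PR, POL, Pz,
#' POR, O) to its channel names.  For channel counts other than 63 the
#' channels are split into \code{n_groups} contiguous generic regions.
#'
#' @param n_channels number of scalp channels.
#' @param n_groups number of generic regions for non-63-channel layouts.
#' @return named list of character vectors.
#' @export
default_channel_groups <- function(n_channels = 63,
                                   n_groups = min(4, n_channels)) {
  if (n_channels == 63) return(montage_63)
  nm <- default_channel_names(n_channels)
  split(nm, paste0("R", cut(seq_len(n_channels), n_groups, labels = FALSE)))
}

#' Read a channel-group map from a delimited file
#'
#' Expects a two-column header-bearing table (\code{channel_name},
#' \code{group_name}), tab- or comma-delimited.
#'
#' @param path file path.
#' @return named list: group name -> character vector of channel names.
#' @export
read_channel_groups <- function(path) {
  tab <- utils::read.delim(path, sep = "", stringsAsFactors = FALSE)
  stopifnot(all(c("channel_name", "group_name") %in% names(tab)))
  if (anyDuplicated(tab$channel_name))
    stop("duplicate channel names in channel-group map")
  split(tab$channel_name, tab$group_name)
}

#' Write a channel-group map
#' @param groups named list as returned by \code{\link{default_channel_groups}}.
#' @param path output path (tab-delimited).
#' @return the written data frame, invisibly.
#' @export
write_channel_groups <- function(groups, path) {
  tab <- data.frame(channel_name = unlist(groups, use.names = FALSE),
                    group_name = rep(names(groups), lengths(groups)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

# Resolve a name-based group map to channel indices of a dataset.
resolve_channel_groups <- function(groups, channel_names) {
  lapply(groups, function(ch) {
    idx <- match(ch, channel_names)
    if (anyNA(idx))
      stop("unknown channel(s) in map: ",
           paste(ch[is.na(idx)], collapse = ", "))
    idx
  })
}

#' Region-level event-related potentials of one subject
#'
#' Averages the epochs over trials, then over the channels within each
#' region of the group map: one waveform per region.
#'
#' @param epochs an \code{\link{eeg_epochs}} with at least one trial.
#' @param groups channel-group map (named list of channel names); defaults
#'   to the packaged montage for 63 channels.
#' @return object of class \code{erp_result}: list with \code{waveforms}
#'   (regions x time matrix), \code{times_ms}, \code{subject_id},
#'   \code{group}.
#' @export
compute_erp <- function(epochs,
                        groups = default_channel_groups(dim(epochs$data)[2])) {
  stopifnot(inherits(epochs, "eeg_epochs"), dim(epochs$data)[1] >= 1)
  idx <- resolve_channel_groups(groups, epochs$channel_names)
  trial_mean <- apply(epochs$data, c(2, 3), mean)   # channels x time
  w <- t(vapply(idx, function(i)
    colMeans(trial_mean[i, , drop = FALSE]), numeric(dim(epochs$data)[3])))
  rownames(w) <- names(groups)
  structure(list(waveforms = w, times_ms = epochs$times_ms,
                 subject_id = epochs$subject_id, group = epochs$group),
            class = "erp_result")
}

#' Stack per-subject ERPs of one region
#'
#' @param erps list of \code{erp_result}.
#' @param region region name.
#' @return subjects x time matrix.
#' @export
erp_stack <- function(erps, region) {
  t(vapply(erps, function(e) e$waveforms[region, ],
           numeric(ncol(erps[[1]]$waveforms))))
}

#' Cohort-average ERP
#'
#' The cohort ERP is the mean of the corresponding participants' ERPs.
#'
#' @param erps list of \code{erp_result} (same regions/time axis).
#' @return regions x time matrix.
#' @export
cohort_erp <- function(erps) {
  Reduce(`+`, lapply(erps, `[[`, "waveforms")) / length(erps)
}

#' Sign-rank significance of per-subject values against zero
#'
#' One Wilcoxon sign-rank test per column of the observation matrix
#' (columns index the tested family: time-points or regions), FDR-corrected
#' across the family.  Constant columns get p = NA and are never flagged.
#'
#' @param values subjects x K numeric matrix.
#' @param alpha FDR level.
#' @return list with \code{p}, \code{p_adjusted}, \code{flags}.
#' @export
erp_significance_vs_baseline <- function(values, alpha = 0.05) {
  stopifnot(is.matrix(values), nrow(values) >= 2)
  p <- apply(values, 2, function(v) {
    if (all(v == 0)) return(NA_real_)
    signrank_test(v)$p_value
  })
  if (anyNA(p)) warning("constant (all-zero) columns flagged non-significant")
  fc <- fdr_correct(p, alpha)
  list(p = p, p_adjusted = fc$adjusted, flags = fc$flags)
}

#' Group ERP difference with rank-sum flags and bootstrap CI
#'
#' Per column (time-point), a two-sided rank-sum test between the groups'
#' per-subject values, FDR-corrected across columns; plus the HC-minus-MCI
#' mean difference waveform with a percentile-bootstrap 95\% CI over
#' subjects.
#'
#' @param hc_values,mci_values subjects x K matrices.
#' @param alpha FDR level.
#' @param n_boot bootstrap resamples for the CI.
#' @param seed RNG seed.
#' @return list with \code{difference}, \code{ci_low}, \code{ci_high},
#'   \code{p}, \code{p_adjusted}, \code{flags}.
#' @export
erp_group_difference <- function(hc_values, mci_values, alpha = 0.05,
                                 n_boot = 1000, seed = NULL) {
  stopifnot(is.matrix(hc_values), is.matrix(mci_values),
            ncol(hc_values) == ncol(mci_values),
            nrow(hc_values) >= 2, nrow(mci_values) >= 2)
  K <- ncol(hc_values)
  p <- vapply(seq_len(K), function(j) {
    x <- hc_values[, j]; y <- mci_values[, j]
    if (length(unique(c(x, y))) == 1L) return(NA_real_)
    ranksum_test(x, y)$p_value
  }, numeric(1))
  fc <- fdr_correct(p, alpha)
  diff_obs <- colMeans(hc_values) - colMeans(mci_values)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(nrow(hc_values), replace = TRUE)
      j <- sample.int(nrow(mci_values), replace = TRUE)
      colMeans(hc_values[i, , drop = FALSE]) -
        colMeans(mci_values[j, , drop = FALSE])
    }, numeric(K))
  })
  boot <- matrix(boot, nrow = K)
  list(difference = diff_obs,
       ci_low = apply(boot, 1, stats::quantile, 0.025),
       ci_high = apply(boot, 1, stats::quantile, 0.975),
       p = p, p_adjusted = fc$adjusted, flags = fc$flags)
}
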