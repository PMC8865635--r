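#' Run the full synthetic-cohort study and summarise it
#'
#' Simulates a two-group cohort, runs per-subject time-resolved animacy
#' decoding, compares group peak latencies, computes RDM series and the
#' group RDM-distance time course, and classifies HC vs MCI from
#' activation patterns at the decoding peak.  Every numeric in the result
#' is computed at run time from the given seed.
#'
#' @param design a \code{\link{synthetic_design}}.
#' @param effects a \code{\link{group_effects}}.
#' @param n_hc,n_mci subjects per group.
#' @param times_ms latencies analysed (default: every
#'   \code{decim}-th sample of the epoch).
#' @param decim take every \code{decim}-th sample when \code{times_ms} is
#'   NULL.
#' @param n_repetitions bin-randomisation repetitions per time-point.
#' @param n_boot bootstrap resamples for group tests.
#' @param rdm_times_ms latencies at which RDMs are computed (default: the
#'   decoding latencies thinned to at most 12).
#' @param seed master seed.
#' @return list of tidy components: \code{accuracy} (subject x time table),
#'   \code{peaks}, \code{latency_test}, \code{rdm_distance},
#'   \code{group_classification}, \code{seed}.
#' @export
run_study <- function(design = synthetic_design(), effects = group_effects(),
                      n_hc = 6, n_mci = 6, times_ms = NULL, decim = 10,
                      n_repetitions = 50, n_boot = 1000,
                      rdm_times_ms = NULL, seed = 1L) {
  cohort <- generate_cohort(design, effects, n_hc, n_mci, seed)
  groups <- vapply(cohort, `[[`, "", "group")
  if (is.null(times_ms)) {
    tm <- cohort[[1]]$times_ms
    times_ms <- tm[seq(1, length(tm), by = decim)]
  }
  seeds <- derive_seeds(seed + 1L, length(cohort) + 3L)
  courses <- lapply(seq_along(cohort), function(i)
    decode_timecourse(cohort[[i]],
                      decoder_config(n_repetitions = n_repetitions,
                                     seed = seeds[i]),
                      times_ms = times_ms))
  acc_tab <- do.call(rbind, lapply(courses, function(cc)
    data.frame(subject_id = cc$subject_id, group = cc$group,
               time_ms = cc$times_ms, accuracy = cc$accuracy)))
  peaks <- data.frame(
    subject_id = vapply(courses, `[[`, "", "subject_id"),
    group = groups,
    peak_time_ms = vapply(courses, `[[`, numeric(1), "peak_time_ms"),
    peak_accuracy = vapply(courses, `[[`, numeric(1), "peak_accuracy"))
  lat <- compare_peak_latency(courses[groups == "HC"],
                              courses[groups == "MCI"],
                              n_boot = n_boot, seed = seeds[length(cohort) + 1L])
  if (is.null(rdm_times_ms))
    rdm_times_ms <- times_ms[seq(1, length(times_ms),
                                 length.out = min(12, length(times_ms)))]
  series <- lapply(cohort, compute_rdm_series, times_ms = rdm_times_ms)
  rdist <- rdm_distance_timecourse(series[groups == "HC"],
                                   series[groups == "MCI"],
                                   n_perm = n_boot,
                                   seed = seeds[length(cohort) + 2L])
  peak_t <- stats::median(peaks$peak_time_ms)
  pats <- lapply(cohort, activation_pattern, time_ms = peak_t)
  gc <- classify_groups_timepoint(pats, groups, n_boot = n_boot,
                                  seed = seeds[length(cohort) + 3L])
  list(accuracy = acc_tab, peaks = peaks, latency_test = lat,
       rdm_distance = rdist, group_classification = gc,
       classification_time_ms = peak_t, seed = seed)
}

#' Write a study summary as delimited tables
#'
#' @param study result of \code{\link{run_study}}.
#' @param dir output directory (created if needed).
#' @return vector of written paths, invisibly.
#' @export
write_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) {
    p <- file.path(dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  lat <- as.data.frame(study$latency_test)
  summ <- data.frame(
    quantity = c("median_peak_delay_ms", "latency_p", "rdm_max_time_ms",
                 "rdm_d_max", "rdm_p", "group_classification_accuracy",
                 "group_classification_p", "classification_time_ms", "seed"),
    value = c(study$latency_test$estimate, study$latency_test$p_value,
              study$rdm_distance$max_time_ms, study$rdm_distance$d_max,
              study$rdm_distance$p_value, study$group_classification$estimate,
              study$group_classification$p_value,
              study$classification_time_ms, study$seed))
  paths <- c(w(study$accuracy, "accuracy.tsv"),
             w(study$peaks, "peaks.tsv"),
             w(lat, "latency_test.tsv"),
             w(data.frame(time_ms = study$rdm_distance$times_ms,
                          distance = study$rdm_distance$distance,
                          scaled = study$rdm_distance$scaled),
               "rdm_distance.tsv"),
             w(summ, "summary.tsv"))
  invisible(paths)
}
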