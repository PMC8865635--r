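#' Result container for a statistical test
#'
#' Light S3 wrapper used by every test in the package so that resampling
#' metadata (method, resample count, sidedness, seed) travels with the
#' statistic and p-value.
#'
#' @param statistic observed statistic.
#' @param p_value p-value in (0, 1].
#' @param method method label.
#' @param n_resamples resamples/permutations used (NA for analytic tests).
#' @param side "greater", "less" or "two.sided".
#' @param seed RNG seed used, if any.
#' @param estimate point estimate (often equals \code{statistic}).
#' @param ci length-2 confidence interval, if available.
#' @param se standard error, if available.
#' @param boot resampling distribution, if retained.
#' @return an object of class \code{eeg_test}.
#' @export
eeg_test <- function(statistic, p_value, method, n_resamples = NA,
                     side = "two.sided", seed = NULL, estimate = statistic,
                     ci = NULL, se = NULL, boot = NULL) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n_resamples = n_resamples, side = side, seed = seed,
                 estimate = estimate, ci = ci, se = se, boot = boot),
            class = "eeg_test")
}

#' @export
print.eeg_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (%s", x$method, x$statistic,
              x$p_value, x$side))
  if (!is.na(x$n_resamples)) cat(sprintf(", %d resamples", x$n_resamples))
  cat(")\n")
  if (!is.null(x$ci))
    cat(sprintf("  estimate %.4g, 95%% CI [%.4g, %.4g]", x$estimate,
                x$ci[1], x$ci[2]),
        if (!is.null(x$se)) sprintf(", SE %.4g", x$se) else "", "\n")
  invisible(x)
}

#' Convert a test result to a tidy one-row record
#' @param x an \code{eeg_test}.
#' @param ... unused.
#' @return one-row data frame.
#' @export
as.data.frame.eeg_test <- function(x, ...) {
  data.frame(method = x$method, statistic = x$statistic,
             estimate = x$estimate, p_value = x$p_value, side = x$side,
             n_resamples = x$n_resamples,
             ci_low = if (is.null(x$ci)) NA else x$ci[1],
             ci_high = if (is.null(x$ci)) NA else x$ci[2],
             se = x$se %||% NA)
}

resample_group <- function(v, frac, replace) {
  n <- length(v)
  if (replace) v[sample.int(n, n, replace = TRUE)]
  else v[sample.int(n, ceiling(frac * n))]
}

#' Bootstrap test of a statistic against a baseline
#'
#' Resamples the input (each group independently when \code{samples} is a
#' list), recomputes the statistic, and computes the p-value as
#' \code{(count of resampled statistics on the null side of baseline + 1) /
#' (n + 1)}, so the smallest attainable p-value is \code{1 / (n + 1)}
#' (0.0001 rounded to four decimals at the default 10,000 resamples).
#' The default resampling scheme draws 80\% of each group without
#' replacement, i.e. repeated subsampling of participants.
#'
#' @param samples numeric vector, or list of numeric vectors (one per
#'   group), passed to \code{statistic}.
#' @param statistic function mapping (resampled) \code{samples} to a
#'   scalar.
#' @param baseline null value the bootstrap distribution is compared
#'   against.
#' @param n number of resamples.
#' @param side "greater" (alternative: statistic > baseline), "less", or
#'   "two.sided".
#' @param frac subsample fraction per group when \code{replace = FALSE}.
#' @param replace draw with replacement (classical bootstrap) instead of
#'   subsampling.
#' @param seed RNG seed.
#' @return an \code{\link{eeg_test}} carrying the bootstrap distribution,
#'   percentile 95\% CI and bootstrap SE of the statistic.
#' @export
bootstrap_test <- function(samples, statistic, baseline = 0, n = 10000,
                           side = c("greater", "less", "two.sided"),
                           frac = 0.8, replace = FALSE, seed = NULL) {
  side <- match.arg(side)
  stopifnot(n >= 1)
  grouped <- is.list(samples)
  if (grouped) stopifnot(all(lengths(samples) >= 1))
  else stopifnot(length(samples) >= 1)
  obs <- statistic(samples)
  boot <- with_seed(seed, vapply(seq_len(n), function(i) {
    rs <- if (grouped) lapply(samples, resample_group, frac, replace)
          else resample_group(samples, frac, replace)
    statistic(rs)
  }, numeric(1)))
  p_greater <- (sum(boot <= baseline) + 1) / (n + 1)
  p_less <- (sum(boot >= baseline) + 1) / (n + 1)
  p <- switch(side, greater = p_greater, less = p_less,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  eeg_test(obs, p, "bootstrap", n_resamples = n, side = side, seed = seed,
           ci = unname(stats::quantile(boot, c(0.025, 0.975))),
           se = stats::sd(boot), boot = boot)
}

#' Two-sample permutation test
#'
#' Forms the null distribution by relabeling observations between the two
#' groups.  When the number of distinct relabelings \code{choose(n1+n2, n1)}
#' does not exceed \code{n}, all of them are enumerated and the p-value is
#' exact (the observed labeling counts as one of them); otherwise \code{n}
#' random relabelings are drawn and \code{p = (count + 1) / (n + 1)}.
#'
#' @param x,y numeric samples of the two groups.
#' @param statistic function of (x, y) returning a scalar; default
#'   difference of means.
#' @param n maximum number of relabelings.
#' @param side "two.sided" (default), "greater" or "less".
#' @param seed RNG seed (random mode only).
#' @return an \code{\link{eeg_test}}.
#' @export
permutation_test <- function(x, y, statistic = function(x, y) mean(x) - mean(y),
                             n = 10000, side = c("two.sided", "greater", "less"),
                             seed = NULL) {
  side <- match.arg(side)
  stopifnot(length(x) >= 1, length(y) >= 1)
  obs <- statistic(x, y)
  pool <- c(x, y); nx <- length(x); nt <- length(pool)
  n_exact <- choose(nt, nx)
  tol <- 1e-12 * (1 + abs(obs))
  if (n_exact <= n) {
    idx <- utils::combn(nt, nx)
    null <- apply(idx, 2, function(i) statistic(pool[i], pool[-i]))
    pg <- sum(null >= obs - tol) / n_exact
    pl <- sum(null <= obs + tol) / n_exact
    n_used <- n_exact; exact <- TRUE
  } else {
    null <- with_seed(seed, vapply(seq_len(n), function(i) {
      i1 <- sample.int(nt, nx)
      statistic(pool[i1], pool[-i1])
    }, numeric(1)))
    pg <- (sum(null >= obs - tol) + 1) / (n + 1)
    pl <- (sum(null <= obs + tol) + 1) / (n + 1)
    n_used <- n; exact <- FALSE
  }
  p <- switch(side, greater = pg, less = pl,
              two.sided = min(1, 2 * min(pg, pl)))
  eeg_test(obs, p, if (exact) "permutation (exhaustive)" else "permutation",
           n_resamples = n_used, side = side, seed = seed, boot = null)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p-value for small tie-free samples, normal approximation with
#' continuity and tie correction otherwise (the \code{stats::wilcox.test}
#' defaults).  All-tied data yield p = 1 with a warning.
#'
#' @param x,y numeric samples.
#' @param side "two.sided" (default), "greater" or "less".
#' @return an \code{\link{eeg_test}}.
#' @export
ranksum_test <- function(x, y, side = "two.sided") {
  if (length(unique(c(x, y))) == 1L) {
    warning("all observations tied; rank-sum p-value set to 1")
    return(eeg_test(NA_real_, 1, "rank-sum", side = side))
  }
  w <- suppressWarnings(stats::wilcox.test(x, y, alternative = side))
  eeg_test(unname(w$statistic), w$p.value, "rank-sum", side = side)
}

#' Wilcoxon signed-rank test against a null value
#'
#' @param x numeric sample.
#' @param mu null location.
#' @param side "two.sided" (default), "greater" or "less".
#' @return an \code{\link{eeg_test}}.
#' @export
signrank_test <- function(x, mu = 0, side = "two.sided") {
  if (all(x == mu)) {
    warning("all observations equal the null value; sign-rank p-value set to 1")
    return(eeg_test(NA_real_, 1, "sign-rank", side = side))
  }
  w <- suppressWarnings(stats::wilcox.test(x, mu = mu, alternative = side))
  eeg_test(unname(w$statistic), w$p.value, "sign-rank", side = side)
}

#' Benjamini-Hochberg FDR correction
#'
#' @param p_values vector of p-values (NA allowed; never flagged).
#' @param alpha FDR level.
#' @return list with \code{adjusted} p-values and logical \code{flags}
#'   (\code{adjusted <= alpha}).
#' @export
fdr_correct <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L)
    return(list(adjusted = numeric(0), flags = logical(0)))
  adj <- stats::p.adjust(p_values, method = "BH")
  flags <- !is.na(adj) & adj <= alpha
  list(adjusted = adj, flags = flags)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (Student) two-sided t-test computed from group means,
#' SDs and sizes, as used for demographic tables; Welch's unequal-variance
#' form is available behind a flag.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param welch use Welch's approximation instead of pooled variance.
#' @return an \code{\link{eeg_test}} with the t statistic and two-sided p.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    tval <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  p <- 2 * stats::pt(-abs(tval), df)
  eeg_test(tval, p, if (welch) "Welch t (summary)" else "pooled t (summary)",
           estimate = mean1 - mean2)
}
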