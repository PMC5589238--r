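#' Per-dyad change scores
#'
#' Computes, for the complete-case cohort, the biomarker change scores
#' (always post minus pre), per-dyad percent changes relative to baseline,
#' and cohort-standardized z-scores of the changes.
#'
#' @param cohort a [cohort_table()]; rows with any missing hormone value are
#'   dropped first via [complete_cases()].
#' @return a data frame of class `"change_scores"` with columns `dyad_id`,
#'   the four raw hormone columns, `delta_cortisol`, `delta_crf` (measure
#'   units), `pct_change_cortisol`, `pct_change_crf` (fractions of
#'   baseline), and `z_delta_cortisol`, `z_delta_crf` (dimensionless,
#'   standardized with the sample n-1 SD; mean 0, SD 1 over the cohort).
#' @export
compute_changes <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  cc <- suppressMessages(complete_cases(cohort))
  if (nrow(cc) < 2) stop("need at least 2 complete-case dyads")
  delta_cortisol <- cc$cortisol_post - cc$cortisol_pre
  delta_crf <- cc$crf_post - cc$crf_pre
  zc <- function(x, label) {
    s <- stats::sd(x)
    if (s == 0) stop("zero variance of ", label, ": z-scores undefined")
    (x - mean(x)) / s
  }
  out <- data.frame(
    dyad_id = cc$dyad_id,
    cortisol_pre = cc$cortisol_pre, cortisol_post = cc$cortisol_post,
    crf_pre = cc$crf_pre, crf_post = cc$crf_post,
    delta_cortisol = delta_cortisol,
    delta_crf = delta_crf,
    pct_change_cortisol = delta_cortisol / cc$cortisol_pre,
    pct_change_crf = delta_crf / cc$crf_pre,
    z_delta_cortisol = zc(delta_cortisol, "delta_cortisol"),
    z_delta_crf = zc(delta_crf, "delta_crf"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("change_scores", "data.frame")
  out
}

#' Pre/post summary statistics
#'
#' Container for the printed summary statistics of a paired pre/post
#' measure, sufficient (with the change-score identity) to recover the
#' baseline-delta coupling without raw data.
#'
#' @param mean_pre,sd_pre,mean_post,sd_post means and sample SDs, measure units.
#' @param r_pre_post Pearson correlation of pre with post, in (-1, 1).
#' @param n number of pairs, at least 2.
#' @return a list of class `"summary_stats"`.
#' @export
summary_stats <- function(mean_pre, sd_pre, mean_post, sd_post, r_pre_post, n) {
  if (sd_pre <= 0 || sd_post <= 0) stop("SDs must be positive")
  if (abs(r_pre_post) >= 1) stop("r_pre_post must lie in (-1, 1)")
  if (n < 2) stop("n must be at least 2")
  structure(list(mean_pre = mean_pre, sd_pre = sd_pre, mean_post = mean_post,
                 sd_post = sd_post, r_pre_post = r_pre_post, n = as.integer(n)),
            class = "summary_stats")
}

#' Empirical pre/post summary statistics from raw pairs
#'
#' @param pre,post equal-length numeric vectors.
#' @return a [summary_stats()] computed with sample (n-1) SDs.
#' @export
empirical_summary <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  summary_stats(mean(pre), stats::sd(pre), mean(post), stats::sd(post),
                stats::cor(pre, post), length(pre))
}

#' Change-score identity
#'
#' Closed-form relations giving the SD of the change score and its
#' correlations with baseline and follow-up from the pre/post SDs and their
#' correlation alone:
#' \deqn{sd(\Delta) = \sqrt{s_{pre}^2 + s_{post}^2 - 2 r s_{pre} s_{post}}}
#' \deqn{r(pre, \Delta) = (r\,s_{post} - s_{pre}) / sd(\Delta)}
#' \deqn{r(\Delta, post) = (s_{post} - r\,s_{pre}) / sd(\Delta)}
#' These hold exactly for any sample when fed that sample's own moments, and
#' in population for any bivariate distribution with the given moments. They
#' expose how a strong negative baseline-delta correlation (e.g. -0.84 for
#' cortisol with printed SDs 7.09/5.61 and r = -0.24) is implied by the
#' printed summary statistics themselves.
#'
#' @param s a [summary_stats()].
#' @return a list of class `"identity_result"` with `sd_delta` (measure
#'   units), `r_pre_delta`, `r_delta_post`.
#' @export
change_identity <- function(s) {
  stopifnot(inherits(s, "summary_stats"))
  sd_delta <- sqrt(s$sd_pre^2 + s$sd_post^2 - 2 * s$r_pre_post * s$sd_pre * s$sd_post)
  if (sd_delta == 0) {
    stop("sd_delta is 0 (perfect positive coupling with equal SDs): correlations undefined")
  }
  structure(list(
    sd_delta = sd_delta,
    r_pre_delta = (s$r_pre_post * s$sd_post - s$sd_pre) / sd_delta,
    r_delta_post = (s$sd_post - s$r_pre_post * s$sd_pre) / sd_delta
  ), class = "identity_result")
}

#' Paired t test on pre minus post
#'
#' Thin wrapper around [stats::t.test()] with the sign convention of the
#' source analyses: the statistic is computed on `pre - post`, so a mean
#' increase yields a negative t (the study prints the CRF increase as
#' +82.30 pg/ml but its paired t as -2.52).
#'
#' @param pre,post equal-length numeric vectors, n >= 2.
#' @return a list of class `"paired_test_result"`: `t`, `df` (= n-1), `p`
#'   (two-sided), `mean_diff` (pre - post, measure units).
#' @export
paired_test <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  d <- pre - post
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(structure(list(t = 0, df = length(d) - 1L, p = 1, mean_diff = 0),
                       class = "paired_test_result"))
    }
    stop("zero variance of paired differences: t undefined")
  }
  ht <- stats::t.test(pre, post, paired = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = unname(ht$estimate)),
            class = "paired_test_result")
}

#' Paired t test from printed summary statistics
#'
#' @param mean_diff mean difference (in the pre-minus-post convention if the
#'   printed t is to be reproduced), measure units.
#' @param sd_diff SD of the paired differences, > 0.
#' @param n number of pairs, >= 2.
#' @return a `"paired_test_result"` with `t = mean_diff / (sd_diff /
#'   sqrt(n))`, `df = n - 1`, two-sided `p`.
#' @export
paired_test_from_summary <- function(mean_diff, sd_diff, n) {
  if (sd_diff <= 0) stop("sd_diff must be positive")
  if (n < 2) stop("n must be at least 2")
  t <- mean_diff / (sd_diff / sqrt(n))
  df <- n - 1
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 mean_diff = mean_diff),
            class = "paired_test_result")
}

#' Regression-to-the-mean diagnostics
#'
#' Regression to the mean would pull extreme baselines toward the mean on
#' remeasurement and shrink the follow-up variance. Two diagnostics are
#' returned: the Pitman-Morgan test of equality of correlated variances
#' (a t test on the correlation between per-dyad sums and differences, df
#' n-2), and a symmetric-inversion check - a paired comparison of the
#' absolute deviations from the respective means, |pre - mean(pre)| versus
#' |post - mean(post)|, which is null when individuals cross the mean to an
#' equal and opposite degree.
#'
#' @param pre,post equal-length numeric vectors, n >= 3.
#' @return a list of class `"rtm_result"`: `var_pre`, `var_post`,
#'   `pitman_morgan` (list `t`, `df`, `p`), and `symmetric_inversion`
#'   (a `"paired_test_result"` on the absolute deviations).
#' @export
rtm_diagnostics <- function(pre, post) {
  n <- length(pre)
  stopifnot(length(post) == n, n >= 3)
  if (stats::sd(pre) == 0 && stats::sd(post) == 0) {
    stop("degenerate variance: both series are constant")
  }
  s <- pre + post
  d <- pre - post
  if (stats::sd(d) == 0 || stats::sd(s) == 0) {
    pm <- list(t = 0, df = n - 2L, p = 1)
  } else {
    r_sd <- stats::cor(s, d)
    t <- r_sd * sqrt(n - 2) / sqrt(1 - r_sd^2)
    pm <- list(t = t, df = n - 2L, p = 2 * stats::pt(-abs(t), n - 2))
  }
  dev_pre <- abs(pre - mean(pre))
  dev_post <- abs(post - mean(post))
  si <- if (stats::sd(dev_pre - dev_post) == 0 && any(dev_pre != dev_post)) {
    stop("degenerate variance in symmetric-inversion comparison")
  } else {
    paired_test(dev_pre, dev_post)
  }
  structure(list(var_pre = stats::var(pre), var_post = stats::var(post),
                 pitman_morgan = pm, symmetric_inversion = si),
            class = "rtm_result")
}
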