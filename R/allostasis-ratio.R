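#' Group-versus-individual percent change ("allostasis ratio")
#'
#' For one biomarker, contrasts the magnitude of group-mean change with the
#' mean magnitude of individual change, both relative to baseline:
#' `group_pct = 100 * (mean(post) - mean(pre)) / mean(pre)` (ratio of
#' means) and `individual_pct = 100 * mean(|post_i - pre_i| / pre_i)`
#' (mean of per-dyad ratios). Their quotient `|group_pct| / individual_pct`
#' is low when individual changes are large yet mutually cancelling - the
#' signature of group-level homeostasis maintained through bidirectional
#' individual change.
#'
#' @param pre,post equal-length numeric vectors with positive baselines.
#' @param measure label, e.g. `"cortisol"` or `"crf"`.
#' @return a list of class `"ratio_result"`: `measure`, `group_pct`,
#'   `individual_pct` (both percentages), `ratio` (dimensionless, >= 0).
#' @export
ratio_determination <- function(pre, post, measure = "measure") {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  if (any(pre <= 0)) stop("all baseline values must be positive")
  group_pct <- 100 * (mean(post) - mean(pre)) / mean(pre)
  individual_pct <- 100 * mean(abs(post - pre) / pre)
  structure(list(measure = measure, group_pct = group_pct,
                 individual_pct = individual_pct,
                 ratio = if (individual_pct == 0) 0 else abs(group_pct) / individual_pct),
            class = "ratio_result")
}

.ratio_stat <- function(cort_pre, cort_post, crf_pre, crf_post) {
  r1 <- ratio_determination(cort_pre, cort_post, "cortisol")
  r2 <- ratio_determination(crf_pre, crf_post, "crf")
  r1$ratio - r2$ratio
}

#' Permutation contrast of the allostasis ratio between two measures
#'
#' Tests whether the group-versus-individual change ratio differs between
#' cortisol and CRF. The observed statistic is `ratio(cortisol) -
#' ratio(crf)`. Under the null that the two measures carry the same
#' group/individual change structure, the per-dyad (pre, post) pairs -
#' after each measure is standardized to unit baseline mean, so the swap is
#' scale-free - are exchangeable between the measure labels; the null
#' distribution is built by randomly swapping, per dyad, which measure's
#' pair is labelled cortisol. The two-sided p uses add-one smoothing,
#' `p = (1 + #(|stat*| >= |obs|)) / (n_permutations + 1)`.
#'
#' This permutation contrast is the package's principled inferential
#' replacement for entering the four percentages of the ratio table into a
#' Fisher exact test (see [fisher_2x2_literal()] for that paper-literal
#' mode).
#'
#' @param changes a `"change_scores"` object from [compute_changes()] (it
#'   carries the raw pre/post columns needed here).
#' @param n_permutations number of random swap patterns, at least 100.
#' @param seed integer seed for the swap draws.
#' @return a list of class `"measure_contrast_result"`: `table` (2x2 matrix
#'   of the four percentages, measures in columns), `observed` (the ratio
#'   difference), `method = "permutation"`, `p`, `n_permutations`, `seed`.
#' @export
contrast_measures_permutation <- function(changes, n_permutations = 9999L,
                                          seed = 1L) {
  stopifnot(inherits(changes, "change_scores"))
  if (n_permutations < 100) stop("n_permutations must be at least 100")
  n <- nrow(changes)
  ## scale-free standardized pairs (unit baseline mean per measure)
  a_pre <- changes$cortisol_pre / mean(changes$cortisol_pre)
  a_post <- changes$cortisol_post / mean(changes$cortisol_pre)
  b_pre <- changes$crf_pre / mean(changes$crf_pre)
  b_post <- changes$crf_post / mean(changes$crf_pre)
  observed <- .ratio_stat(a_pre, a_post, b_pre, b_post)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  null_stats <- vapply(seq_len(n_permutations), function(i) {
    swap <- stats::runif(n) < 0.5
    .ratio_stat(ifelse(swap, b_pre, a_pre), ifelse(swap, b_post, a_post),
                ifelse(swap, a_pre, b_pre), ifelse(swap, a_post, b_post))
  }, numeric(1))
  p <- (1 + sum(abs(null_stats) >= abs(observed))) / (n_permutations + 1)

  rc <- ratio_determination(changes$cortisol_pre, changes$cortisol_post, "cortisol")
  rf <- ratio_determination(changes$crf_pre, changes$crf_post, "crf")
  tab <- matrix(c(rc$group_pct, rc$individual_pct, rf$group_pct, rf$individual_pct),
                nrow = 2, dimnames = list(c("group_pct", "individual_pct"),
                                          c("cortisol", "crf")))
  structure(list(table = tab, observed = observed, method = "permutation",
                 p = p, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "measure_contrast_result")
}

#' Two-tailed Fisher exact probability of a 2x2 table by enumeration
#'
#' Full hypergeometric enumeration with fixed margins: the two-tailed p is
#' the sum of probabilities of all tables whose point probability does not
#' exceed that of the observed table (up to a relative tolerance of 1e-7).
#'
#' @param a,b,c,d nonnegative integer cell counts (row-wise).
#' @return the two-tailed probability.
#' @keywords internal
fisher_exact_2x2 <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0L, k - n2); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Paper-literal Fisher test on the ratio-table percentages
#'
#' Reproduction-only mode mirroring the source analysis, which entered the
#' four group/individual percentages into a 2x2 table and reported a Fisher
#' exact p. Percentages are taken in magnitude, rounded to the nearest
#' nonnegative integer, treated as counts, and tested by full
#' hypergeometric enumeration. Treating percentages as counts is not a
#' defined statistical procedure; the result is flagged accordingly and
#' [contrast_measures_permutation()] is the supported inference.
#'
#' @param table 2x2 numeric matrix of percentages (rows: group, individual;
#'   columns: the two measures).
#' @return a list of class `"measure_contrast_result"` with `method =
#'   "fisher_literal"`, the rounded count table, `p`, and a `note` flagging
#'   the procedure as statistically ill-defined.
#' @export
fisher_2x2_literal <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(!is.finite(table))) stop("all four entries must be finite")
  counts <- round(abs(table))
  if (any(counts < 0)) stop("negative entry after taking magnitudes")
  p <- fisher_exact_2x2(counts[1, 1], counts[1, 2], counts[2, 1], counts[2, 2])
  structure(list(table = counts, method = "fisher_literal", p = p,
                 n_permutations = NA_integer_, seed = NA_integer_,
                 note = "statistically ill-defined; for reproduction of the source table only"),
            class = "measure_contrast_result")
}
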