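# Small deterministic cohort fixtures built in code.

# plain data frame stripped of provenance/rownames for round-trip equality
plain <- function(cohort) {
  d <- as.data.frame(cohort)
  attr(d, "provenance") <- NULL
  rownames(d) <- NULL
  d
}

# n-dyad cohort with hand-set hormone values and benign covariates.
# cortisol/crf pre/post can be overridden; defaults are mildly varying.
make_cohort <- function(n = 6,
                        cortisol_pre = 40 + seq_len(n),
                        cortisol_post = 42 + seq_len(n) * 0.5,
                        crf_pre = 300 + 10 * seq_len(n),
                        crf_post = 380 + 12 * seq_len(n),
                        infant_sex = rep(c("M", "F"), length.out = n),
                        pen_id = rep("pen1", n),
                        social_rank = stats::ave(seq_len(n), pen_id,
                                                 FUN = seq_along)) {
  cohort_table(data.frame(
    dyad_id = sprintf("d%02d", seq_len(n)),
    pen_id = pen_id,
    exposure_cohort = rep(c("early", "late"), length.out = n),
    maternal_age = 6 + seq_len(n) * 0.4,
    maternal_weight = 4 + seq_len(n) * 0.2,
    social_rank = social_rank,
    infant_age_at_onset = 100 + 10 * seq_len(n),
    infant_weight = 1 + seq_len(n) * 0.05,
    infant_sex = infant_sex,
    dyadic_distance_hfd = 1.5 + (seq_len(n) %% 4),
    cortisol_pre = cortisol_pre,
    cortisol_post = cortisol_post,
    crf_pre = crf_pre,
    crf_post = crf_post,
    stringsAsFactors = FALSE
  ), provenance = "test fixture")
}

# change_scores object straight from raw pre/post vectors (bypasses cohort
# plumbing for statistic-level tests)
make_changes <- function(cort_pre, cort_post, crf_pre, crf_post) {
  zc <- function(x) (x - mean(x)) / stats::sd(x)
  structure(data.frame(
    dyad_id = sprintf("d%02d", seq_along(cort_pre)),
    cortisol_pre = cort_pre, cortisol_post = cort_post,
    crf_pre = crf_pre, crf_post = crf_post,
    delta_cortisol = cort_post - cort_pre,
    delta_crf = crf_post - crf_pre,
    pct_change_cortisol = (cort_post - cort_pre) / cort_pre,
    pct_change_crf = (crf_post - crf_pre) / crf_pre,
    z_delta_cortisol = zc(cort_post - cort_pre),
    z_delta_crf = zc(crf_post - crf_pre),
    stringsAsFactors = FALSE
  ), class = c("change_scores", "data.frame"))
}
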