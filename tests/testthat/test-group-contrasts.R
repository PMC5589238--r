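test_that("baseline-split interaction equals squared two-sample t on deltas", {
  set.seed(10)
  for (i in 1:5) {
    pre <- rnorm(24, 44, 7); post <- rnorm(24, 44, 6)
    res <- baseline_split_interaction(pre, post)
    tt <- t.test(I(post - pre) ~ I(pre > mean(pre)), var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
    expect_equal(res$df, c(1, 22))
    # partial eta squared identity for single-df effects
    expect_equal(res$partial_eta_sq, res$F / (res$F + res$df[2]), tolerance = 1e-10)
  }
})

test_that("baseline-split handles null and strong known effects", {
  # identical deltas across dyads: no interaction
  pre <- c(40, 41, 46, 47, 39, 48)
  res0 <- baseline_split_interaction(pre, pre + 2)
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)

  # delta shifted by 5 SD between baseline groups, n = 40
  set.seed(11)
  pre <- c(rnorm(20, 38, 1), rnorm(20, 50, 1))
  delta <- rnorm(40, 0, 1) + ifelse(pre > mean(pre), -5, 0)
  res1 <- baseline_split_interaction(pre, pre + delta)
  expect_lt(res1$p, 1e-6)
  expect_gt(res1$partial_eta_sq, 0.8)
  # high-baseline group decreases, low increases: inversion cells
  cells <- res1$cells
  hi <- cells[cells$group == "high", ]; lo <- cells[cells$group == "low", ]
  expect_lt(hi$mean[hi$time == "post"], hi$mean[hi$time == "pre"])
  expect_posthoc <- res1$posthoc
  expect_true(any(expect_posthoc$significant))

  # covariate variant uses df (1, n-3)
  covar <- rnorm(40)
  expect_equal(baseline_split_interaction(pre, pre + delta, covar)$df, c(1, 37))

  expect_error(baseline_split_interaction(c(1, 2, 10), c(1, 2, 10)), "n >= 4")
  expect_error(baseline_split_interaction(c(1, 1, 1, 10), c(1, 1, 1, 10)),
               "at least 2 dyads")
})

test_that("Newman-Keuls flags a superset of Bonferroni-significant pairs", {
  set.seed(12)
  for (i in 1:20) {
    k <- 4; n_cell <- 8
    mus <- rnorm(k, 0, 1.2)
    x <- lapply(mus, function(m) rnorm(n_cell, m, 1))
    means <- vapply(x, mean, numeric(1)); names(means) <- paste0("c", 1:k)
    mse <- mean(vapply(x, var, numeric(1)))
    dfe <- k * (n_cell - 1)
    nk <- newman_keuls(means, n_cell, mse, dfe)
    pairs <- utils::combn(k, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      tstat <- abs(means[a] - means[b]) / sqrt(2 * mse / n_cell)
      p_bonf <- min(1, 2 * pt(-tstat, dfe) * ncol(pairs))
      if (p_bonf <= 0.05) {
        row <- nk[(nk$cell_low %in% paste0("c", c(a, b))) &
                    (nk$cell_high %in% paste0("c", c(a, b))), ]
        expect_true(row$significant,
                    label = sprintf("NK covers Bonferroni pair %d-%d (rep %d)", a, b, i))
      }
    }
  }
})

test_that("measure x condition interaction reduces to the paired t", {
  set.seed(13)
  pre_c <- rnorm(22, 44, 7); post_c <- rnorm(22, 44, 6)
  pre_f <- rnorm(22, 340, 117); post_f <- rnorm(22, 422, 134)
  ch <- make_changes(pre_c, post_c, pre_f, post_f)
  res <- measure_condition_anova(ch)
  tt <- t.test(0.1 * ch$delta_crf - ch$delta_cortisol)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$df, c(1, 21))

  # perfectly matched scaled changes: no interaction
  ch0 <- make_changes(pre_c, post_c, pre_f, pre_f + 10 * (post_c - pre_c))
  expect_equal(measure_condition_anova(ch0)$F, 0)
})

test_that("measure x condition F sits in the study regime on synthetic cohorts", {
  fs <- vapply(1:100, function(s) {
    sim <- generate_cohort(synthetic_config(), seed = 2000 + s)
    r <- measure_condition_anova(compute_changes(sim$cohort))
    c(r$F, r$p)
  }, numeric(2))
  # band frozen from a 300-seed pilot (median F 4.3; the study regime is F ~ 4.7)
  expect_gt(median(fs[1, ]), 2.5)
  expect_lt(median(fs[1, ]), 8)
  expect_gte(mean(fs[2, ] < 0.05), 0.4)
})

test_that("predictor contrasts recover nulls, identities and the weight effect", {
  set.seed(14)
  n <- 10000
  pre_c <- rnorm(n, 44, 7); post_c <- rnorm(n, 44, 6)
  pre_f <- rnorm(n, 340, 117); post_f <- rnorm(n, 422, 134)
  ch <- make_changes(pre_c, post_c, pre_f, post_f)
  null_pred <- rnorm(n)
  pc <- predictor_contrast(null_pred, ch, name = "noise")
  expect_lt(abs(pc$r_cort), 0.05)
  expect_lt(abs(pc$r_crf), 0.05)

  pc2 <- predictor_contrast(ch$z_delta_cortisol, ch)
  expect_equal(pc2$r_cort, 1, tolerance = 1e-12)

  expect_error(predictor_contrast(rep(1, n), ch), "zero-variance")

  # maternal weight associates with the cortisol change, not the CRF change
  hits <- vapply(1:20, function(s) {
    sim <- generate_cohort(synthetic_config(n_dyads = 200), seed = 3000 + s)
    chs <- compute_changes(sim$cohort)
    r <- predictor_contrast(sim$cohort$maternal_weight, chs, "maternal_weight")
    r$r_cort > 0 && r$interaction_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("cross-sectional exposure-by-weight analysis detects slope inversion", {
  # power under opposite +-1 SD slopes, n = 11 per group (rate frozen by pilot: 0.96)
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 11
    w_e <- rnorm(n, 4.9, 1); w_u <- rnorm(n, 4.9, 1)
    co <- make_cohort(2 * n)
    df <- as.data.frame(co)
    df$exposure_cohort <- rep(c("early", "late"), each = n)
    df$maternal_weight <- c(w_e, w_u)
    df$cortisol_post[df$exposure_cohort == "early"] <-
      44 + scale(w_e)[, 1] * 5 + rnorm(n, 0, 5)
    df$cortisol_pre[df$exposure_cohort == "late"] <-
      44 - scale(w_u)[, 1] * 5 + rnorm(n, 0, 5)
    df$infant_age_at_onset <- rnorm(2 * n, 158, 30)
    res <- cross_sectional_analysis(cohort_table(df))
    res$interaction_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # degenerate constant response errors out
  co <- make_cohort(8)
  df <- as.data.frame(co)
  df$cortisol_pre <- 44; df$cortisol_post <- 44
  expect_error(cross_sectional_analysis(cohort_table(df)), "degenerate")

  small <- make_cohort(4)
  expect_error(cross_sectional_analysis(small), "at least 3")
})

test_that("dominance coding reverses rank within pens", {
  co <- make_cohort(6, pen_id = rep(c("pen1", "pen2"), each = 3))
  expect_equal(dominance_score(co), c(3, 2, 1, 3, 2, 1))
})
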