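test_that("duplicated variables merge first at height zero", {
  set.seed(21)
  df <- as.data.frame(make_cohort(20,
    cortisol_pre = 40 + rnorm(20), cortisol_post = 44 + rnorm(20)))
  df$maternal_weight <- rnorm(20, 5, 1)
  df$dup_weight <- df$maternal_weight
  co <- cohort_table(df)
  tree <- cluster_variables(co, c("maternal_weight", "dup_weight", "infant_weight"))
  expect_equal(tree$height[1], 0, tolerance = 1e-12)
  expect_setequal(tree$labels[-tree$merge[1, ]], c("maternal_weight", "dup_weight"))
})

test_that("clustering agrees with a brute-force agglomeration oracle", {
  set.seed(22)
  n <- 60
  base <- rnorm(n)
  df <- as.data.frame(make_cohort(n, cortisol_pre = 40 + rnorm(n),
                                  cortisol_post = 44 + rnorm(n)))
  df$maternal_weight <- 5 + 0.9 * scale(base)[, 1] + 0.4 * rnorm(n)
  df$infant_weight <- 1.2 + 0.9 * scale(base)[, 1] * 0.3 + 0.12 * rnorm(n)
  df$maternal_age <- 8 + 3 * rnorm(n)
  co <- cohort_table(df)
  cand <- c("maternal_weight", "infant_weight", "maternal_age")
  tree <- cluster_variables(co, cand)

  # the strongly correlated pair merges first
  expect_setequal(tree$labels[-tree$merge[1, ]],
                  c("maternal_weight", "infant_weight"))

  # brute-force complete-linkage agglomeration on the same distances
  m <- scale(sapply(cand, function(v) as.numeric(df[[v]])))
  d <- as.matrix(dist(t(m))) / sqrt(n - 1)
  clusters <- as.list(cand)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  expect_equal(tree$height, heights, tolerance = 1e-12)

  # heights are non-decreasing along the agglomeration
  expect_true(all(diff(tree$height) >= -1e-12))

  df$maternal_age <- 8  # zero variance under standardization
  expect_error(cluster_variables(cohort_table(df), cand), "zero-variance")
})

test_that("core selection is anchored, outcome-free, monotone and cutoff-sensitive", {
  sim <- generate_cohort(synthetic_config(n_dyads = 200), seed = 23)
  tree <- cluster_variables(sim$cohort)

  expect_error(select_core(tree, anchor = "nonexistent"), "anchor")
  expect_error(select_core(tree, cutoff = 0), "positive")

  # below all merge heights only the anchor's singleton remains: empty core
  expect_length(select_core(tree, cutoff = min(tree$height) / 2), 0)

  # above all merge heights: every non-outcome candidate
  all_core <- select_core(tree, cutoff = max(tree$height) * 2)
  expect_setequal(all_core, c("maternal_weight", "dominance", "infant_weight",
                              "dyadic_distance_hfd", "infant_age_at_onset"))

  # monotone: core at a smaller cutoff is a subset of core at a larger one
  cuts <- seq(0.5, 2.2, by = 0.1)
  cores <- lapply(cuts, function(h) select_core(tree, cutoff = h))
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(cores[[i - 1]] %in% cores[[i]]))
  }
})

test_that("index equals the hand-computed oriented z-score sum", {
  df <- as.data.frame(make_cohort(4))
  df$maternal_weight <- c(4, 5, 6, 7)
  df$infant_weight <- c(1.0, 1.2, 1.1, 1.5)
  co <- cohort_table(df)
  res <- build_index(co, c("maternal_weight", "infant_weight"),
                     orientations = c(maternal_weight = -1, infant_weight = -1))
  zw <- scale(c(4, 5, 6, 7))[, 1]
  zi <- scale(c(1.0, 1.2, 1.1, 1.5))[, 1]
  expect_equal(unname(res$index), -zw - zi, tolerance = 1e-12)
  expect_equal(mean(res$index), 0, tolerance = 1e-12)
  expect_equal(unname(abs(res$orientations)), c(1, 1))

  expect_error(build_index(co, character(0)), "empty")
  expect_error(build_index(co, "maternal_weight",
                           orientations = c(infant_weight = -1)),
               "orientation missing")
  expect_error(build_index(co, "maternal_weight",
                           orientations = c(maternal_weight = -0.5)),
               "\\+1 or -1")
})

test_that("index is invariant to affine rescaling of core variables", {
  sim <- generate_cohort(synthetic_config(n_dyads = 50), seed = 24)
  core <- c("maternal_weight", "infant_weight", "dyadic_distance_hfd")
  r1 <- build_index(sim$cohort, core)
  df <- as.data.frame(sim$cohort)
  df$maternal_weight <- df$maternal_weight * 1000  # kg -> g
  r2 <- build_index(cohort_table(df), core)
  expect_equal(r1$index, r2$index, tolerance = 1e-9)
  expect_equal(r1$association$F, r2$association$F, tolerance = 1e-9)
})

test_that("association model matches a reference least-squares fit", {
  sim <- generate_cohort(synthetic_config(n_dyads = 100), seed = 25)
  core <- c("maternal_weight", "dominance", "infant_weight", "dyadic_distance_hfd")
  res <- build_index(sim$cohort, core)
  co <- sim$cohort
  delta <- co$cortisol_post - co$cortisol_pre
  fit <- lm(delta ~ res$index + factor(co$infant_sex, c("M", "F")))
  tv <- summary(fit)$coefficients[2, "t value"]
  expect_equal(res$association$F, tv^2, tolerance = 1e-10)
  expect_equal(res$association$df, c(1, 97))
  expect_equal(res$association$partial_eta_sq,
               tv^2 / (tv^2 + 97), tolerance = 1e-10)
  expect_lt(res$r_index_delta, 0)   # vulnerability predicts cortisol decreases
  fit_pre <- lm(co$cortisol_pre ~ res$index + factor(co$infant_sex, c("M", "F")))
  expect_equal(res$adj_r2_pre_cortisol, summary(fit_pre)$adj.r.squared,
               tolerance = 1e-10)
})

test_that("association p is calibrated when core variables are pure noise", {
  ps <- vapply(1:200, function(s) {
    cfg <- synthetic_config(n_dyads = 30, lambda_weight = 0, lambda_rank = 0,
                            lambda_infantweight = 0, lambda_proximity = 0,
                            lambda_precortisol = 0)
    sim <- generate_cohort(cfg, seed = 5000 + s)
    build_index(sim$cohort, c("maternal_weight", "infant_weight",
                              "dyadic_distance_hfd"))$association$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})
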