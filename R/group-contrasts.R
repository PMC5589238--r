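#' Newman-Keuls stepwise studentized-range procedure
#'
#' Orders the cell means and tests each pairwise range with the studentized
#' range distribution at the number of means it spans; a range is declared
#' significant only if every enclosing range is. Uses a common error
#' variance and the harmonic mean of the two cell sizes.
#'
#' @param means numeric vector of cell means (named, ideally).
#' @param n_per_cell cell sizes (recycled if scalar).
#' @param mse pooled error variance.
#' @param df_error error degrees of freedom.
#' @param alpha significance level for the stepwise flags (default 0.05).
#' @return data frame with one row per pair: the two cells, the span `k`,
#'   studentized range `q`, `p` from [stats::ptukey()], and `significant`.
#' @export
newman_keuls <- function(means, n_per_cell, mse, df_error, alpha = 0.05) {
  k_total <- length(means)
  stopifnot(k_total >= 2, mse >= 0, df_error >= 1)
  n_per_cell <- rep_len(n_per_cell, k_total)
  if (is.null(names(means))) names(means) <- paste0("cell", seq_len(k_total))
  ord <- order(means)
  m <- means[ord]; nn <- n_per_cell[ord]
  pairs <- list()
  sig <- matrix(NA, k_total, k_total)
  ## visit ranges from widest span downward so enclosing results are known
  for (span in k_total:2) {
    for (i in 1:(k_total - span + 1)) {
      j <- i + span - 1
      n_h <- 2 / (1 / nn[i] + 1 / nn[j])
      se <- sqrt(mse / n_h)
      q <- if (se == 0) 0 else (m[j] - m[i]) / se
      p <- if (se == 0) 1 else stats::ptukey(q, span, df_error, lower.tail = FALSE)
      enclosing_ok <- TRUE
      if (span < k_total) {
        ## all previously-tested ranges containing (i, j) must be significant
        for (ii in 1:i) for (jj in j:k_total) {
          if ((jj - ii + 1) > span && isFALSE(sig[ii, jj])) enclosing_ok <- FALSE
        }
      }
      s <- enclosing_ok && p <= alpha
      sig[i, j] <- s
      pairs[[length(pairs) + 1]] <- data.frame(
        cell_low = names(m)[i], cell_high = names(m)[j], k = span,
        q = q, p = p, significant = s, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, pairs)
}

#' Baseline-split inversion analysis
#'
#' Codes dyads by baseline above versus below the cohort mean of `pre` and
#' tests the group x time interaction of the pre/post repeated measure. For
#' this two-group pre/post design the interaction F equals the squared t of
#' the two-sample comparison of the change scores between groups; with a
#' covariate it is the F of the group term in the least-squares model of
#' the change score on group plus covariate. Partial eta squared is
#' `SS_group / (SS_group + SS_error)`. Newman-Keuls post hoc testing is run
#' on the four group x time cell means using the pooled within-cell
#' variance (an approximation to the mixed-design error structure).
#'
#' @param pre,post equal-length numeric vectors, n >= 4, both baseline
#'   groups nonempty with at least 2 members.
#' @param covariate optional numeric covariate entered as a linear term.
#' @return a list of class `"split_interaction_result"`: `cells` (data
#'   frame of group x time means, SEs, n), `F`, `df` (c(1, n-2) or
#'   c(1, n-3) with covariate), `p`, `partial_eta_sq`, `group` (the
#'   per-dyad high/low coding), `posthoc` (the [newman_keuls()] table).
#' @export
baseline_split_interaction <- function(pre, post, covariate = NULL) {
  n <- length(pre)
  stopifnot(length(post) == n, n >= 4)
  grp <- factor(ifelse(pre > mean(pre), "high", "low"), levels = c("low", "high"))
  if (any(table(grp) < 2)) stop("each baseline group must contain at least 2 dyads")
  delta <- post - pre

  if (is.null(covariate)) {
    fit <- stats::lm(delta ~ grp)
  } else {
    stopifnot(length(covariate) == n)
    fit <- stats::lm(delta ~ grp + covariate)
  }
  av <- suppressWarnings(stats::anova(fit))  # perfect fits warn; handled below
  ss_grp <- av["grp", "Sum Sq"]
  ss_err <- av["Residuals", "Sum Sq"]
  df_err <- av["Residuals", "Df"]
  eps <- 1e-12 * (sum(delta^2) + 1)  # guards the constant-delta case
  if (ss_err <= eps) {
    F <- if (ss_grp <= eps) 0 else Inf
    p <- if (ss_grp <= eps) 1 else 0
  } else {
    F <- (ss_grp / av["grp", "Df"]) / (ss_err / df_err)
    p <- stats::pf(F, 1, df_err, lower.tail = FALSE)
  }
  pes <- if (ss_grp <= eps && ss_err <= eps) 0 else ss_grp / (ss_grp + ss_err)

  cells <- do.call(rbind, lapply(levels(grp), function(g) {
    idx <- grp == g
    data.frame(group = g, time = c("pre", "post"),
               mean = c(mean(pre[idx]), mean(post[idx])),
               se = c(stats::sd(pre[idx]), stats::sd(post[idx])) / sqrt(sum(idx)),
               n = sum(idx), stringsAsFactors = FALSE)
  }))
  cell_means <- stats::setNames(cells$mean, paste(cells$group, cells$time, sep = "_"))
  within <- unlist(lapply(levels(grp), function(g) {
    idx <- grp == g
    c(pre[idx] - mean(pre[idx]), post[idx] - mean(post[idx]))
  }))
  df_cells <- 2 * (table(grp)[1] - 1) + 2 * (table(grp)[2] - 1)
  mse <- sum(within^2) / df_cells
  posthoc <- newman_keuls(cell_means, rep(as.vector(table(grp)), each = 2),
                          mse, as.numeric(df_cells))

  structure(list(cells = cells, F = F, df = c(1, df_err), p = p,
                 partial_eta_sq = pes, group = grp, posthoc = posthoc),
            class = "split_interaction_result")
}

#' Measure x condition repeated-measures interaction
#'
#' Contrasts the pre-to-post change of the two biomarkers in one
#' repeated-measures design, with CRF rescaled into the cortisol range
#' (division by 10 by default). For two within-subject measures the
#' interaction reduces to the paired test of the per-dyad difference of
#' (scaled) change scores, `scale_crf * delta_crf - delta_cortisol`;
#' F = t^2 with df (1, n-1).
#'
#' @param changes a `"change_scores"` object.
#' @param scale_crf scale factor applied to CRF (default 0.1).
#' @return list of class `"measure_condition_result"`: `F`, `df`, `p`,
#'   and the underlying paired `t`.
#' @export
measure_condition_anova <- function(changes, scale_crf = 0.1) {
  stopifnot(inherits(changes, "change_scores"))
  n <- nrow(changes)
  if (n < 2) stop("need at least 2 dyads")
  d <- scale_crf * changes$delta_crf - changes$delta_cortisol
  tol <- 1e-10 * max(stats::sd(changes$delta_cortisol),
                     abs(scale_crf) * stats::sd(changes$delta_crf), 1)
  if (stats::sd(d) <= tol) {
    t <- 0; p <- 1
  } else {
    t <- mean(d) / (stats::sd(d) / sqrt(n))
    p <- 2 * stats::pt(-abs(t), n - 1)
  }
  structure(list(F = t^2, df = c(1, n - 1), p = p, t = t,
                 scale_crf = scale_crf),
            class = "measure_condition_result")
}

#' Predictor contrast against the two standardized change scores
#'
#' Correlates one predictor with the standardized cortisol and CRF change
#' scores and tests whether the two associations differ (the repeated
#' measures x predictor interaction): the least-squares regression of
#' `z_delta_cortisol - z_delta_crf` on the standardized predictor, with
#' F equal to the squared t of the slope, df (1, n-2).
#'
#' @param predictor numeric vector, complete for all dyads.
#' @param changes a `"change_scores"` object of matching length.
#' @param name predictor label carried into the result.
#' @return list of class `"predictor_contrast"`: `predictor`, `r_cort`,
#'   `p_cort`, `r_crf`, `p_crf`, `interaction_F`, `interaction_df`,
#'   `interaction_p`.
#' @export
predictor_contrast <- function(predictor, changes, name = deparse(substitute(predictor))) {
  stopifnot(inherits(changes, "change_scores"))
  n <- nrow(changes)
  stopifnot(length(predictor) == n)
  if (anyNA(predictor)) stop("predictor must be complete for all dyads")
  if (stats::sd(predictor) == 0) stop("zero-variance predictor")
  ct1 <- stats::cor.test(predictor, changes$z_delta_cortisol)
  ct2 <- stats::cor.test(predictor, changes$z_delta_crf)
  diff <- changes$z_delta_cortisol - changes$z_delta_crf
  zp <- (predictor - mean(predictor)) / stats::sd(predictor)
  fit <- summary(stats::lm(diff ~ zp))
  tval <- fit$coefficients["zp", "t value"]
  structure(list(predictor = name,
                 r_cort = unname(ct1$estimate), p_cort = ct1$p.value,
                 r_crf = unname(ct2$estimate), p_crf = ct2$p.value,
                 interaction_F = tval^2, interaction_df = c(1, n - 2),
                 interaction_p = fit$coefficients["zp", "Pr(>|t|)"]),
            class = "predictor_contrast")
}

#' Cross-sectional exposure-by-weight analysis
#'
#' Uses the staggered design to contrast exposed with not-yet-exposed
#' mothers at one calendar window: the response is post-stressor cortisol
#' for the early cohort and baseline cortisol for the late cohort. Fits the
#' least-squares model `response ~ exposure * maternal_weight +
#' infant_age_at_onset` and reports the exposure main effect, the exposure
#' x weight interaction (F = squared t of the interaction coefficient), and
#' the within-group Pearson correlations of weight with the response.
#'
#' @param cohort a [cohort_table()] with both exposure cohorts present
#'   (>= 3 dyads each) and the needed cortisol value present in each row.
#' @return list of class `"cross_section_result"`: `group_F`, `group_df`,
#'   `group_p`, `interaction_F`, `interaction_df`, `interaction_p`,
#'   `r_by_group` (data frame: group, n, r, p), `covariates`.
#' @export
cross_sectional_analysis <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  early <- cohort[cohort$exposure_cohort == "early", , drop = FALSE]
  late <- cohort[cohort$exposure_cohort == "late", , drop = FALSE]
  if (nrow(early) < 3 || nrow(late) < 3) {
    stop("each exposure cohort must contain at least 3 dyads")
  }
  df <- data.frame(
    response = c(early$cortisol_post, late$cortisol_pre),
    exposure = factor(c(rep("exposed", nrow(early)), rep("unexposed", nrow(late))),
                      levels = c("unexposed", "exposed")),
    weight = c(early$maternal_weight, late$maternal_weight),
    infant_age = c(early$infant_age_at_onset, late$infant_age_at_onset)
  )
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (stats::sd(df$response) == 0) stop("degenerate response: constant cortisol")
  fit <- stats::lm(response ~ exposure * weight + infant_age, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  df_err <- fit$df.residual
  t_int <- co["exposureexposed:weight", "t value"]
  t_grp <- co["exposureexposed", "t value"]
  r_by_group <- do.call(rbind, lapply(levels(df$exposure), function(g) {
    idx <- df$exposure == g
    ct <- stats::cor.test(df$weight[idx], df$response[idx])
    data.frame(group = g, n = sum(idx), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  }))
  structure(list(group_F = t_grp^2, group_df = c(1, df_err),
                 group_p = co["exposureexposed", "Pr(>|t|)"],
                 interaction_F = t_int^2, interaction_df = c(1, df_err),
                 interaction_p = co["exposureexposed:weight", "Pr(>|t|)"],
                 r_by_group = r_by_group,
                 covariates = "infant_age_at_onset"),
            class = "cross_section_result")
}

#' Dominance coding of within-pen social rank
#'
#' Recodes rank (1 = most dominant) as `pen size + 1 - rank`, so that
#' larger values mean more dominant and reported association directions
#' match the narrative convention. The raw-rank alternative is simply the
#' `social_rank` column itself.
#'
#' @param cohort a [cohort_table()].
#' @return numeric vector of dominance scores aligned with `cohort`.
#' @export
dominance_score <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  pen_size <- stats::ave(rep(1, nrow(cohort)), cohort$pen_id, FUN = sum)
  pen_size + 1 - cohort$social_rank
}
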