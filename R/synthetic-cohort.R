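#' Configuration for the synthetic dyad-cohort generator
#'
#' Defaults reproduce the printed marginals of the motivating cohort of 22
#' bonnet macaque mother-infant dyads: plasma cortisol 44.12 (7.09) pre and
#' 44.36 (5.61) ug/dl post with pre/post correlation -0.24; CSF CRF 339.83
#' (117.40) pre and 422.13 (134.08) pg/ml post with correlation 0.26;
#' maternal weight 4.94 (0.95) kg; maternal age 8.5 (3.0) years; infant
#' weight 1.16 (0.32) kg; infant age at stressor onset 158 (52) days.
#'
#' A single latent "dyadic vulnerability" factor v ~ N(0,1) loads on
#' maternal weight (negatively: vulnerable mothers are lighter), within-pen
#' social rank (vulnerable mothers are subordinate), infant weight
#' (negatively), dyadic proximity (vulnerable dyads are closer, i.e. lower
#' distance score) and baseline cortisol (positively). The post value of
#' each biomarker is generated jointly with its pre value to achieve the
#' configured marginals and pre/post correlation exactly in population;
#' the strong negative baseline-delta coupling then follows automatically
#' from the change-score identity rather than from a separate equation.
#'
#' @param n_dyads number of dyads (default 22, the analysed cohort size).
#' @param pen_sizes integer vector of pen sizes summing to `n_dyads`
#'   (default: dyads spread over four pens of 4-7).
#' @param seed integer seed used by [generate_cohort()] unless overridden.
#' @param cortisol_pre_mean,cortisol_pre_sd,cortisol_post_mean,cortisol_post_sd
#'   plasma cortisol marginals, ug/dl.
#' @param r_prepost_cortisol pre/post cortisol correlation.
#' @param crf_pre_mean,crf_pre_sd,crf_post_mean,crf_post_sd CSF CRF
#'   marginals, pg/ml.
#' @param r_prepost_crf pre/post CRF correlation.
#' @param maternal_weight_mean,maternal_weight_sd kg.
#' @param maternal_age_mean,maternal_age_sd years.
#' @param infant_weight_mean,infant_weight_sd kg.
#' @param onset_mean,onset_sd infant age at stressor onset, days.
#' @param onset_late_offset mean extra age (days) of late-cohort infants at
#'   onset, matching the staggered design (default 79).
#' @param distance_mean,distance_sd dyadic-distance score marginals on the
#'   1-5 scale (the study prints no distribution; a mid-scale continuous
#'   aggregate is assumed).
#' @param lambda_weight,lambda_rank,lambda_infantweight,lambda_proximity,lambda_precortisol
#'   loadings (in `[0, 1]`, applied with the signs above) of the latent
#'   vulnerability factor on each observable.
#' @param sex_effect_crf standardized shift (in units of SD of the CRF
#'   change score) added to the CRF change of mothers of female infants;
#'   folded into the joint pre/post draw so marginals are preserved.
#' @param early_fraction share of dyads assigned to the early exposure
#'   cohort (default 12/22).
#' @param floor small positive floor applied to weights (kg).
#' @param cortisol_floor,crf_floor assay detection floors for the hormone
#'   values (defaults 1 ug/dl and 20 pg/ml, the CRF assay's stated
#'   sensitivity); draws below the floor are censored at it, as a
#'   radioimmunoassay would report them. Percent-change statistics are only
#'   meaningful for detectable baselines, so the floors are part of the
#'   generator's measurement model, not an analysis tuning knob.
#'
#' @return a validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_dyads = 22L,
                             pen_sizes = NULL,
                             seed = 1L,
                             cortisol_pre_mean = 44.12, cortisol_pre_sd = 7.09,
                             cortisol_post_mean = 44.36, cortisol_post_sd = 5.61,
                             r_prepost_cortisol = -0.24,
                             crf_pre_mean = 339.83, crf_pre_sd = 117.40,
                             crf_post_mean = 422.13, crf_post_sd = 134.08,
                             r_prepost_crf = 0.26,
                             maternal_weight_mean = 4.94, maternal_weight_sd = 0.95,
                             maternal_age_mean = 8.5, maternal_age_sd = 3.0,
                             infant_weight_mean = 1.16, infant_weight_sd = 0.32,
                             onset_mean = 158, onset_sd = 52,
                             onset_late_offset = 79,
                             distance_mean = 3.0, distance_sd = 0.8,
                             lambda_weight = 0.75, lambda_rank = 0.75,
                             lambda_infantweight = 0.70, lambda_proximity = 0.70,
                             lambda_precortisol = 0.80,
                             sex_effect_crf = 0.85,
                             early_fraction = 12 / 22,
                             floor = 0.01,
                             cortisol_floor = 1, crf_floor = 20) {
  cfg <- as.list(environment())
  cfg$n_dyads <- as.integer(n_dyads)
  if (is.null(pen_sizes)) cfg$pen_sizes <- .default_pen_sizes(cfg$n_dyads)
  cfg$pen_sizes <- as.integer(cfg$pen_sizes)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

.default_pen_sizes <- function(n) {
  if (n <= 7) return(n)
  n_pens <- max(1L, ceiling(n / 6))
  base <- n %/% n_pens
  sizes <- rep(base, n_pens)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' @keywords internal
validate_synthetic_config <- function(cfg) {
  sds <- c("cortisol_pre_sd", "cortisol_post_sd", "crf_pre_sd", "crf_post_sd",
           "maternal_weight_sd", "maternal_age_sd", "infant_weight_sd",
           "onset_sd", "distance_sd")
  for (nm in sds) if (cfg[[nm]] <= 0) stop("configuration error: ", nm, " must be > 0")
  for (nm in c("r_prepost_cortisol", "r_prepost_crf")) {
    if (abs(cfg[[nm]]) >= 1) stop("configuration error: ", nm, " must lie in (-1, 1)")
  }
  lambdas <- c("lambda_weight", "lambda_rank", "lambda_infantweight",
               "lambda_proximity", "lambda_precortisol")
  for (nm in lambdas) {
    if (cfg[[nm]] < -1 || cfg[[nm]] > 1) stop("configuration error: ", nm, " must lie in [-1, 1]")
  }
  if (cfg$early_fraction < 0 || cfg$early_fraction > 1) {
    stop("configuration error: early_fraction must lie in [0, 1]")
  }
  if (sum(cfg$pen_sizes) != cfg$n_dyads) {
    stop("configuration error: pen_sizes must sum to n_dyads")
  }
  ## feasibility of the CRF post decomposition: r^2 + b_sex^2 must not exceed 1
  b <- .crf_sex_coef(cfg)
  if (cfg$r_prepost_crf^2 + b^2 >= 1) {
    stop("configuration error: sex_effect_crf too large for r_prepost_crf ",
         "(implied residual variance < 0)")
  }
  invisible(TRUE)
}

## coefficient on the centred standardized sex contrast inside crf_post,
## chosen so the female-vs-male shift of the CRF change score equals
## sex_effect_crf * SD(delta CRF) while leaving the crf_post marginal intact
.crf_sex_coef <- function(cfg) {
  sd_delta <- sqrt(cfg$crf_pre_sd^2 + cfg$crf_post_sd^2 -
                     2 * cfg$r_prepost_crf * cfg$crf_pre_sd * cfg$crf_post_sd)
  p <- 0.5  # infant sex is Bernoulli(1/2)
  cfg$sex_effect_crf * sd_delta * sqrt(p * (1 - p)) / cfg$crf_post_sd
}

#' Generate a synthetic dyad cohort with hidden vulnerability truth
#'
#' Draws a cohort from the latent-factor generative model described in
#' [synthetic_config()]. The per-dyad latent vulnerability `v` is returned
#' separately for parameter-recovery studies and is never written into the
#' cohort table.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; defaults to `config$seed`. Fixed seed gives a
#'   bit-identical cohort.
#' @return a list of class `"synthetic_cohort"` with elements `cohort`
#'   (a [cohort_table()]) and `truth` (data frame `dyad_id`, `v`).
#' @export
generate_cohort <- function(config = synthetic_config(), seed = config$seed) {
  validate_synthetic_config(config)
  n <- config$n_dyads
  if (n < 2) stop("configuration error: n_dyads must be >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  v <- stats::rnorm(n)

  load_obs <- function(lambda, sign) {
    lambda <- abs(lambda)
    sign * lambda * v + sqrt(1 - lambda^2) * stats::rnorm(n)
  }
  ## unit-variance standardized observables
  x_mw  <- load_obs(config$lambda_weight, -1)        # lighter mother <- high v
  x_iw  <- load_obs(config$lambda_infantweight, -1)  # lighter infant <- high v
  x_dd  <- load_obs(config$lambda_proximity, -1)     # closer dyad (low distance) <- high v
  x_cp  <- load_obs(config$lambda_precortisol, +1)   # higher baseline cortisol <- high v

  maternal_weight <- config$maternal_weight_mean + config$maternal_weight_sd * x_mw
  infant_weight <- config$infant_weight_mean + config$infant_weight_sd * x_iw
  dyadic_distance <- config$distance_mean + config$distance_sd * x_dd
  cortisol_pre <- config$cortisol_pre_mean + config$cortisol_pre_sd * x_cp

  r <- config$r_prepost_cortisol
  cortisol_post <- config$cortisol_post_mean + config$cortisol_post_sd *
    (r * x_cp + sqrt(1 - r^2) * stats::rnorm(n))

  infant_sex <- sample(c("M", "F"), n, replace = TRUE)
  ## unit-variance centred contrast (I(F) - p)/sqrt(pq) at p = 1/2: +1 F, -1 M
  sex_contrast <- (as.numeric(infant_sex == "F") - 0.5) * 2

  rc <- config$r_prepost_crf
  b <- .crf_sex_coef(config)
  x_crf_pre <- stats::rnorm(n)
  crf_pre <- config$crf_pre_mean + config$crf_pre_sd * x_crf_pre
  crf_post <- config$crf_post_mean + config$crf_post_sd *
    (rc * x_crf_pre + b * sex_contrast + sqrt(1 - rc^2 - b^2) * stats::rnorm(n))

  ## pens and within-pen rank from the noisy latent order (rank 1 = lowest v)
  pen_id <- rep(sprintf("pen%d", seq_along(config$pen_sizes)), config$pen_sizes)
  lr <- abs(config$lambda_rank)
  rank_score <- lr * v + sqrt(1 - lr^2) * stats::rnorm(n)
  social_rank <- integer(n)
  for (idx in split(seq_len(n), pen_id)) {
    social_rank[idx] <- rank(rank_score[idx], ties.method = "first")
  }

  ## staggered exposure cohorts; late infants older at onset by the offset
  n_early <- round(config$early_fraction * n)
  exposure <- rep("late", n)
  exposure[sample.int(n, n_early)] <- "early"
  p_late <- 1 - n_early / n
  off <- config$onset_late_offset
  var_within <- config$onset_sd^2 - p_late * (1 - p_late) * off^2
  if (var_within <= 0) {
    stop("configuration error: onset_late_offset too large for onset_sd")
  }
  onset <- config$onset_mean - p_late * off + sqrt(var_within) * stats::rnorm(n) +
    off * (exposure == "late")

  clip <- function(x, lo = config$floor) pmax(x, lo)
  cohort <- cohort_table(data.frame(
    dyad_id = sprintf("dyad%03d", seq_len(n)),
    pen_id = pen_id,
    exposure_cohort = exposure,
    maternal_age = config$maternal_age_mean + config$maternal_age_sd * stats::rnorm(n),
    maternal_weight = clip(maternal_weight),
    social_rank = social_rank,
    infant_age_at_onset = pmax(onset, 1),
    infant_weight = clip(infant_weight),
    infant_sex = infant_sex,
    dyadic_distance_hfd = pmin(pmax(dyadic_distance, 1), 5),
    cortisol_pre = clip(cortisol_pre, config$cortisol_floor),
    cortisol_post = clip(cortisol_post, config$cortisol_floor),
    crf_pre = clip(crf_pre, config$crf_floor),
    crf_post = clip(crf_post, config$crf_floor),
    stringsAsFactors = FALSE
  ), provenance = sprintf("synthetic (seed %d)", as.integer(seed)))

  structure(list(cohort = cohort,
                 truth = data.frame(dyad_id = cohort$dyad_id, v = v,
                                    stringsAsFactors = FALSE)),
            class = "synthetic_cohort")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Correlation of a constructed index with the hidden vulnerability truth
#'
#' Validation harness for parameter-recovery studies: given the hidden
#' latent values returned by [generate_cohort()] and a per-dyad index (for
#' example from [build_index()]), returns their Pearson correlation.
#'
#' @param cohort the generated [cohort_table()].
#' @param truth the `truth` data frame from [generate_cohort()] (columns
#'   `dyad_id`, `v`), or a numeric vector aligned with `cohort`.
#' @param index numeric per-dyad index values aligned with `cohort`.
#' @return the Pearson correlation (scalar).
#' @export
truth_recovery_report <- function(cohort, truth, index) {
  v <- if (is.data.frame(truth)) {
    truth$v[match(cohort$dyad_id, truth$dyad_id)]
  } else as.numeric(truth)
  if (length(v) != nrow(cohort) || anyNA(v)) {
    stop("truth values do not match the cohort")
  }
  if (length(index) != nrow(cohort)) {
    stop("length mismatch: index has ", length(index), " values for ",
         nrow(cohort), " dyads")
  }
  stats::cor(index, v)
}
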