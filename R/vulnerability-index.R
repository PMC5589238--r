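## Default candidate set mirroring the eight-factor structure-discovery
## clustering: five putative vulnerability observables plus the
## standardized cortisol change anchor and two peripheral variables.
.default_candidates <- c("maternal_weight", "dominance", "infant_weight",
                         "dyadic_distance_hfd", "cortisol_pre",
                         "infant_age_at_onset", "crf_pre", "z_delta_cortisol")

## Variables that are outcomes (HPA-axis measures); they may enter the
## clustering for structure discovery but never the composite index.
.outcome_variables <- c("z_delta_cortisol", "delta_cortisol", "delta_crf",
                        "cortisol_pre", "cortisol_post", "crf_pre", "crf_post",
                        "z_delta_crf")

#' Build the candidate-variable matrix from a cohort
#'
#' Resolves candidate names against the cohort columns plus two derived
#' variables: `dominance` (see [dominance_score()]) and `z_delta_cortisol`
#' (standardized post-minus-pre cortisol change).
#'
#' @param cohort a [cohort_table()] (complete cases are used).
#' @param candidates character vector of variable names.
#' @return numeric matrix, one column per candidate.
#' @keywords internal
candidate_matrix <- function(cohort, candidates) {
  cc <- suppressMessages(complete_cases(cohort))
  cols <- lapply(candidates, function(nm) {
    if (nm == "dominance") return(dominance_score(cc))
    if (nm == "z_delta_cortisol") {
      d <- cc$cortisol_post - cc$cortisol_pre
      return((d - mean(d)) / stats::sd(d))
    }
    if (!nm %in% names(cc)) stop("unknown candidate variable: ", nm)
    as.numeric(cc[[nm]])
  })
  m <- do.call(cbind, cols)
  colnames(m) <- candidates
  if (anyNA(m)) {
    keep <- stats::complete.cases(m)
    m <- m[keep, , drop = FALSE]
  }
  m
}

#' Hierarchical clustering of candidate variables
#'
#' Agglomerative clustering of variables (not dyads): the distance between
#' two variables is the Euclidean distance between their observation
#' columns, z-scored first by default. Heights are reported in
#' per-observation linkage units - raw Euclidean distance divided by
#' sqrt(n - 1) - so that for standardized columns the height between two
#' variables equals `sqrt(2 * (1 - r))` regardless of cohort size and a
#' fixed cutoff is meaningful across cohorts.
#'
#' @param cohort a [cohort_table()] with complete cases for the candidates.
#' @param candidates variable names (cohort columns plus the derived
#'   `dominance` and `z_delta_cortisol`); at least 2.
#' @param linkage `"complete"` (default), `"single"`, or `"average"`.
#' @param standardize z-score columns before computing distances (default
#'   TRUE; zero-variance candidates are then an error).
#' @return an object of class `"variable_cluster_tree"` wrapping the
#'   [stats::hclust()] result: `labels`, `merge`, `height`
#'   (non-decreasing, per-observation units), `hclust`, `n_obs`.
#' @export
cluster_variables <- function(cohort, candidates = .default_candidates,
                              linkage = c("complete", "single", "average"),
                              standardize = TRUE) {
  linkage <- match.arg(linkage)
  if (length(candidates) < 2) stop("need at least 2 candidate variables")
  m <- candidate_matrix(cohort, candidates)
  if (nrow(m) < 3) stop("too few complete observations to cluster variables")
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance candidate with standardization on: ",
           paste(colnames(m)[sds == 0], collapse = ", "))
    }
    m <- scale(m)
  }
  d <- stats::dist(t(m), method = "euclidean") / sqrt(nrow(m) - 1)
  hc <- stats::hclust(d, method = linkage)
  structure(list(labels = hc$labels, merge = hc$merge, height = hc$height,
                 hclust = hc, n_obs = nrow(m), linkage = linkage,
                 standardized = standardize),
            class = "variable_cluster_tree")
}

#' Select the core vulnerability variable set
#'
#' Cuts the variable tree at the given height and returns the flat cluster
#' containing the anchor variable (the standardized cortisol change by
#' default), minus the anchor itself and any other outcome variables.
#' Deterministic given the tree and cutoff, and monotone in the cutoff.
#'
#' @param tree a `"variable_cluster_tree"` from [cluster_variables()].
#' @param cutoff positive height in the tree's linkage units (default 1.2
#'   per-observation units, i.e. variables correlated above ~0.28 with the
#'   anchor cluster when standardized).
#' @param anchor the outcome variable anchoring the core cluster.
#' @return character vector of core variable names (possibly empty).
#' @export
select_core <- function(tree, cutoff = 1.2, anchor = "z_delta_cortisol") {
  stopifnot(inherits(tree, "variable_cluster_tree"))
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!anchor %in% tree$labels) stop("anchor not among tree leaves: ", anchor)
  groups <- stats::cutree(tree$hclust, h = cutoff)
  core <- names(groups)[groups == groups[[anchor]]]
  setdiff(core, c(anchor, .outcome_variables))
}

#' Default vulnerability orientations
#'
#' Signs such that a higher oriented value means a more vulnerable dyad:
#' maternal weight inverted (lighter mothers more vulnerable), infant
#' weight inverted, dyadic distance inverted (closer dyads more
#' vulnerable), raw social rank direct (subordinate, high rank number,
#' more vulnerable) and hence dominance inverted.
#'
#' @param core character vector of core variable names.
#' @return named numeric vector of +1/-1 orientations.
#' @export
default_orientations <- function(core) {
  known <- c(maternal_weight = -1, infant_weight = -1,
             dyadic_distance_hfd = -1, dominance = -1, social_rank = +1,
             maternal_age = -1, infant_age_at_onset = -1)
  unknown <- setdiff(core, names(known))
  if (length(unknown) > 0) {
    stop("no default orientation for: ", paste(unknown, collapse = ", "),
         "; supply orientations explicitly")
  }
  known[core]
}

#' Build the composite dyadic vulnerability index
#'
#' The index is the per-dyad sum of oriented z-scores of the core
#' variables, a dimensionless composite with cohort mean ~0 in which
#' higher values mean greater dyadic vulnerability. Association models are
#' fitted by least squares with infant sex as a two-level categorical
#' covariate: the index predicting the cortisol change score (slope, F of
#' the index term with df (1, n-3), partial eta squared), and the index
#' predicting baseline cortisol (adjusted R-squared).
#'
#' @param cohort a [cohort_table()]; complete cases are used.
#' @param core nonempty character vector of core variable names (cohort
#'   columns or the derived `dominance`).
#' @param orientations named +1/-1 vector, one entry per core variable;
#'   defaults to [default_orientations()].
#' @return list of class `"vulnerability_index_result"`: `core_variables`,
#'   `orientations`, `index` (per-dyad, named by dyad), `association`
#'   (list `slope`, `F`, `df`, `p`, `partial_eta_sq`), `r_index_delta`,
#'   `adj_r2_pre_cortisol`.
#' @export
build_index <- function(cohort, core, orientations = default_orientations(core)) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (length(core) == 0) stop("core variable set is empty")
  missing_or <- setdiff(core, names(orientations))
  if (length(missing_or) > 0) {
    stop("orientation missing for core variable(s): ",
         paste(missing_or, collapse = ", "))
  }
  if (!all(abs(orientations[core]) == 1)) stop("orientations must be +1 or -1")
  cc <- suppressMessages(complete_cases(cohort))
  m <- candidate_matrix(cc, core)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance core variable: ", paste(core[sds == 0], collapse = ", "))
  }
  z <- scale(m)
  index <- as.vector(z %*% orientations[core])
  names(index) <- cc$dyad_id

  delta <- cc$cortisol_post - cc$cortisol_pre
  sexf <- factor(cc$infant_sex, levels = c("M", "F"))
  fit <- stats::lm(delta ~ index + sexf)
  av <- stats::anova(fit)
  ss_idx <- av["index", "Sum Sq"]; ss_err <- av["Residuals", "Sum Sq"]
  df_err <- av["Residuals", "Df"]
  t_idx <- summary(fit)$coefficients["index", "t value"]
  association <- list(
    slope = unname(stats::coef(fit)["index"]),
    F = t_idx^2, df = c(1, df_err),
    p = summary(fit)$coefficients["index", "Pr(>|t|)"],
    partial_eta_sq = if (ss_idx + ss_err == 0) 0 else {
      (t_idx^2) / (t_idx^2 + df_err)
    }
  )
  fit_pre <- stats::lm(cc$cortisol_pre ~ index + sexf)
  structure(list(core_variables = core, orientations = orientations[core],
                 index = index, association = association,
                 r_index_delta = stats::cor(index, delta),
                 adj_r2_pre_cortisol = summary(fit_pre)$adj.r.squared),
            class = "vulnerability_index_result")
}
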