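#' Pipeline run configuration
#'
#' @param input path to a cohort file, or a [synthetic_config()] to
#'   simulate one, or a [cohort_table()] directly.
#' @param seed master integer seed; per-stage seeds are derived from it and
#'   recorded in the report (`simulate` uses `seed`, the permutation
#'   contrast `seed + 1`).
#' @param stages character vector of stages to run, in fixed order, among
#'   `"changes"`, `"ratio"`, `"contrasts"`, `"index"`.
#' @param n_permutations permutation count for the ratio contrast.
#' @param cutoff core-selection cutoff in per-observation linkage units.
#' @param linkage clustering linkage method.
#' @param rank_coding `"dominance"` (default) or `"raw"` for how social
#'   rank enters predictor contrasts and clustering.
#' @param out_dir optional output directory; when given, per-stage tables,
#'   the consolidated JSON report and the verbatim config are written there.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(input = synthetic_config(), seed = 1L,
                       stages = c("changes", "ratio", "contrasts", "index"),
                       n_permutations = 9999L, cutoff = 1.2,
                       linkage = "complete",
                       rank_coding = c("dominance", "raw"),
                       out_dir = NULL) {
  rank_coding <- match.arg(rank_coding)
  stages <- match.arg(stages, c("changes", "ratio", "contrasts", "index"),
                      several.ok = TRUE)
  structure(list(input = input, seed = as.integer(seed), stages = stages,
                 seeds = list(simulate = as.integer(seed),
                              permutation = as.integer(seed) + 1L),
                 n_permutations = as.integer(n_permutations),
                 cutoff = cutoff, linkage = linkage,
                 rank_coding = rank_coding, out_dir = out_dir),
            class = "run_config")
}

.log_stage <- function(...) message(sprintf("[allostat %s] ", format(Sys.time(), "%H:%M:%S")), ...)

#' Run the full analysis pipeline
#'
#' Resolves the input cohort (reading or simulating as needed), then runs
#' the enabled stages in order - change scores, allostasis-ratio contrast,
#' group contrasts (measure x condition, baseline split, predictor tables,
#' cross-sectional, pen effect), vulnerability index - and assembles one
#' consolidated report containing every summary statistic the stages
#' produce. Identical config and seeds give a byte-identical report.
#' P-values collected across analyses are supplementarily
#' Benjamini-Hochberg adjusted in `report$multiplicity` (the primary
#' decision rule remains two-sided p <= 0.05 uncorrected, mirroring the
#' source analyses; the BH column is clearly supplementary).
#'
#' @param config a [run_config()].
#' @return the report (a nested list, class `"allostat_report"`),
#'   invisibly if written to disk. Stage failures abort with an error
#'   naming the stage.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  report <- list(schema = "allostat-report/1",
                 seeds = config$seeds,
                 stages = config$stages)

  ## resolve input
  if (inherits(config$input, "cohort_table")) {
    cohort <- config$input
    report$input <- list(kind = "cohort", n = nrow(cohort))
  } else if (inherits(config$input, "synthetic_config")) {
    .log_stage("simulate: generating synthetic cohort")
    sim <- generate_cohort(config$input, seed = config$seeds$simulate)
    cohort <- sim$cohort
    report$input <- list(kind = "synthetic", n = nrow(cohort),
                         seed = config$seeds$simulate)
  } else if (is.character(config$input)) {
    .log_stage("read: ", config$input)
    cohort <- read_cohort(config$input)
    report$input <- list(kind = "file", path = config$input, n = nrow(cohort))
  } else stop("unsupported input type")

  cc <- suppressMessages(complete_cases(cohort))
  report$input$n_complete <- nrow(cc)
  run_stage <- function(stage, expr) {
    .log_stage("stage ", stage)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  changes <- run_stage("changes", compute_changes(cohort))
  if ("changes" %in% config$stages) {
    sc <- empirical_summary(changes$cortisol_pre, changes$cortisol_post)
    sf <- empirical_summary(changes$crf_pre, changes$crf_post)
    report$changes <- list(
      cortisol = c(unclass(sc), unclass(change_identity(sc))),
      crf = c(unclass(sf), unclass(change_identity(sf))),
      mean_delta_cortisol = mean(changes$delta_cortisol),
      mean_delta_crf = mean(changes$delta_crf),
      mean_abs_delta_cortisol = mean(abs(changes$delta_cortisol)),
      range_delta_cortisol = range(changes$delta_cortisol),
      paired_cortisol = unclass(paired_test(changes$cortisol_pre, changes$cortisol_post)),
      paired_crf = unclass(paired_test(changes$crf_pre, changes$crf_post)),
      rtm_cortisol = .flatten_rtm(rtm_diagnostics(changes$cortisol_pre, changes$cortisol_post))
    )
  }

  if ("ratio" %in% config$stages) {
    perm <- run_stage("ratio", contrast_measures_permutation(
      changes, n_permutations = config$n_permutations,
      seed = config$seeds$permutation))
    report$ratio <- list(
      table = as.data.frame(perm$table),
      observed = perm$observed, p_permutation = perm$p,
      n_permutations = perm$n_permutations, seed = perm$seed,
      fisher_literal_p = fisher_2x2_literal(perm$table)$p)
  }

  if ("contrasts" %in% config$stages) {
    report$contrasts <- run_stage("contrasts", {
      rank_var <- if (config$rank_coding == "dominance") {
        dominance_score(cc)
      } else cc$social_rank
      predictors <- list(
        maternal_age = cc$maternal_age,
        maternal_weight = cc$maternal_weight,
        cortisol_pre = cc$cortisol_pre,
        crf_pre = cc$crf_pre,
        dyadic_distance_hfd = cc$dyadic_distance_hfd,
        social_rank = rank_var,
        infant_age_at_onset = cc$infant_age_at_onset,
        infant_weight = cc$infant_weight,
        infant_sex_M1 = as.numeric(cc$infant_sex == "M")
      )
      ptab <- do.call(rbind, lapply(names(predictors), function(nm) {
        x <- predictors[[nm]]
        if (anyNA(x)) return(NULL)
        as.data.frame(unclass(predictor_contrast(x, changes, name = nm))[
          c("predictor", "r_cort", "p_cort", "r_crf", "p_crf",
            "interaction_F", "interaction_p")])
      }))
      split <- baseline_split_interaction(changes$cortisol_pre, changes$cortisol_post,
                                          covariate = if (anyNA(cc$infant_age_at_onset)) NULL else cc$infant_age_at_onset)
      pen_fit <- stats::anova(stats::lm(changes$delta_cortisol ~ factor(cc$pen_id)))
      list(
        measure_condition = unclass(measure_condition_anova(changes)),
        predictor_table = ptab,
        baseline_split = list(cells = split$cells, F = split$F, df = split$df,
                              p = split$p, partial_eta_sq = split$partial_eta_sq,
                              posthoc = split$posthoc),
        pen_effect = list(F = pen_fit[1, "F value"], p = pen_fit[1, "Pr(>F)"]),
        cross_sectional = tryCatch(unclass(cross_sectional_analysis(cohort)),
                                   error = function(e) list(skipped = conditionMessage(e)))
      )
    })
  }

  if ("index" %in% config$stages) {
    report$index <- run_stage("index", {
      tree <- cluster_variables(cohort, linkage = config$linkage)
      core <- select_core(tree, cutoff = config$cutoff)
      if (length(core) == 0) {
        list(core_variables = character(0),
             note = "no variables co-cluster with the change-score anchor at this cutoff")
      } else {
        res <- build_index(cohort, core)
        list(tree = .serialize_tree(tree), core_variables = res$core_variables,
             orientations = as.list(res$orientations),
             index = as.list(res$index), association = res$association,
             r_index_delta = res$r_index_delta,
             adj_r2_pre_cortisol = res$adj_r2_pre_cortisol)
      }
    })
  }

  report$multiplicity <- .bh_table(report)
  class(report) <- "allostat_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    utils::write.csv(as.data.frame(changes),
                     file.path(config$out_dir, "change_scores.csv"), row.names = FALSE)
    jsonlite::write_json(.strip_classes(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    cfg <- config; cfg$input <- if (is.character(cfg$input)) cfg$input else .strip_classes(unclass(cfg$input))
    jsonlite::write_json(.strip_classes(unclass(cfg)),
                         file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    return(invisible(report))
  }
  report
}

.flatten_rtm <- function(r) {
  list(var_pre = r$var_pre, var_post = r$var_post,
       pitman_morgan = r$pitman_morgan,
       symmetric_inversion = unclass(r$symmetric_inversion))
}

.serialize_tree <- function(tree) {
  list(labels = tree$labels,
       merge = apply(tree$merge, 1, function(row) as.list(row)),
       height = tree$height, linkage = tree$linkage, n_obs = tree$n_obs)
}

## collect every named p-value in the report and attach BH-adjusted values
.bh_table <- function(report) {
  ps <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], paste(path, nm, sep = "/"))
    } else if (is.numeric(x) && length(x) == 1 && grepl("(^|/)p(_cort|_crf)?$", path)) {
      ps[[path]] <<- x
    }
  }
  for (sec in intersect(names(report), c("changes", "ratio", "contrasts", "index"))) {
    walk(report[[sec]], sec)
  }
  if (length(ps) == 0) return(NULL)
  data.frame(analysis = names(ps), p = unlist(ps),
             p_adj_bh = stats::p.adjust(unlist(ps), method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

.strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(lapply(x, unclass)))
  if (is.list(x)) {
    x <- lapply(x, .strip_classes)
  }
  if (!is.null(attr(x, "class")) && !is.data.frame(x)) attr(x, "class") <- NULL
  x
}
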