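## Canonical column schema for a dyad cohort table. Extra columns are carried
## through untouched so users can attach covariates.
.cohort_numeric <- c(
  "maternal_age", "maternal_weight", "infant_age_at_onset", "infant_weight",
  "dyadic_distance_hfd", "cortisol_pre", "cortisol_post", "crf_pre", "crf_post"
)
.cohort_columns <- c(
  "dyad_id", "pen_id", "exposure_cohort", "maternal_age", "maternal_weight",
  "social_rank", "infant_age_at_onset", "infant_weight", "infant_sex",
  "dyadic_distance_hfd", "cortisol_pre", "cortisol_post", "crf_pre", "crf_post"
)
.hormone_columns <- c("cortisol_pre", "cortisol_post", "crf_pre", "crf_post")

#' Construct a validated dyad cohort table
#'
#' A cohort table holds one row per mother-infant dyad: maternal covariates
#' (age in years, weight in kg, within-pen social rank with 1 = most
#' dominant), infant covariates (age at stressor onset in days post-partum,
#' weight in kg, sex), the mean dyadic-distance proximity score on the 1-5
#' observational scale, and pre/post values of plasma cortisol (ug/dl) and
#' CSF CRF (pg/ml). Any field may be `NA`.
#'
#' @param data data frame containing at least the canonical columns
#'   `dyad_id`, `pen_id`, `exposure_cohort`, `maternal_age`,
#'   `maternal_weight`, `social_rank`, `infant_age_at_onset`,
#'   `infant_weight`, `infant_sex`, `dyadic_distance_hfd`, `cortisol_pre`,
#'   `cortisol_post`, `crf_pre`, `crf_post`. Extra columns are kept.
#' @param provenance free-text note recording where the table came from.
#'
#' @return a `cohort_table`: a data frame with class `"cohort_table"` and a
#'   `"provenance"` attribute.
#'
#' @details Validation enforces: unique `dyad_id`; positive weights and
#'   hormone values where present; `dyadic_distance_hfd` within \[1, 5\];
#'   `infant_sex` in \{M, F\}; `exposure_cohort` in \{early, late\}; and
#'   social ranks within each pen distinct and within `1..pen size` (rank
#'   ties are rejected because the dominance protocol forces a total order
#'   within a pen).
#' @export
cohort_table <- function(data, provenance = "") {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.cohort_columns, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in .cohort_numeric) data[[col]] <- as.numeric(data[[col]])
  data$social_rank <- as.integer(data$social_rank)
  for (col in c("dyad_id", "pen_id", "exposure_cohort", "infant_sex")) {
    data[[col]] <- as.character(data[[col]])
  }
  validate_cohort(data)
  structure(data, class = c("cohort_table", "data.frame"), provenance = provenance)
}

#' Validate cohort invariants
#'
#' @param data data frame with the canonical cohort columns.
#' @return invisibly `TRUE`; otherwise an error citing the violated invariant.
#' @keywords internal
validate_cohort <- function(data) {
  id <- data$dyad_id
  if (anyNA(id)) stop("dyad_id may not be missing")
  if (anyDuplicated(id)) {
    stop("duplicate dyad_id: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  positive <- c("maternal_weight", "infant_weight", .hormone_columns)
  for (col in positive) {
    bad <- which(!is.na(data[[col]]) & data[[col]] <= 0)
    if (length(bad) > 0) {
      stop(sprintf("column '%s' must be positive; violated in row(s) %s",
                   col, paste(bad, collapse = ", ")))
    }
  }
  dd <- data$dyadic_distance_hfd
  bad <- which(!is.na(dd) & (dd < 1 | dd > 5))
  if (length(bad) > 0) {
    stop("dyadic_distance_hfd must lie in [1, 5]; violated in row(s) ",
         paste(bad, collapse = ", "))
  }
  sex <- data$infant_sex
  if (any(!is.na(sex) & !sex %in% c("M", "F"))) {
    stop("infant_sex must be 'M' or 'F'")
  }
  ec <- data$exposure_cohort
  if (any(!is.na(ec) & !ec %in% c("early", "late"))) {
    stop("exposure_cohort must be 'early' or 'late'")
  }
  for (pen in unique(data$pen_id[!is.na(data$pen_id)])) {
    rows <- data$pen_id == pen & !is.na(data$pen_id)
    ranks <- data$social_rank[rows]
    ranks <- ranks[!is.na(ranks)]
    if (anyDuplicated(ranks)) {
      stop(sprintf("social ranks within pen '%s' must be distinct (rank ties are rejected)", pen))
    }
    if (length(ranks) > 0 && (min(ranks) < 1 || max(ranks) > sum(rows))) {
      stop(sprintf("social_rank in pen '%s' must lie between 1 and the pen size (%d)",
                   pen, sum(rows)))
    }
  }
  invisible(TRUE)
}

#' Read a dyad cohort table from delimited text
#'
#' @param path path to a UTF-8 delimited text file with a mandatory header
#'   row. Column matching is case-insensitive; extra columns are carried
#'   through. Empty cells and `"NA"` are read as missing.
#' @param delim `"auto"` (default; chooses tab if the header contains a tab,
#'   else comma), `"comma"`, or `"tab"`.
#' @return a validated [cohort_table()] with row order preserved and
#'   provenance set to the file path.
#' @export
read_cohort <- function(path, delim = c("auto", "comma", "tab")) {
  delim <- match.arg(delim)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- switch(delim,
    comma = ",",
    tab = "\t",
    auto = if (grepl("\t", header)) "\t" else ","
  )
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           na.strings = c("", "NA"), colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           encoding = "UTF-8")
  names(raw)[match(tolower(.cohort_columns), tolower(names(raw)))] <- .cohort_columns
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("header is missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in c(.cohort_numeric, "social_rank")) {
    vals <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("malformed numeric cell in column '%s', row %d: '%s'",
                   col, bad[1], vals[bad[1]]))
    }
    raw[[col]] <- parsed
  }
  cohort_table(raw, provenance = path)
}

#' Write a cohort table to delimited text
#'
#' Missing values are written as empty cells; `read_cohort()` on the result
#' reproduces the cohort field-for-field at full numeric precision.
#'
#' @param cohort a [cohort_table()].
#' @param path output file path.
#' @param delim `"comma"` (default) or `"tab"`.
#' @return invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, delim = c("comma", "tab")) {
  delim <- match.arg(delim)
  stopifnot(inherits(cohort, "cohort_table"))
  df <- as.data.frame(cohort)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(x) {
        if (is.na(x)) NA_character_ else format(x, digits = 17, scientific = FALSE)
      }, character(1))
    }
  }
  utils::write.table(df, path, sep = if (delim == "comma") "," else "\t",
                     na = "", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict a cohort to dyads with complete hormone data
#'
#' Keeps only dyads with all four hormone measures (`cortisol_pre`,
#' `cortisol_post`, `crf_pre`, `crf_post`) present. In the motivating study
#' 24 dyads were enrolled but HPA-axis data were unavailable for two,
#' leaving 22 for analysis; this operation realises that complete-case view.
#'
#' @param cohort a [cohort_table()].
#' @return the complete-case `cohort_table`; a message reports the counts
#'   and a warning is raised if no dyads survive.
#' @export
complete_cases <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  keep <- rowSums(is.na(as.data.frame(cohort)[, .hormone_columns])) == 0
  out <- cohort[keep, , drop = FALSE]
  message(sprintf("complete_cases: %d of %d dyads retained", sum(keep), length(keep)))
  if (nrow(out) == 0) warning("no dyads have complete hormone data")
  structure(out, class = c("cohort_table", "data.frame"),
            provenance = attr(cohort, "provenance"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Dyad cohort: %d dyads, %d pens", nrow(x),
              length(unique(x$pen_id))), "\n")
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("Provenance:", prov, "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
`[.cohort_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(.cohort_columns %in% names(out))) {
    class(out) <- c("cohort_table", "data.frame")
    attr(out, "provenance") <- attr(x, "provenance")
  }
  out
}
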