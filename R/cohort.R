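#' @importFrom rlang .data
#' @importFrom stats median quantile rbinom rnorm runif qnorm plogis qlogis
#'   qchisq pchisq setNames sd var acf uniroot optim integrate pnorm
NULL

# Enumerations used throughout the cohort schema.
PATHWAYS <- c("IDA", "BCSP", "SYMPTOMATIC")
TNM_STAGES <- c("I", "II", "III", "IV")
SEXES <- c("M", "F")
LOCATION_TOKENS <- c("PROX", "DIST")
EXCLUSION_CATEGORIES <- c(
  "incomplete", "metachronous_duplicate", "other_neoplasm",
  "non_incident", "incidental_or_followup"
)

COHORT_COLUMNS <- c(
  "id", "age", "sex", "hb_g_l", "pathway", "tnm_stage", "locations",
  "prior_bc_months", "prior_bc_hb_g_l", "exclusion"
)

#' Collapse TNM stage to the early/late dichotomy
#'
#' Stages I and II are grouped as `"early"`, stages III and IV as `"late"`.
#' This is the standard two-category prognostic split used when modelling
#' stage shift between diagnostic pathways.
#'
#' @param tnm_stage Character vector with values in `"I"`, `"II"`, `"III"`,
#'   `"IV"`.
#' @return Character vector of `"early"` / `"late"`.
#' @examples
#' derive_stage_category(c("I", "II", "III", "IV"))
#' @export
derive_stage_category <- function(tnm_stage) {
  bad <- !tnm_stage %in% TNM_STAGES
  if (any(bad)) {
    stop("invalid TNM stage value(s): ",
         paste(unique(tnm_stage[bad]), collapse = ", "), call. = FALSE)
  }
  ifelse(tnm_stage %in% c("I", "II"), "early", "late")
}

#' Derive tumour side from lesion locations
#'
#' Lesions at or distal to the splenic flexure are left-sided; lesions
#' proximal to it are right-sided. A case with synchronous lesions is
#' classified right-sided if *any* lesion is proximal to the splenic
#' flexure.
#'
#' @param locations Character vector; each element lists lesion locations as
#'   semicolon-joined tokens `"PROX"` (proximal to the splenic flexure) and
#'   `"DIST"` (at or distal to it), e.g. `"DIST"` or `"PROX;DIST"`.
#' @return Character vector of `"left"` / `"right"`.
#' @examples
#' derive_side(c("DIST", "PROX;DIST", "PROX"))
#' @export
derive_side <- function(locations) {
  if (any(is.na(locations) | !nzchar(trimws(locations)))) {
    stop("each record must have at least one tumour location", call. = FALSE)
  }
  toks <- strsplit(locations, ";", fixed = TRUE)
  vapply(toks, function(tk) {
    tk <- trimws(tk)
    tk <- tk[nzchar(tk)]
    if (length(tk) == 0L) {
      stop("each record must have at least one tumour location", call. = FALSE)
    }
    bad <- setdiff(tk, LOCATION_TOKENS)
    if (length(bad) > 0L) {
      stop("unknown location token(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(tk == "PROX")) "right" else "left"
  }, character(1))
}

validate_cohort_rows <- function(data) {
  included <- is.na(data$exclusion) | !nzchar(data$exclusion)
  check_enum <- function(values, allowed, column, rows_must = included) {
    bad <- which((rows_must | !is.na(values)) &
                   (is.na(values) | !values %in% allowed))
    # excluded rows may leave a field empty, but a non-missing value must
    # still be a legal token
    bad <- bad[included[bad] | !is.na(values[bad])]
    if (length(bad) > 0L) {
      stop(sprintf("row %d: invalid or missing value in column '%s'",
                   bad[1], column), call. = FALSE)
    }
  }
  check_enum(data$sex, SEXES, "sex")
  check_enum(data$pathway, PATHWAYS, "pathway")
  check_enum(data$tnm_stage, TNM_STAGES, "tnm_stage")
  if (any(!is.na(data$exclusion) & nzchar(data$exclusion) &
            !data$exclusion %in% EXCLUSION_CATEGORIES)) {
    bad <- which(!is.na(data$exclusion) & nzchar(data$exclusion) &
                   !data$exclusion %in% EXCLUSION_CATEGORIES)
    stop(sprintf("row %d: invalid value in column 'exclusion'", bad[1]),
         call. = FALSE)
  }
  bad_age <- which(included & (is.na(data$age) | data$age <= 0))
  if (length(bad_age) > 0L) {
    stop(sprintf("row %d: invalid or missing value in column 'age'",
                 bad_age[1]), call. = FALSE)
  }
  bad_hb <- which(included & (is.na(data$hb_g_l) | data$hb_g_l <= 0))
  if (length(bad_hb) > 0L) {
    stop(sprintf("row %d: invalid or missing value in column 'hb_g_l'",
                 bad_hb[1]), call. = FALSE)
  }
  bad_loc <- which(included & (is.na(data$locations) |
                                 !nzchar(trimws(data$locations))))
  if (length(bad_loc) > 0L) {
    stop(sprintf("row %d: invalid or missing value in column 'locations'",
                 bad_loc[1]), call. = FALSE)
  }
  bad_bc <- which(!is.na(data$prior_bc_months) & data$prior_bc_months < 0)
  if (length(bad_bc) > 0L) {
    stop(sprintf("row %d: negative value in column 'prior_bc_months'",
                 bad_bc[1]), call. = FALSE)
  }
  if (anyDuplicated(data$id)) {
    stop("duplicate record id(s): ",
         paste(unique(data$id[duplicated(data$id)]), collapse = ", "),
         call. = FALSE)
  }
  invisible(data)
}

add_derived_columns <- function(data) {
  included <- is.na(data$exclusion) | !nzchar(data$exclusion)
  stage_category <- rep(NA_character_, nrow(data))
  side <- rep(NA_character_, nrow(data))
  ok_stage <- !is.na(data$tnm_stage)
  stage_category[ok_stage] <- derive_stage_category(data$tnm_stage[ok_stage])
  ok_loc <- !is.na(data$locations) & nzchar(trimws(data$locations))
  side[ok_loc] <- derive_side(data$locations[ok_loc])
  dplyr::mutate(data, stage_category = stage_category, side = side)
}

#' Read a cohort CSV
#'
#' Reads a patient-level cohort file (one row per colorectal-cancer case)
#' and derives the analysis fields `stage_category` (early/late) and
#' `side` (left/right). The expected columns are `id`, `age`, `sex` (M/F),
#' `hb_g_l`, `pathway` (IDA/BCSP/SYMPTOMATIC), `tnm_stage` (I--IV),
#' `locations` (semicolon-joined PROX/DIST tokens), `prior_bc_months`
#' (months from the last prior blood count back from the start of the
#' presentation period; empty if none), `prior_bc_hb_g_l` (its Hb result)
#' and `exclusion` (empty for included records).
#'
#' @param path Path to a UTF-8 comma-separated file with a header row.
#' @return A tibble with the schema columns plus derived `stage_category`
#'   and `side`, in file order.
#' @seealso [write_cohort()], [apply_exclusions()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(COHORT_COLUMNS, header)
  if (length(missing_cols) > 0L) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra_cols <- setdiff(header, COHORT_COLUMNS)
  if (length(extra_cols) > 0L) {
    stop("cohort file has unexpected column(s): ",
         paste(extra_cols, collapse = ", "), call. = FALSE)
  }
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      age = readr::col_double(),
      sex = readr::col_character(),
      hb_g_l = readr::col_double(),
      pathway = readr::col_character(),
      tnm_stage = readr::col_character(),
      locations = readr::col_character(),
      prior_bc_months = readr::col_double(),
      prior_bc_hb_g_l = readr::col_double(),
      exclusion = readr::col_character()
    ),
    progress = FALSE, lazy = FALSE
  )
  problems <- readr::problems(data)
  if (nrow(problems) > 0L) {
    stop(sprintf("unparseable cell at row %d, column %d of %s",
                 problems$row[1], problems$col[1], path), call. = FALSE)
  }
  validate_cohort_rows(data)
  add_derived_columns(data)
}

#' Write a cohort CSV
#'
#' Writes the schema columns of a cohort tibble (derived columns are
#' recomputed on read, so they are not stored). `write_cohort()` followed by
#' [read_cohort()] reproduces every field.
#'
#' @param cohort Cohort tibble as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort[, COHORT_COLUMNS], path, na = "", progress = FALSE)
  invisible(path)
}

#' Apply the cohort exclusion filter
#'
#' Removes records flagged for exclusion (incomplete record, metachronous
#' duplicate entry, other neoplastic diagnosis, non-incident presentation,
#' diagnosis on follow-up or as an incidental finding) and tallies each
#' category.
#'
#' @param cohort Cohort tibble with an `exclusion` column (`NA` or `""` for
#'   included records).
#' @return A list with elements `cohort` (the retained records, in order)
#'   and `report` (an exclusion report: named counts per category plus
#'   `n_input` and `n_retained`).
#' @examples
#' cohort <- generate_cohort(calibrated_config(group_sizes = c(
#'   IDA = 5, BCSP = 5, SYMPTOMATIC = 10)), seed = 1)
#' apply_exclusions(cohort)$report
#' @export
apply_exclusions <- function(cohort) {
  flagged <- !is.na(cohort$exclusion) & nzchar(cohort$exclusion)
  counts <- vapply(EXCLUSION_CATEGORIES,
                   function(cat) sum(cohort$exclusion[flagged] == cat),
                   integer(1))
  report <- structure(
    list(counts = counts,
         n_input = nrow(cohort),
         n_retained = sum(!flagged)),
    class = "exclusion_report"
  )
  list(cohort = cohort[!flagged, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report:", x$n_input, "records in,", x$n_retained,
      "retained\n")
  for (nm in names(x$counts)) cat(sprintf("  %-24s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Serialize an exclusion report to JSON
#'
#' @param report An exclusion report from [apply_exclusions()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to file).
#' @export
exclusion_report_json <- function(report, path = NULL) {
  obj <- c(as.list(report$counts),
           list(n_input = report$n_input, n_retained = report$n_retained))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Classify prior blood-count history
#'
#' Classifies each record by the outcome of the last blood count taken
#' within a look-back window measured from the start of the presentation
#' period (the 3 months immediately before diagnosis): `"not_done"` if no
#' count exists or it falls outside the window, `"done_low"` if the count is
#' within the window and its Hb is strictly below the anaemia threshold, and
#' `"done_normal"` otherwise (Hb exactly at the threshold counts as normal).
#'
#' @param cohort Cohort tibble; uses columns `prior_bc_months` and
#'   `prior_bc_hb_g_l`.
#' @param window_months Look-back window in months (default 24, i.e. the
#'   2-year comparison window).
#' @param hb_threshold Anaemia threshold in g/l (default 110).
#' @return The cohort with an added `bc_class` column
#'   (`done_normal`/`done_low`/`not_done`).
#' @export
classify_blood_count_history <- function(cohort, window_months = 24,
                                         hb_threshold = 110) {
  stopifnot(window_months > 0, hb_threshold > 0)
  if (any(!is.na(cohort$prior_bc_months) & cohort$prior_bc_months < 0)) {
    stop("negative prior blood-count offset", call. = FALSE)
  }
  dplyr::mutate(
    cohort,
    bc_class = dplyr::case_when(
      is.na(.data$prior_bc_months) ~ "not_done",
      .data$prior_bc_months > window_months ~ "not_done",
      .data$prior_bc_hb_g_l < hb_threshold ~ "done_low",
      TRUE ~ "done_normal"
    )
  )
}
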