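q1q3 <- function(x) unname(quantile(x, c(0.25, 0.75), type = 7, names = FALSE))

pct <- function(num, den, digits = 1) round(100 * num / den, digits)

group_summary <- function(data, n_total, digits = 1) {
  tibble::tibble(
    n = nrow(data),
    percent = pct(nrow(data), n_total, digits),
    sex_ratio_mf = round(sum(data$sex == "M") / sum(data$sex == "F"), 1),
    age_median = median(data$age),
    age_q1 = q1q3(data$age)[1],
    age_q3 = q1q3(data$age)[2],
    hb_median = median(data$hb_g_l),
    hb_q1 = q1q3(data$hb_g_l)[1],
    hb_q3 = q1q3(data$hb_g_l)[2],
    early_n = sum(data$stage_category == "early"),
    early_percent = pct(sum(data$stage_category == "early"), nrow(data),
                        digits),
    right_n = sum(data$side == "right"),
    right_percent = pct(sum(data$side == "right"), nrow(data), digits)
  )
}

#' Case-mix summary by presentation pathway
#'
#' Recomputes the descriptive table of the cohort split by diagnostic
#' pathway: group size and percentage of the whole cohort, M/F sex ratio,
#' median (Q1--Q3) of age and Hb at diagnosis, and the counts and
#' percentages of early-stage and right-sided disease. Quartiles use the
#' linear-interpolation convention (R quantile type 7); percentages are
#' rounded to one decimal.
#'
#' @param cohort Cohort tibble with derived `stage_category` and `side`.
#' @return A tibble with one row per pathway present in the cohort.
#' @examples
#' pathway_summary(generate_cohort(calibrated_config(), seed = 1))
#' @export
pathway_summary <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  n_total <- nrow(cohort)
  cohort |>
    dplyr::group_by(pathway = factor(.data$pathway,
                                     levels = PATHWAYS)) |>
    dplyr::group_modify(~ group_summary(.x, n_total)) |>
    dplyr::ungroup() |>
    dplyr::mutate(pathway = as.character(.data$pathway))
}

#' IDA-subgroup summary by blood-count history
#'
#' Recomputes the descriptive table of the iron-deficiency-anaemia subgroup
#' split by the outcome of the last blood count in the comparison window:
#' done with normal Hb, done with low Hb, or not done. Percentages are
#' rounded to whole numbers, matching the granularity at which such
#' subgroup tables are conventionally reported.
#'
#' @param ida_cohort Cohort tibble containing IDA-pathway records only.
#' @param window_months,hb_threshold Passed to
#'   [classify_blood_count_history()].
#' @return A tibble with one row per blood-count class present.
#' @export
blood_count_summary <- function(ida_cohort, window_months = 24,
                                hb_threshold = 110) {
  if (nrow(ida_cohort) == 0L) stop("empty cohort", call. = FALSE)
  if (any(ida_cohort$pathway != "IDA")) {
    stop("blood_count_summary() expects IDA-pathway records only",
         call. = FALSE)
  }
  n_total <- nrow(ida_cohort)
  classify_blood_count_history(ida_cohort, window_months, hb_threshold) |>
    dplyr::group_by(bc_class = factor(.data$bc_class,
                                      levels = c("done_normal", "done_low",
                                                 "not_done"))) |>
    dplyr::group_modify(~ group_summary(.x, n_total, digits = 0)) |>
    dplyr::ungroup() |>
    dplyr::mutate(bc_class = as.character(.data$bc_class))
}

#' Cumulative prevalence of prior blood counts by look-back horizon
#'
#' For each look-back horizon (months before the presentation period),
#' computes the cumulative percentage of the IDA subgroup with at least one
#' blood count within that horizon, split by tumour stage and by whether
#' the count's Hb was below the anaemia threshold. At each horizon the
#' (stage, Hb class) splits sum to the overall cumulative percentage.
#'
#' @param ida_cohort Cohort tibble containing IDA-pathway records only.
#' @param horizons_months Strictly increasing vector of look-back horizons
#'   in months (default `c(12, 24, 36)`).
#' @param hb_threshold Anaemia threshold in g/l (default 110).
#' @return A long tibble with columns `horizon_months`, `stage_category`,
#'   `hb_class` (`low`/`normal`), `n` and `cum_percent` (of the whole
#'   subgroup), plus per-horizon totals in attribute-free long rows where
#'   `stage_category = "all"` and `hb_class = "all"`.
#' @export
cumulative_prevalence <- function(ida_cohort,
                                  horizons_months = c(12, 24, 36),
                                  hb_threshold = 110) {
  if (length(horizons_months) == 0L) stop("no horizons given", call. = FALSE)
  if (any(diff(horizons_months) <= 0)) {
    stop("horizons must be strictly increasing", call. = FALSE)
  }
  if (any(ida_cohort$pathway != "IDA")) {
    stop("cumulative_prevalence() expects IDA-pathway records only",
         call. = FALSE)
  }
  n_total <- nrow(ida_cohort)
  done <- dplyr::filter(ida_cohort, !is.na(.data$prior_bc_months)) |>
    dplyr::mutate(hb_class = ifelse(.data$prior_bc_hb_g_l < hb_threshold,
                                    "low", "normal"))
  per_horizon <- purrr::map(horizons_months, function(h) {
    within <- dplyr::filter(done, .data$prior_bc_months <= h)
    split <- within |>
      dplyr::count(.data$stage_category, .data$hb_class) |>
      dplyr::mutate(horizon_months = h,
                    cum_percent = 100 * .data$n / n_total)
    total <- tibble::tibble(stage_category = "all", hb_class = "all",
                            n = nrow(within), horizon_months = h,
                            cum_percent = 100 * nrow(within) / n_total)
    dplyr::bind_rows(split, total)
  })
  dplyr::bind_rows(per_horizon) |>
    dplyr::select("horizon_months", "stage_category", "hb_class", "n",
                  "cum_percent")
}

#' Stage distribution by pathway (stacked-bar data and plot)
#'
#' @param cohort Cohort tibble.
#' @return A ggplot showing the early/late stage split within each
#'   presentation pathway.
#' @export
plot_stage_distribution <- function(cohort) {
  counts <- cohort |>
    dplyr::count(.data$pathway, .data$stage_category) |>
    dplyr::group_by(.data$pathway) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$pathway, y = .data$percent,
                               fill = .data$stage_category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Presentation pathway", y = "% of cases",
                  fill = "Stage") +
    ggplot2::theme_minimal()
}

#' Cumulative blood-count prevalence plot
#'
#' @param prevalence Long tibble from [cumulative_prevalence()].
#' @return A ggplot of cumulative percentage against look-back horizon,
#'   one line per (stage, Hb class) stratum.
#' @export
plot_cumulative_prevalence <- function(prevalence) {
  strata <- dplyr::filter(prevalence, .data$stage_category != "all")
  ggplot2::ggplot(strata,
                  ggplot2::aes(x = .data$horizon_months,
                               y = .data$cum_percent,
                               colour = paste(.data$stage_category,
                                              .data$hb_class, sep = " / "))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Look-back horizon (months)",
                  y = "Cumulative % with a blood count",
                  colour = "Stage / Hb") +
    ggplot2::theme_minimal()
}
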