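# Calibration constants: published case-mix of the 1138-case secondary-care
# CRC cohort (2010-2016) by presentation pathway, and the effect sizes of
# its side/stage logistic models. Ages in years, Hb in g/l; spreads are
# normal-scale sd solved from the printed IQR (sd = IQR / 1.349).

PATHWAY_CASEMIX <- list(
  group_sizes = c(IDA = 171L, BCSP = 187L, SYMPTOMATIC = 780L),
  sex_ratio_mf = c(IDA = 1.1, BCSP = 1.5, SYMPTOMATIC = 1.3),
  age = list(IDA = c(median = 78, q1 = 71, q3 = 86),
             BCSP = c(median = 68, q1 = 64, q3 = 71),
             SYMPTOMATIC = c(median = 75, q1 = 64, q3 = 83)),
  hb = list(IDA = c(median = 89, q1 = 80, q3 = 100),
            BCSP = c(median = 138, q1 = 126, q3 = 147),
            SYMPTOMATIC = c(median = 124, q1 = 106, q3 = 140)),
  marginal_right = 0.39,
  marginal_early = 0.45
)

# Published odds ratios: side model (IDA, BCSP, female vs male) and stage
# model (IDA, BCSP vs symptomatic).
SIDE_OR <- c(IDA = 10.61, BCSP = 0.95, female = 1.94)
STAGE_OR <- c(IDA = 1.65, BCSP = 2.42)
HB_OR_PER_G_L <- 0.95

# IDA subgroup blood-count history split (done-normal / done-low / not-done)
# and per-class diagnosis-age summaries.
BC_CLASS_CASEMIX <- list(
  counts = c(done_normal = 80L, done_low = 38L, not_done = 53L),
  age = list(done_normal = c(median = 78, q1 = 75, q3 = 85),
             done_low = c(median = 83, q1 = 77, q3 = 88),
             not_done = c(median = 73, q1 = 66, q3 = 83))
)

# Survival calibration: median late-stage onset ages by blood-count status
# and the tested-group hazard multiplier.
ONSET_MEDIAN_TESTED <- 75
ONSET_MEDIAN_UNTESTED <- 70
TESTED_HAZARD_MULTIPLIER <- 0.66

iqr_sd <- function(q) unname((q["q3"] - q["q1"]) / (qnorm(0.75) - qnorm(0.25)))

# Truncated-normal sampler via inverse-CDF; vectorised over n.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Calibrated synthetic-cohort configuration
#'
#' Returns the default generative specification for [generate_cohort()],
#' calibrated so that simulated cohorts reproduce the case-mix of the
#' 1138-case reference cohort: pathway group sizes 171/187/780, per-pathway
#' sex ratios and age/Hb distributions (normal with location = printed
#' median and sd = IQR/1.349, truncated to plausible clinical ranges),
#' true side- and stage-model coefficients equal to the logs of the
#' published odds ratios, and intercepts solved numerically so that the
#' expected marginal proportions are 39% right-sided and 45% early-stage.
#'
#' @param group_sizes Named integer vector of cases per pathway
#'   (`IDA`, `BCSP`, `SYMPTOMATIC`).
#' @param side_or Named true odds ratios for the side model
#'   (`IDA`, `BCSP`, `female`); the female effect compares to male.
#' @param stage_or Named true odds ratios for the stage model (`IDA`,
#'   `BCSP`); the outcome is early stage, reference pathway symptomatic.
#' @param marginal_right,marginal_early Target marginal proportions used to
#'   solve the intercepts.
#' @return A `synth_config` list: group sizes, per-pathway female
#'   probabilities, age/Hb truncated-normal parameters, side/stage model
#'   coefficient vectors (log-odds scale, intercept included), and the
#'   blood-count history split for the IDA group.
#' @examples
#' cfg <- calibrated_config()
#' exp(cfg$side_model[["IDA"]])
#' @export
calibrated_config <- function(group_sizes = PATHWAY_CASEMIX$group_sizes,
                              side_or = SIDE_OR,
                              stage_or = STAGE_OR,
                              marginal_right = PATHWAY_CASEMIX$marginal_right,
                              marginal_early = PATHWAY_CASEMIX$marginal_early) {
  stopifnot(all(group_sizes >= 0), all(side_or > 0), all(stage_or > 0))
  p_female <- 1 / (1 + PATHWAY_CASEMIX$sex_ratio_mf)
  w <- group_sizes / sum(group_sizes)

  side_beta <- log(side_or)
  # expected right-sided proportion over the pathway x sex mix
  side_margin <- function(a) {
    lp_path <- c(IDA = side_beta[["IDA"]], BCSP = side_beta[["BCSP"]],
                 SYMPTOMATIC = 0)
    p <- vapply(PATHWAYS, function(g) {
      (1 - p_female[[g]]) * plogis(a + lp_path[[g]]) +
        p_female[[g]] * plogis(a + lp_path[[g]] + side_beta[["female"]])
    }, numeric(1))
    sum(w * p)
  }
  a_side <- uniroot(function(a) side_margin(a) - marginal_right,
                    c(-20, 20), tol = 1e-10)$root

  stage_beta <- log(stage_or)
  stage_margin <- function(a) {
    lp <- c(IDA = stage_beta[["IDA"]], BCSP = stage_beta[["BCSP"]],
            SYMPTOMATIC = 0)
    sum(w * plogis(a + lp[PATHWAYS]))
  }
  a_stage <- uniroot(function(a) stage_margin(a) - marginal_early,
                     c(-20, 20), tol = 1e-10)$root

  dists <- function(tab, lower, upper) {
    lapply(tab, function(q) {
      c(mean = unname(q[["median"]]), sd = iqr_sd(q),
        lower = lower, upper = upper)
    })
  }

  structure(list(
    group_sizes = group_sizes,
    p_female = p_female,
    age_dist = dists(PATHWAY_CASEMIX$age, 18, 105),
    hb_dist = dists(PATHWAY_CASEMIX$hb, 40, 180),
    side_model = c(intercept = a_side, side_beta),
    stage_model = c(intercept = a_stage, stage_beta),
    bc_split = BC_CLASS_CASEMIX$counts / sum(BC_CLASS_CASEMIX$counts),
    bc_window_months = 24,
    hb_threshold = 110
  ), class = "synth_config")
}

#' Calibrated Weibull proportional-hazards truth
#'
#' Solves the true survival parameters (shape `k`, scale `sigma`, log
#' hazard ratio `beta`) of the current-status generative model from three
#' calibration statements: the median age at late-stage onset is 75 years
#' in subjects with a prior blood count (tested, `x = 1`) and 70 years in
#' those without (`x = 0`), and the tested-group hazard multiplier is
#' `exp(beta) = 0.66`. Under the Weibull proportional-hazards model
#' `S(t | x) = exp(-(t / sigma)^k * exp(beta * x))` the median for group `x`
#' is `sigma * (log(2) * exp(-beta * x))^(1/k)`, which inverts in closed
#' form: `k = log(1 / 0.66) / log(75 / 70)` and
#' `sigma = 70 / log(2)^(1/k)`.
#'
#' Also carries the diagnosis-age (observation-age) distributions per
#' covariate group: truncated normals on \[40, 100\] matched to the
#' IDA-subgroup descriptives, pooling the two tested classes.
#'
#' @param median_tested,median_untested Median onset ages (years).
#' @param hr_tested Tested-group hazard multiplier `exp(beta)`.
#' @return A `survival_truth` list with `k`, `sigma`, `beta` and
#'   `diag_age`, a list of truncated-normal parameters for the tested and
#'   untested observation-age distributions.
#' @examples
#' tr <- calibrated_truth()
#' tr$sigma * (log(2) * exp(-tr$beta))^(1 / tr$k)  # 75
#' @export
calibrated_truth <- function(median_tested = ONSET_MEDIAN_TESTED,
                             median_untested = ONSET_MEDIAN_UNTESTED,
                             hr_tested = TESTED_HAZARD_MULTIPLIER) {
  stopifnot(median_tested > median_untested, median_untested > 0,
            hr_tested > 0, hr_tested < 1)
  beta <- log(hr_tested)
  k <- log(1 / hr_tested) / log(median_tested / median_untested)
  sigma <- median_untested / log(2)^(1 / k)

  # observation-age distributions: tested pools the two done classes
  n_dn <- BC_CLASS_CASEMIX$counts[["done_normal"]]
  n_dl <- BC_CLASS_CASEMIX$counts[["done_low"]]
  m <- c(BC_CLASS_CASEMIX$age$done_normal[["median"]], BC_CLASS_CASEMIX$age$done_low[["median"]])
  s <- c(iqr_sd(BC_CLASS_CASEMIX$age$done_normal), iqr_sd(BC_CLASS_CASEMIX$age$done_low))
  wts <- c(n_dn, n_dl) / (n_dn + n_dl)
  mean_tested <- sum(wts * m)
  sd_tested <- sqrt(sum(wts * (s^2 + (m - mean_tested)^2)))

  structure(list(
    k = k, sigma = sigma, beta = beta,
    diag_age = list(
      tested = c(mean = mean_tested, sd = sd_tested, lower = 40, upper = 100),
      untested = c(mean = BC_CLASS_CASEMIX$age$not_done[["median"]],
                   sd = iqr_sd(BC_CLASS_CASEMIX$age$not_done),
                   lower = 40, upper = 100)
    )
  ), class = "survival_truth")
}

#' Generate a synthetic cohort
#'
#' Draws a full patient-level cohort from a [calibrated_config()]
#' specification: exact group sizes per pathway; sex from the per-pathway
#' female probability; age and Hb from per-pathway truncated normals;
#' tumour side from the true side model given pathway and sex; stage from
#' the true stage model given pathway (side and stage independent given
#' pathway and sex); and, for IDA cases, a prior blood-count history drawn
#' from the configured done-normal/done-low/not-done split, with the count
#' placed uniformly inside the 2-year comparison window and its Hb drawn
#' below or above the anaemia threshold as the class requires.
#'
#' @param config A `synth_config` list from [calibrated_config()].
#' @param seed Integer seed; output is fully deterministic given
#'   `(config, seed)`.
#' @return A cohort tibble in the [read_cohort()] schema with derived
#'   `stage_category` and `side` columns, plus a `true_side`/`true_stage`
#'   consistency: `side` and `stage_category` are the simulated outcomes.
#' @examples
#' cohort <- generate_cohort(calibrated_config(), seed = 1)
#' nrow(cohort)  # 1138
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "synth_config"))
  if (any(config$group_sizes < 0)) stop("group sizes must be >= 0")
  set.seed(as.integer(seed))

  rows <- lapply(PATHWAYS, function(g) {
    n <- config$group_sizes[[g]]
    if (n == 0L) return(NULL)
    female <- rbinom(n, 1, config$p_female[[g]])
    ad <- config$age_dist[[g]]
    hd <- config$hb_dist[[g]]
    age <- rtruncnorm(n, ad[["mean"]], ad[["sd"]], ad[["lower"]], ad[["upper"]])
    hb <- rtruncnorm(n, hd[["mean"]], hd[["sd"]], hd[["lower"]], hd[["upper"]])

    sb <- config$side_model
    lp_side <- sb[["intercept"]] +
      (g == "IDA") * sb[["IDA"]] + (g == "BCSP") * sb[["BCSP"]] +
      female * sb[["female"]]
    right <- rbinom(n, 1, plogis(lp_side))

    tb <- config$stage_model
    lp_stage <- tb[["intercept"]] +
      (g == "IDA") * tb[["IDA"]] + (g == "BCSP") * tb[["BCSP"]]
    early <- rbinom(n, 1, plogis(lp_stage))
    # early stage drawn first, then split uniformly into I/II (III/IV)
    stage <- ifelse(early == 1,
                    sample(c("I", "II"), n, replace = TRUE),
                    sample(c("III", "IV"), n, replace = TRUE))

    prior_bc_months <- rep(NA_real_, n)
    prior_bc_hb <- rep(NA_real_, n)
    if (g == "IDA") {
      cls <- sample(names(config$bc_split), n, replace = TRUE,
                    prob = config$bc_split)
      done <- cls != "not_done"
      prior_bc_months[done] <- runif(sum(done), 0, config$bc_window_months)
      low <- cls == "done_low"
      # keep 0.51 below the threshold so rounding to integer g/l cannot
      # promote a low count to normal
      prior_bc_hb[low] <- rtruncnorm(sum(low), 95, 12, 40,
                                     config$hb_threshold - 0.51)
      normal <- cls == "done_normal"
      prior_bc_hb[normal] <- rtruncnorm(sum(normal), 122, 12,
                                        config$hb_threshold, 170)
    }

    tibble::tibble(
      age = round(age, 1), sex = ifelse(female == 1, "F", "M"),
      hb_g_l = round(hb, 0), pathway = g, tnm_stage = stage,
      locations = ifelse(right == 1, "PROX", "DIST"),
      prior_bc_months = round(prior_bc_months, 2),
      prior_bc_hb_g_l = round(prior_bc_hb, 0),
      exclusion = NA_character_
    )
  })

  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
                       id = sprintf("S%04d", seq_len(nrow(out))),
                       .before = 1)
  add_derived_columns(out)
}

#' Generate a synthetic current-status dataset
#'
#' Simulates current-status observations of age at late-stage onset under
#' the Weibull proportional-hazards model. For each subject: the tested
#' covariate `x ~ Bernoulli(p_tested)`; the latent onset age
#' `T = sigma * (E * exp(-beta * x))^(1/k)` with `E ~ Exp(1)` (so the
#' hazard is multiplied by `exp(beta * x)`); the observation (diagnosis)
#' age `C` is drawn independently of `T` from the covariate group's
#' truncated-normal diagnosis-age distribution; the record keeps only
#' `(C, 1[T <= C], x)`.
#'
#' @param truth A `survival_truth` list from [calibrated_truth()].
#' @param n Number of subjects.
#' @param p_tested Probability that a subject has a prior blood count.
#' @param seed Integer seed.
#' @return Tibble with columns `age` (observation age `C`), `late`
#'   (logical, late stage at diagnosis, i.e. onset already occurred) and
#'   `tested` (0/1).
#' @export
generate_current_status <- function(truth, n, p_tested, seed) {
  stopifnot(inherits(truth, "survival_truth"), n > 0)
  if (p_tested < 0 || p_tested > 1) {
    stop("p_tested must be a probability in [0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  x <- rbinom(n, 1, p_tested)
  e <- -log(runif(n))
  t_onset <- truth$sigma * (e * exp(-truth$beta * x))^(1 / truth$k)
  ga <- ifelse(x == 1, "tested", "untested")
  age <- numeric(n)
  for (g in c("tested", "untested")) {
    idx <- ga == g
    d <- truth$diag_age[[g]]
    age[idx] <- rtruncnorm(sum(idx), d[["mean"]], d[["sd"]],
                           d[["lower"]], d[["upper"]])
  }
  tibble::tibble(age = age, late = t_onset <= age, tested = x)
}
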