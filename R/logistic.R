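logistic_loglik <- function(beta, x, y) {
  eta <- drop(x %*% beta)
  # numerically stable Bernoulli log-likelihood:
  # sum y*eta - log(1 + exp(eta))
  sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
}

#' Binary logistic regression by iteratively reweighted least squares
#'
#' Maximises the Bernoulli log-likelihood by Newton--Raphson in its IRLS
#' form. The coefficient covariance is the inverse observed information at
#' the optimum, giving Wald standard errors, odds ratios with 95%
#' confidence intervals and two-sided p-values.
#'
#' Quasi-complete separation is flagged when any coefficient exceeds 15 in
#' absolute value on the logit scale during iteration, and reported as an
#' error naming the offending predictor.
#'
#' @param design Numeric design matrix including the intercept column;
#'   column names label the coefficients.
#' @param outcome Binary (0/1 or logical) response vector, one per design
#'   row.
#' @param max_iter Maximum IRLS iterations (default 50).
#' @param tol Convergence tolerance on the log-likelihood change (default
#'   1e-10).
#' @return A `logistic_fit` object: coefficients, covariance matrix,
#'   standard errors, log-likelihood, iteration count, convergence flag,
#'   fitted probabilities and the data dimensions. Use [generics::tidy()]
#'   for the odds-ratio table or [wald_or_table()] for the formatted
#'   version.
#' @examples
#' x <- cbind(intercept = 1, group = rep(c(0, 1), each = 50))
#' y <- c(rep(c(1, 0), c(10, 40)), rep(c(1, 0), c(20, 30)))
#' fit <- fit_logistic(x, y)
#' exp(fit$coefficients["group"])  # cross-product odds ratio 3
#' @export
fit_logistic <- function(design, outcome, max_iter = 50, tol = 1e-10) {
  x <- as.matrix(design)
  y <- as.numeric(outcome)
  if (nrow(x) != length(y)) {
    stop("design rows and outcome length differ", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("outcome is constant; the model is not identifiable", call. = FALSE)
  }
  if (is.null(colnames(x))) {
    colnames(x) <- c("intercept", paste0("x", seq_len(ncol(x) - 1)))
  }
  if (qr(x)$rank < ncol(x)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }

  beta <- rep(0, ncol(x))
  ll_old <- logistic_loglik(beta, x, y)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    xtw <- t(x * w)
    beta <- drop(solve(xtw %*% x, xtw %*% z))
    if (any(abs(beta) > 15)) {
      worst <- colnames(x)[which.max(abs(beta))]
      stop("apparent separation: coefficient for '", worst,
           "' diverged during IRLS", call. = FALSE)
    }
    ll_new <- logistic_loglik(beta, x, y)
    if (abs(ll_new - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  mu <- plogis(drop(x %*% beta))
  info <- t(x * (mu * (1 - mu))) %*% x
  vcov <- solve(info)
  dimnames(vcov) <- list(colnames(x), colnames(x))
  se <- sqrt(diag(vcov))
  names(beta) <- colnames(x)

  structure(list(
    coefficients = beta, vcov = vcov, se = se,
    log_likelihood = ll_old, iterations = iter, converged = converged,
    fitted = mu, n = length(y), outcome = y, design = x
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit (IRLS):", x$n, "observations,",
      length(x$coefficients), "coefficients\n")
  cat("log-likelihood:", format(x$log_likelihood), "| iterations:",
      x$iterations, "| converged:", x$converged, "\n")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a logistic fit into an odds-ratio table
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return Tibble with one row per term: `term`, `estimate` (log-odds),
#'   `std.error`, `statistic` (Wald z), `p.value`, `odds.ratio`,
#'   `conf.low`, `conf.high` (95% Wald interval on the odds-ratio scale).
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) {
  z <- x$coefficients / x$se
  p <- 2 * pnorm(-abs(z))
  crit <- qnorm(0.975)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(p),
    odds.ratio = exp(unname(x$coefficients)),
    conf.low = exp(unname(x$coefficients - crit * x$se)),
    conf.high = exp(unname(x$coefficients + crit * x$se))
  )
}

#' One-line model summary of a logistic fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return Tibble with `n`, `df`, `logLik`, `AIC`, `iterations`,
#'   `converged`.
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  k <- length(x$coefficients)
  tibble::tibble(
    n = x$n, df = k, logLik = x$log_likelihood,
    AIC = 2 * k - 2 * x$log_likelihood,
    iterations = x$iterations, converged = x$converged
  )
}

#' Formatted Wald odds-ratio table
#'
#' Formats a converged fit as an odds-ratio table with 95% confidence
#' intervals rounded to two decimals, and a display p-value where values
#' below 1e-4 print as `"< 0.0001"`. The intercept row is dropped: the
#' table reports predictor effects.
#'
#' @param fit A converged `logistic_fit`.
#' @return Tibble with `term`, `or`, `conf.low`, `conf.high`,
#'   `or_ci` (formatted string), `p.value`, `p_display`.
#' @export
wald_or_table <- function(fit) {
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (any(fit$se <= 0 | !is.finite(fit$se))) {
    stop("degenerate standard error", call. = FALSE)
  }
  tidy(fit) |>
    dplyr::filter(.data$term != "intercept") |>
    dplyr::transmute(
      term = .data$term,
      or = round(.data$odds.ratio, 2),
      conf.low = round(.data$conf.low, 2),
      conf.high = round(.data$conf.high, 2),
      or_ci = sprintf("%.2f (%.2f-%.2f)", .data$odds.ratio, .data$conf.low,
                      .data$conf.high),
      p.value = .data$p.value,
      p_display = ifelse(.data$p.value < 1e-4, "< 0.0001",
                         sprintf("%.2g", .data$p.value))
    )
}

model_design <- function(cohort, spec) {
  n <- nrow(cohort)
  outcome <- switch(spec$outcome,
    side_right = as.numeric(cohort$side == "right"),
    stage_early = as.numeric(cohort$stage_category == "early")
  )
  cols <- list(intercept = rep(1, n))
  for (p in spec$predictors) {
    if (p == "pathway") {
      missing_path <- setdiff(PATHWAYS, unique(cohort$pathway))
      if (length(missing_path) > 0L) {
        stop("pathway absent from cohort: ",
             paste(missing_path, collapse = ", "), call. = FALSE)
      }
      cols$IDA <- as.numeric(cohort$pathway == "IDA")
      cols$BCSP <- as.numeric(cohort$pathway == "BCSP")
    } else if (p == "sex") {
      cols$female <- as.numeric(cohort$sex == "F")
    } else if (p == "hb") {
      cols$hb_g_l <- cohort$hb_g_l
    } else if (p == "age") {
      cols$age <- cohort$age
    } else {
      stop("unknown predictor: ", p, call. = FALSE)
    }
  }
  list(design = do.call(cbind, cols), outcome = outcome)
}

#' The four pathway/side/stage model specifications
#'
#' Model A: right-sided disease on pathway (IDA, BCSP vs symptomatic) and
#' sex (female vs male). Model B: right-sided disease on Hb (per g/l).
#' Model C: right-sided disease on age (per year). Model D: early-stage
#' disease on pathway. Reference categories: left side, late stage,
#' symptomatic pathway, male sex.
#'
#' @return Named list of model specifications.
#' @export
model_specs <- function() {
  list(
    A = list(outcome = "side_right", predictors = c("pathway", "sex")),
    B = list(outcome = "side_right", predictors = "hb"),
    C = list(outcome = "side_right", predictors = "age"),
    D = list(outcome = "stage_early", predictors = "pathway")
  )
}

#' Fit the four standard pathway models
#'
#' Fits models A--D (see [model_specs()]) to a cohort by IRLS.
#'
#' @param cohort Cohort tibble with derived `stage_category` and `side`.
#' @param models Character subset of `c("A","B","C","D")` (default all).
#' @return Named list of `logistic_fit` objects.
#' @examples
#' fits <- fit_pathway_models(generate_cohort(calibrated_config(), seed = 1))
#' wald_or_table(fits$A)
#' @export
fit_pathway_models <- function(cohort, models = c("A", "B", "C", "D")) {
  specs <- model_specs()[models]
  purrr::map(specs, function(spec) {
    md <- model_design(cohort, spec)
    fit_logistic(md$design, md$outcome)
  })
}

#' Simulate and fit the Hb dose-response model
#'
#' Generates `(hb, side)` pairs in which the log-odds of right-sided
#' disease is linear in Hb with slope `log(true_or_per_g_l)`, then fits
#' model B (side on Hb) by IRLS and returns the fit. Hb is drawn from the
#' pooled three-pathway mixture of the calibrated cohort configuration,
#' and the intercept is solved so the marginal right-sided proportion
#' matches the calibrated 39%.
#'
#' @param n Number of subjects (default 1138).
#' @param true_or_per_g_l True odds ratio per g/l of Hb (default 0.95,
#'   i.e. about a 5% increase in odds per g/l decrease).
#' @param seed Integer seed.
#' @param config Cohort configuration providing the Hb mixture (default
#'   [calibrated_config()]).
#' @return A `logistic_fit` for the simulated data.
#' @export
hb_effect_simulation <- function(n = 1138, true_or_per_g_l = HB_OR_PER_G_L,
                                 seed, config = calibrated_config()) {
  stopifnot(n > 0, true_or_per_g_l > 0)
  set.seed(as.integer(seed))
  w <- config$group_sizes / sum(config$group_sizes)
  grp <- sample(names(w), n, replace = TRUE, prob = w)
  hb <- numeric(n)
  for (g in names(w)) {
    idx <- grp == g
    hd <- config$hb_dist[[g]]
    hb[idx] <- rtruncnorm(sum(idx), hd[["mean"]], hd[["sd"]],
                          hd[["lower"]], hd[["upper"]])
  }
  slope <- log(true_or_per_g_l)
  intercept <- uniroot(
    function(a) mean(plogis(a + slope * hb)) - PATHWAY_CASEMIX$marginal_right,
    c(-40, 40), extendInt = "yes", tol = 1e-10
  )$root
  y <- rbinom(n, 1, plogis(intercept + slope * hb))
  fit_logistic(cbind(intercept = 1, hb_g_l = hb), y)
}

#' Hosmer--Lemeshow goodness-of-fit test
#'
#' Groups observations into `g` equal-size risk classes by fitted
#' probability (ties broken by stable sort order) and compares observed
#' with expected event counts via the chi-square statistic on `g - 2`
#' degrees of freedom.
#'
#' @param fit A `logistic_fit`.
#' @param g Number of risk groups (default 10).
#' @return Tibble with `statistic`, `df`, `p.value` and the per-group
#'   observed/expected table in attribute `groups`.
#' @export
hosmer_lemeshow <- function(fit, g = 10) {
  stopifnot(g >= 2, fit$n >= g)
  ord <- order(fit$fitted)  # stable in R
  idx <- ceiling(seq_along(ord) / (fit$n / g))
  idx <- pmin(idx, g)
  groups <- tibble::tibble(
    group = idx, fitted = fit$fitted[ord], y = fit$outcome[ord]
  ) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), observed = sum(.data$y),
                     expected = sum(.data$fitted), .groups = "drop")
  stat <- with(groups,
               sum((observed - expected)^2 /
                     (expected * (1 - expected / n))))
  out <- tibble::tibble(statistic = stat, df = g - 2,
                        p.value = pchisq(stat, g - 2, lower.tail = FALSE))
  attr(out, "groups") <- groups
  out
}
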