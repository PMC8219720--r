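test_that("a saturated 2x2 fit equals the cross-product odds ratio", {
  x <- cbind(intercept = 1, group = rep(c(0, 1), each = 50))
  y <- c(rep(c(1, 0), c(10, 40)), rep(c(1, 0), c(20, 30)))
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  expect_equal(exp(fit$coefficients[["group"]]),
               (20 * 40) / (30 * 10), tolerance = 1e-8)
  expect_equal(plogis(fit$coefficients[["intercept"]]), 10 / 50,
               tolerance = 1e-8)
})

test_that("IRLS reaches the likelihood optimum of an independent optimizer", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(40:120, 1)
    p <- sample(1:2, 1)
    x <- cbind(intercept = 1,
               matrix(rnorm(n * p), n, p,
                      dimnames = list(NULL, paste0("v", seq_len(p)))))
    beta_true <- rnorm(p + 1, 0, 0.8)
    y <- rbinom(n, 1, plogis(drop(x %*% beta_true)))
    if (length(unique(y)) < 2) next
    fit <- tryCatch(fit_logistic(x, y), error = function(e) NULL)
    if (is.null(fit)) next  # separation in a random draw
    ll_oracle <- optim_logistic_loglik(x, y)
    expect_lt(abs(fit$log_likelihood - ll_oracle), 1e-6)
  }
})

test_that("degenerate designs and outcomes are rejected", {
  x <- cbind(intercept = 1, a = rnorm(20))
  expect_error(fit_logistic(x, rep(1, 20)), "constant")
  expect_error(fit_logistic(cbind(x, a2 = x[, "a"]),
                            rep(c(0, 1), 10)), "rank deficient")
  expect_error(fit_logistic(x[1:10, ], rep(c(0, 1), 10)), "differ")
  # perfectly separated data are reported with the predictor's name
  sep <- cbind(intercept = 1, split = c(rep(0, 10), rep(1, 10)))
  expect_error(fit_logistic(sep, c(rep(0, 10), rep(1, 10))),
               "separation.*split")
})

test_that("shifting a continuous predictor only moves the intercept", {
  set.seed(21)
  x <- cbind(intercept = 1, z = rnorm(200, 50, 10))
  y <- rbinom(200, 1, plogis(-2 + 0.04 * x[, "z"]))
  f1 <- fit_logistic(x, y)
  x2 <- x
  x2[, "z"] <- x2[, "z"] - 50
  f2 <- fit_logistic(x2, y)
  expect_equal(f1$coefficients[["z"]], f2$coefficients[["z"]],
               tolerance = 1e-6)
  expect_equal(f2$coefficients[["intercept"]],
               f1$coefficients[["intercept"]] + 50 * f1$coefficients[["z"]],
               tolerance = 1e-6)
})

test_that("the odds-ratio table is internally consistent", {
  cohort <- generate_cohort(calibrated_config(), seed = 31)
  fit <- fit_pathway_models(cohort, "A")$A
  td <- tidy(fit)
  expect_equal(td$odds.ratio, exp(td$estimate))
  expect_true(all(td$conf.low < td$odds.ratio &
                    td$odds.ratio < td$conf.high))
  tab <- wald_or_table(fit)
  expect_false("intercept" %in% tab$term)
  expect_true(all(tab$conf.low <= tab$or & tab$or <= tab$conf.high))

  # null coefficient with SE 0.1: CI bounds are exp(+/- 1.96 * 0.1)
  null_fit <- fit
  null_fit$coefficients[] <- 0
  null_fit$se[] <- 0.1
  tab0 <- wald_or_table(null_fit)
  expect_equal(tab0$or, rep(1, nrow(tab0)))
  expect_equal(tab0$conf.low, rep(round(exp(-qnorm(0.975) * 0.1), 2),
                                  nrow(tab0)))
  expect_true(all(tidy(null_fit)$p.value > 0.99))

  degen <- fit
  degen$se[2] <- 0
  expect_error(wald_or_table(degen), "degenerate")
})

test_that("model specifications and reference coding follow the design", {
  cohort <- generate_cohort(calibrated_config(), seed = 41)
  fits <- fit_pathway_models(cohort)
  expect_named(fits, c("A", "B", "C", "D"))
  expect_named(fits$A$coefficients,
               c("intercept", "IDA", "BCSP", "female"))
  expect_named(fits$B$coefficients, c("intercept", "hb_g_l"))
  expect_named(fits$C$coefficients, c("intercept", "age"))
  expect_named(fits$D$coefficients, c("intercept", "IDA", "BCSP"))

  no_bcsp <- dplyr::filter(cohort, pathway != "BCSP")
  expect_error(fit_pathway_models(no_bcsp, "A"), "BCSP")
})

test_that("IRLS agrees with glm on the four standard models", {
  cohort <- generate_cohort(calibrated_config(), seed = 51)
  fits <- fit_pathway_models(cohort)
  glm_a <- glm(I(side == "right") ~ I(pathway == "IDA") +
                 I(pathway == "BCSP") + I(sex == "F"),
               family = binomial(), data = cohort)
  expect_equal(unname(fits$A$coefficients), unname(coef(glm_a)),
               tolerance = 1e-6)
  expect_equal(unname(fits$A$se),
               unname(sqrt(diag(vcov(glm_a)))), tolerance = 1e-5)
  glm_d <- glm(I(stage_category == "early") ~ I(pathway == "IDA") +
                 I(pathway == "BCSP"),
               family = binomial(), data = cohort)
  expect_equal(unname(fits$D$coefficients), unname(coef(glm_d)),
               tolerance = 1e-6)
})

test_that("the Hb simulation recovers null and flips under relabelling", {
  fit0 <- hb_effect_simulation(n = 4000, true_or_per_g_l = 1, seed = 61)
  expect_lt(abs(fit0$coefficients[["hb_g_l"]]), 0.005)

  fit <- hb_effect_simulation(n = 2000, true_or_per_g_l = 0.95, seed = 62)
  flipped <- fit_logistic(fit$design, 1 - fit$outcome)
  expect_equal(flipped$coefficients[["hb_g_l"]],
               -fit$coefficients[["hb_g_l"]], tolerance = 1e-6)
})

test_that("Wald interval coverage is nominal under the null", {
  set.seed(71)
  covered <- vapply(1:500, function(i) {
    x <- cbind(intercept = 1, group = rep(c(0, 1), each = 100))
    y <- rbinom(200, 1, 0.5)
    fit <- tryCatch(fit_logistic(x, y), error = function(e) NULL)
    if (is.null(fit)) return(NA)
    td <- tidy(fit)
    td$conf.low[2] <= 1 && 1 <= td$conf.high[2]
  }, logical(1))
  cov_rate <- mean(covered, na.rm = TRUE)
  expect_gte(cov_rate, 0.93)
  expect_lte(cov_rate, 0.97)
})

test_that("Hosmer-Lemeshow groups partition the data", {
  cohort <- generate_cohort(calibrated_config(), seed = 81)
  fit <- fit_pathway_models(cohort, "B")$B
  hl <- hosmer_lemeshow(fit, g = 10)
  groups <- attr(hl, "groups")
  expect_equal(nrow(groups), 10)
  expect_equal(sum(groups$n), fit$n)
  expect_equal(sum(groups$observed), sum(fit$outcome))
  expect_gt(hl$p.value, 0)
  expect_lt(hl$p.value, 1)
})
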