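test_that("onset intervals follow the current-status construction", {
  ida <- derive_fixture(make_cohort(2, pathway = "IDA", age = 80,
                                    prior_bc_months = c(10, NA),
                                    prior_bc_hb = c(120, NA)))
  ida$tnm_stage <- c("IV", "I")
  ida <- derive_fixture(ida)
  cs <- build_intervals(ida, horizon_years = 10)
  # late stage at 80 -> onset in [0, 80]; early -> [80, 90]
  expect_equal(cs$L, c(0, 80))
  expect_equal(cs$U, c(80, 90))
  expect_equal(cs$tested, c(1L, 0L))
  expect_error(build_intervals(ida, horizon_years = 0), "positive")

  broken <- ida
  broken$stage_category[1] <- NA
  expect_error(build_intervals(broken), broken$id[1])
})

test_that("log-likelihood matches closed forms and ignores x when beta=0", {
  # one late record with C = sigma, k = 1, beta = 0: exponential form
  d <- tibble::tibble(age = 74.4, late = TRUE, tested = 0L)
  ll <- cs_loglik(list(k = 1, sigma = 74.4, beta = 0), d)
  expect_equal(ll, log(1 - exp(-1)), tolerance = 1e-12)

  set.seed(31)
  d2 <- generate_current_status(calibrated_truth(), 50, 0.5, seed = 32)
  base <- cs_loglik(list(k = 3, sigma = 70, beta = 0), d2)
  shuffled <- d2
  shuffled$tested <- sample(d2$tested)
  expect_equal(cs_loglik(list(k = 3, sigma = 70, beta = 0), shuffled),
               base)
  expect_error(cs_loglik(list(k = -1, sigma = 70, beta = 0), d2))
})

test_that("log-likelihood agrees with a quadrature oracle", {
  set.seed(41)
  for (i in 1:100) {
    k <- runif(1, 1.05, 8)
    sigma <- runif(1, 40, 120)
    beta <- runif(1, -2, 2)
    n <- 20
    d <- tibble::tibble(
      age = runif(n, 30, 90),
      late = runif(n) < 0.5,
      tested = rbinom(n, 1, 0.5)
    )
    d <- d[order(d$late), ]
    ll <- cs_loglik(list(k = k, sigma = sigma, beta = beta), d,
                    horizon_years = 10)
    dd <- d
    dd$L <- ifelse(dd$late, 0, dd$age)
    dd$U <- ifelse(dd$late, dd$age, dd$age + 10)
    oracle <- sum(log(mapply(function(l, u, x) {
      quad_interval_prob(k, sigma, beta, l, u, x)
    }, dd$L, dd$U, dd$tested)))
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("degenerate interval probabilities return -Inf with a flag", {
  d <- tibble::tibble(age = 1e-4, late = TRUE, tested = 0L)
  ll <- cs_loglik(list(k = 8, sigma = 80, beta = 0), d)
  expect_identical(as.numeric(ll), -Inf)
  expect_true(attr(ll, "degenerate"))
})

test_that("the sampler is deterministic and respects the shape constraint", {
  d <- generate_current_status(calibrated_truth(), 120, 0.6, seed = 51)
  f1 <- fit_current_status(d, n_kept = 200, n_burn = 200, seed = 52)
  f2 <- fit_current_status(d, n_kept = 200, n_burn = 200, seed = 52)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$draws$k > 1))
  expect_true(all(f1$draws$sigma > 0))
  expect_equal(nrow(f1$draws), 4 * 200)
  # frozen proposals keep acceptance in a sane Metropolis range
  expect_true(all(f1$acceptance > 0.05 & f1$acceptance < 0.8))
  expect_error(fit_current_status(d[d$tested == 1, ], seed = 1),
               "covariate")
})

test_that("hazards of every kept draw increase with age", {
  d <- generate_current_status(calibrated_truth(), 120, 0.6, seed = 61)
  f <- fit_current_status(d, n_kept = 200, n_burn = 200, seed = 62)
  # Weibull hazard k/sigma (t/sigma)^(k-1) increases iff k > 1
  t <- c(50, 60, 70, 80)
  for (row in sample(nrow(f$draws), 25)) {
    dr <- f$draws[row, ]
    h <- dr$k / dr$sigma * (t / dr$sigma)^(dr$k - 1)
    expect_true(all(diff(h) > 0))
  }
})

test_that("posterior matches a brute-force grid on a small dataset", {
  d <- generate_current_status(calibrated_truth(), 60, 0.5, seed = 71)
  f <- fit_current_status(d, seed = 72)
  dd <- d
  dd$L <- ifelse(dd$late, 0, dd$age)
  dd$U <- ifelse(dd$late, dd$age, dd$age + 10)
  lp <- function(k, s, b) {
    cs_loglik(list(k = k, sigma = s, beta = b), dd) +
      dnorm(log(k - 1), 0, 1.5, log = TRUE) +
      dnorm(log(s), log(80), 1, log = TRUE) +
      dnorm(b, 0, 3, log = TRUE) - log(k - 1) - log(s)
  }
  kg <- seq(1.3, 35, length = 40)
  sg <- seq(50, 110, length = 40)
  bg <- seq(-3, 2, length = 40)
  arr <- array(0, c(40, 40, 40))
  for (i in seq_along(kg)) {
    for (j in seq_along(sg)) {
      arr[i, j, ] <- vapply(bg, function(b) lp(kg[i], sg[j], b), 0)
    }
  }
  arr <- exp(arr - max(arr))
  arr <- arr / sum(arr)
  grid_mean_b <- sum(apply(arr, 3, sum) * bg)
  grid_mean_s <- sum(apply(arr, 2, sum) * sg)
  expect_equal(mean(f$draws$beta), grid_mean_b, tolerance = 0.1)
  expect_equal(mean(f$draws$sigma), grid_mean_s, tolerance = 0.05)
})

test_that("uninformative data return the prior for beta", {
  # huge observation ages make every late interval [0, C] carry
  # probability ~1, so the likelihood is flat and the posterior for
  # beta must reproduce its N(0, 3^2) prior
  d <- tibble::tibble(age = rep(4000, 40), late = TRUE,
                      tested = rep(c(0L, 1L), 20))
  f <- fit_current_status(d, n_kept = 1500, n_burn = 1000, seed = 81)
  expect_lt(abs(mean(f$draws$beta)), 0.5)
  expect_gt(sd(f$draws$beta), 2.2)
  expect_lt(sd(f$draws$beta), 3.8)
})

test_that("posterior summaries transform draws correctly", {
  draws <- tibble::tibble(chain = 1, iter = 1:3,
                          k = c(6, 6, 6), sigma = c(74, 74, 74),
                          beta = c(0, 0, 0))
  f <- structure(list(draws = draws), class = "cs_fit")
  ps <- posterior_summary(f)
  expect_equal(ps$mean[ps$quantity == "effect_tested"], 1)
  expect_equal(ps$mean[ps$quantity == "hr_untested_vs_tested"], 1)

  # analytic median onset equals the numeric root of S(t | x) = 1/2
  k <- 5.2; sigma <- 81; beta <- -0.3
  m_analytic <- sigma * (log(2) * exp(-beta))^(1 / k)
  m_root <- uniroot(function(t) {
    exp(-(t / sigma)^k * exp(beta)) - 0.5
  }, c(1, 500), tol = 1e-12)$root
  expect_equal(m_analytic, m_root, tolerance = 1e-9)
  draws2 <- tibble::tibble(chain = 1, iter = 1, k = k, sigma = sigma,
                           beta = beta)
  f2 <- structure(list(draws = draws2), class = "cs_fit")
  ps2 <- posterior_summary(f2)
  expect_equal(ps2$median[ps2$quantity == "median_onset_tested"],
               m_analytic)
  expect_error(posterior_summary(structure(list(draws = draws[0, ]),
                                           class = "cs_fit")),
               "draws")
})

test_that("survival curves start at 1 and decrease", {
  d <- generate_current_status(calibrated_truth(), 150, 0.65, seed = 91)
  f <- fit_current_status(d, n_kept = 300, n_burn = 300, seed = 92)
  for (x in c(0, 1)) {
    cur <- survival_curves(f, x = x, age_grid = seq(0, 100, by = 5))
    expect_equal(cur$median[cur$age == 0], 1)
    expect_equal(cur$lower[cur$age == 0], 1)
    expect_true(all(diff(cur$median) <= 0))
    expect_true(all(diff(cur$lower) <= 0))
    expect_true(all(cur$lower <= cur$median & cur$median <= cur$upper))
  }
  expect_error(survival_curves(f, 0, c(-1, 5)), "non-negative")
  expect_error(survival_curves(f, 0, c(5, 5)), "increasing")
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("convergence diagnostics behave on known chains", {
  set.seed(101)
  iid <- tibble::tibble(
    chain = rep(1:4, each = 500), iter = rep(1:500, 4),
    theta = rnorm(2000)
  )
  diag <- convergence_diagnostics(iid)
  expect_lt(abs(diag$rhat - 1), 0.02)
  expect_gt(diag$ess, 1000)

  stuck <- tibble::tibble(chain = rep(1:2, each = 100),
                          iter = rep(1:100, 2),
                          theta = rep(c(0, 5), each = 100))
  expect_gt(convergence_diagnostics(stuck)$rhat, 3)

  one_chain <- iid[iid$chain == 1, ]
  expect_error(convergence_diagnostics(one_chain), "two chains")
})

test_that("effective sample size matches the AR(1) closed form", {
  set.seed(111)
  rho <- 0.5
  n <- 4000
  chains <- purrr::map(1:4, function(ch) {
    v <- numeric(n)
    v[1] <- rnorm(1)
    for (t in 2:n) v[t] <- rho * v[t - 1] + rnorm(1, 0, sqrt(1 - rho^2))
    tibble::tibble(chain = ch, iter = 1:n, theta = v)
  })
  diag <- convergence_diagnostics(dplyr::bind_rows(chains))
  expected <- 4 * n * (1 - rho) / (1 + rho)
  expect_lt(abs(diag$ess - expected) / expected, 0.2)
  # independent implementation agrees on the order of magnitude
  cd <- sum(vapply(chains, function(c)
    unname(coda::effectiveSize(c$theta)), numeric(1)))
  expect_lt(abs(diag$ess - cd) / cd, 0.35)
})
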