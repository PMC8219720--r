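# Fixtures are built in code: small deterministic cohorts carrying exact
# published counts, used for worked-example exactness checks.

make_cohort <- function(n, pathway = "SYMPTOMATIC", sex = "M", age = 70,
                        hb = 120, stage = "II", locations = "DIST",
                        prior_bc_months = NA_real_,
                        prior_bc_hb = NA_real_, exclusion = NA_character_,
                        id_prefix = "P") {
  tibble::tibble(
    id = sprintf("%s%04d", id_prefix, seq_len(n)),
    age = rep_len(age, n), sex = rep_len(sex, n),
    hb_g_l = rep_len(hb, n), pathway = rep_len(pathway, n),
    tnm_stage = rep_len(stage, n), locations = rep_len(locations, n),
    prior_bc_months = rep_len(prior_bc_months, n),
    prior_bc_hb_g_l = rep_len(prior_bc_hb, n),
    exclusion = rep_len(exclusion, n)
  )
}

derive_fixture <- function(data) {
  data$stage_category <- ifelse(data$tnm_stage %in% c("I", "II"),
                                "early", "late")
  data$side <- ifelse(grepl("PROX", data$locations), "right", "left")
  data
}

# one pathway group with exact early-stage and right-sided counts; early
# and right assigned independently from opposite ends so the margins are
# exact without fixing their joint distribution
pathway_group <- function(n, pathway, n_early, n_right, sex_m, id_prefix) {
  g <- make_cohort(n, pathway = pathway, id_prefix = id_prefix)
  g$tnm_stage <- rep(c("II", "III"), c(n_early, n - n_early))
  g$locations <- rev(rep(c("PROX", "DIST"), c(n_right, n - n_right)))
  g$sex <- rep(c("M", "F"), c(sex_m, n - sex_m))
  derive_fixture(g)
}

# the 1138-case cohort with the published per-pathway stage/side counts
casemix_cohort <- function() {
  dplyr::bind_rows(
    pathway_group(171, "IDA", n_early = 89, n_right = 141, sex_m = 90,
                  id_prefix = "I"),
    pathway_group(187, "BCSP", n_early = 115, n_right = 56, sex_m = 112,
                  id_prefix = "B"),
    pathway_group(780, "SYMPTOMATIC", n_early = 310, n_right = 245,
                  sex_m = 441, id_prefix = "S")
  )
}

# the IDA subgroup with the published blood-count class split 80/38/53 and
# per-class early/right counts
ida_subgroup_cohort <- function() {
  cls <- function(n, n_early, n_right, months, hb, prefix) {
    g <- make_cohort(n, pathway = "IDA", prior_bc_months = months,
                     prior_bc_hb = hb, id_prefix = prefix)
    g$tnm_stage <- rep(c("I", "IV"), c(n_early, n - n_early))
    g$locations <- rev(rep(c("PROX", "DIST"), c(n_right, n - n_right)))
    derive_fixture(g)
  }
  dplyr::bind_rows(
    cls(80, 44, 65, months = 10, hb = 120, prefix = "N"),
    cls(38, 20, 30, months = 10, hb = 95, prefix = "L"),
    cls(53, 25, 46, months = NA_real_, hb = NA_real_, prefix = "X")
  )
}

# 1258 records: the retained 1138 plus the five exclusion categories at
# their published counts (17/7/35/27/34)
exclusion_cohort <- function() {
  excl_counts <- c(incomplete = 17, metachronous_duplicate = 7,
                   other_neoplasm = 35, non_incident = 27,
                   incidental_or_followup = 34)
  flagged <- purrr::imap(excl_counts, function(n, cat) {
    make_cohort(n, exclusion = cat,
                id_prefix = paste0("E", substr(cat, 1, 2)))
  })
  dplyr::bind_rows(c(list(derive_fixture(casemix_cohort())), flagged))
}

# independent logistic log-likelihood maximizer: BFGS with analytic
# gradient, started at zero (oracle for the IRLS fitter)
optim_logistic_loglik <- function(design, outcome) {
  x <- as.matrix(design)
  y <- as.numeric(outcome)
  nll <- function(b) {
    eta <- drop(x %*% b)
    -sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  }
  grad <- function(b) -drop(t(x) %*% (y - plogis(drop(x %*% b))))
  o <- optim(rep(0, ncol(x)), nll, grad, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))
  -o$value
}

# quadrature oracle for an interval probability under the Weibull-PH model
quad_interval_prob <- function(k, sigma, beta, l, u, x) {
  dens <- function(t) {
    ee <- exp(beta * x)
    (k / sigma) * (t / sigma)^(k - 1) * ee *
      exp(-(t / sigma)^k * ee)
  }
  integrate(dens, l, u, rel.tol = 1e-12, abs.tol = 0)$value
}
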