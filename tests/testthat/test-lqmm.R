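test_that("exact marginal likelihood matches adaptive-quadrature integration", {
  set.seed(16)
  y <- rnorm(60, 10, 1.4)
  X <- cbind(intercept = rep(1, 60))
  cl <- rep(1:3, each = 20)
  for (par in list(c(7.7, 0.15, 0.5), c(9, 0.5, 0.2), c(10, 1, 1))) {
    expect_equal(
      lqmm_loglik(par[1], par[2], par[3], y, X, cl, 0.05),
      lqmm_loglik_oracle(par[1], par[2], par[3], y, X, cl, 0.05),
      tolerance = 1e-7)
  }
  # psi = 0 reduces to plain ALD quantile regression
  expect_equal(lqmm_loglik(9, 0.3, 0, y, X, cl, 0.05),
               sum(hbref:::ald_logdens(y - 9, 0.3, 0.05)))
})

test_that("ICC follows the ALD variance decomposition in closed form", {
  mk <- function(psi2, sigma, p = 0.05) {
    structure(list(psi2 = psi2, sigma = sigma, p = p,
                   sigma_e2 = hbref:::ald_variance(sigma, p),
                   icc_between = psi2 / (psi2 + hbref:::ald_variance(sigma, p)),
                   icc_within = 1 - psi2 / (psi2 + hbref:::ald_variance(sigma, p)),
                   converged = TRUE),
              class = "quantile_mixed_fit")
  }
  expect_equal(unname(icc_from_fit(mk(0, 0.2))["between"]), 0)
  sig_e2 <- hbref:::ald_variance(0.2, 0.05)
  expect_equal(unname(icc_from_fit(mk(sig_e2, 0.2))["between"]), 0.5)
  # hand-set values against an independent evaluation of the formula
  p <- 0.05; sigma <- 0.31; psi2 <- 0.12
  v <- sigma^2 * (1 - 2 * p + 2 * p^2) / (p^2 * (1 - p)^2)
  expect_equal(unname(icc_from_fit(mk(psi2, sigma))["between"]),
               psi2 / (psi2 + v))
  expect_equal(sum(icc_from_fit(mk(psi2, sigma))), 1)
})

test_that("fit is location equivariant: shifting Hb shifts only the intercept", {
  sc <- synth_config("child", n_surveys = 4, n_per_survey = 80,
                     frac_unhealthy = 0, tau_between = 0.4, seed = 17)
  g <- generate_cohort(sc)
  f1 <- fit_lqmm(g$records, p = 0.05, covariates = "age")
  shifted <- g$records
  shifted$hb <- shifted$hb + 2
  f2 <- fit_lqmm(shifted, p = 0.05, covariates = "age")
  expect_equal(f2$beta[["intercept"]], f1$beta[["intercept"]] + 2,
               tolerance = 1e-3)
  expect_equal(f2$psi2, f1$psi2, tolerance = 1e-2)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-2)
  expect_equal(f2$icc_between, f1$icc_between, tolerance = 1e-3)
})

test_that("planted child age slope at the fifth percentile is recovered", {
  # location-shift generator: the per-year slope holds at every quantile
  slopes <- vapply(1:5, function(r) {
    sc <- synth_config("child", n_surveys = 8, n_per_survey = 400,
                       frac_unhealthy = 0, tau_between = 0.3,
                       age_slope_p5 = 0.19, noise = "ald", seed = 300 + r)
    g <- generate_cohort(sc)
    fit_lqmm(g$records, p = 0.05, covariates = "age")$beta[["age"]]
  }, numeric(1))
  expect_equal(mean(slopes), 0.19, tolerance = 0.05 / 0.19)
})

test_that("singular designs are rejected", {
  recs <- make_records(100, group = "woman", sex = "female")
  recs$survey_id <- rep(c("A", "B"), 50)
  recs$hb <- rnorm(100, 13, 1)
  recs$age <- 30          # constant age: no information for the slope
  expect_error(fit_lqmm(recs, covariates = c("age")), "singular")
})

test_that("likelihood-ratio statistic for the random intercept is nonnegative", {
  sc <- synth_config("child", n_surveys = 6, n_per_survey = 100,
                     frac_unhealthy = 0, tau_between = 0.8, seed = 18)
  g <- generate_cohort(sc)
  lr <- lr_test_random_intercept(g$records, covariates = "age")
  expect_gte(lr$statistic, 0)
  expect_lt(lr$p_value, 0.01)   # strong planted survey effect
})
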