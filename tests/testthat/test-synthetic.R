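test_that("the generator is deterministic under its seed", {
  sc <- synth_config("child", n_surveys = 4, n_per_survey = c(100, 200),
                     seed = 40)
  a <- generate_cohort(sc)
  b <- generate_cohort(sc)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  sa <- generate_stfr(sc, a$records)
  sb <- generate_stfr(sc, b$records)
  expect_identical(sa$stfr, sb$stfr)
  expect_identical(sa$hb, sb$hb)
})

test_that("healthy-component Hb moments match the configuration", {
  sc <- synth_config("child", n_surveys = 10, n_per_survey = 10000,
                     tau_between = 0, age_slope_p5 = 0, frac_unhealthy = 0,
                     p_has_altitude = 0, seed = 41)
  g <- generate_cohort(sc)
  expect_equal(mean(g$records$hb), sc$mu_hb, tolerance = 0.01 / sc$mu_hb)
  expect_equal(sd(g$records$hb), sc$sigma_within,
               tolerance = 0.02 / sc$sigma_within)
})

test_that("analytic healthy-component P5 matches a large empirical draw", {
  # no between-survey spread: marginal is the pure age-by-noise convolution
  sc0 <- synth_config("child", n_surveys = 2, n_per_survey = 500000,
                      frac_unhealthy = 0, tau_between = 0,
                      p_has_altitude = 0, seed = 42)
  g0 <- generate_cohort(sc0)   # 10^6 healthy records, no adjustment increments
  p5_0 <- g0$truth$value[g0$truth$param == "true_p5_marginal"]
  expect_lt(abs(empirical_quantile(g0$records$hb, 0.05) - p5_0), 0.01)

  # with between-survey spread the empirical marginal converges to the
  # analytic one as the number of surveys grows, so integrate over many
  sc <- synth_config("child", n_surveys = 2000, n_per_survey = 500,
                     frac_unhealthy = 0, p_has_altitude = 0, seed = 42)
  g <- generate_cohort(sc)
  p5_t <- g$truth$value[g$truth$param == "true_p5_marginal"]
  expect_lt(abs(empirical_quantile(g$records$hb, 0.05) - p5_t), 0.01)
})

test_that("planted healthy flags coincide with the biomarker filter", {
  sc <- synth_config("woman", n_surveys = 6, n_per_survey = 500, seed = 43)
  g <- generate_cohort(sc)
  expect_equal(is_healthy(g$records), g$records$healthy_true)
})

test_that("every planted parameter appears in the truth table", {
  sc <- synth_config("woman", n_surveys = 3, n_per_survey = 100, seed = 44)
  g <- generate_cohort(sc)
  expect_setequal(
    c("seed", "mu_hb", "sigma_within", "tau_between", "age_slope_p5",
      "frac_unhealthy", "unhealthy_hb_shift", "true_p5_survey",
      "true_p5_marginal", "true_icc_p5", "var_frac_between"),
    setdiff(g$truth$param, c("group_child", "n_surveys")))
  expect_equal(g$truth$value[g$truth$param == "seed"], 44)
})

test_that("adjustment recovers the pre-increment Hb distribution", {
  sc_flat <- synth_config("woman", n_surveys = 8, n_per_survey = 2000,
                          p_has_altitude = 0, p_has_smoking = 0, seed = 45)
  sc_incr <- synth_config("woman", n_surveys = 8, n_per_survey = 2000,
                          p_has_altitude = 1, p_has_smoking = 1, seed = 45)
  flat <- generate_cohort(sc_flat)$records
  incr <- adjust_hb_records(generate_cohort(sc_incr)$records)
  # same seed, increments added then removed: distributions agree closely
  expect_equal(mean(incr$hb), mean(flat$hb), tolerance = 0.02 / mean(flat$hb))
  expect_gt(mean(generate_cohort(sc_incr)$records$hb), mean(flat$hb))
})

test_that("zero-noise sTfR data reproduce the planted curve coefficients", {
  sc <- synth_config("child", noise_stfr = 0, seed = 46)
  dummy <- data.frame(stfr = NA_real_, hb = NA_real_)[rep(1, 4000), ]
  srec <- generate_stfr(sc, dummy)
  fit <- fit_rcs(srec$stfr, srec$hb, knots = sc$stfr_curve$knots)
  expect_equal(fit$coef, sc$stfr_curve$coef, tolerance = 1e-6)
  tr <- attr(srec, "stfr_truth")
  got <- find_inflections(fit)
  expect_equal(got$hb[2], tr$value[tr$param == "infl2_hb"], tolerance = 1e-6)
})

test_that("a curve without two inflections is rejected at construction", {
  expect_error(
    synth_config("child", stfr_d2 = c(-0.3, -0.2, -0.1)),
    "two inflection")
})
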