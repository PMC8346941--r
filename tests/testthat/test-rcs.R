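test_that("straight-line data yield zero basis coefficients and the slope", {
  set.seed(19)
  x <- runif(500, 1, 20)
  y <- 12 - 0.15 * x
  fit <- fit_rcs(x, y)
  expect_equal(unname(fit$coef[c("C1", "C2", "C3")]), rep(0, 3),
               tolerance = 1e-10)
  expect_equal(unname(fit$coef["x"]), -0.15, tolerance = 1e-10)
  expect_error(find_inflections(fit), "insufficient curvature")
})

test_that("fitted values match an independent natural-spline basis", {
  set.seed(20)
  x <- rlnorm(800, log(6), 0.5)
  y <- 11 - 0.5 * x + 0.02 * x^2 + rnorm(800, 0, 0.8)
  fit <- fit_rcs(x, y)
  # same function space via splines::ns; fitted values must agree
  B <- splines::ns(x, knots = fit$knots[2:4],
                   Boundary.knots = fit$knots[c(1, 5)])
  ref <- lm.fit(cbind(1, B), y)
  expect_equal(rcs_predict(fit, x), as.numeric(cbind(1, B) %*% ref$coefficients),
               tolerance = 1e-8)
})

test_that("fit is invariant to permuting the input order", {
  set.seed(21)
  x <- rlnorm(300, log(5), 0.4)
  y <- 11 - 0.3 * x + rnorm(300, 0, 0.5)
  f1 <- fit_rcs(x, y)
  idx <- sample(300)
  f2 <- fit_rcs(x[idx], y[idx])
  expect_equal(f1$knots, f2$knots)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-10)
})

test_that("analytic second derivative matches central finite differences", {
  set.seed(22)
  x <- rlnorm(400, log(6), 0.5)
  y <- 12 - 0.4 * x + 0.015 * x^2 + rnorm(400, 0, 0.6)
  fit <- fit_rcs(x, y)
  h <- 1e-4
  probes <- seq(fit$knots[1] + 0.05, fit$knots[5] - 0.05, length.out = 100)
  probes <- probes[vapply(probes, function(p)
    min(abs(p - fit$knots)) > 2 * h, logical(1))]
  fd <- (rcs_predict(fit, probes + h) - 2 * rcs_predict(fit, probes) +
           rcs_predict(fit, probes - h)) / h^2
  an <- second_derivative(fit, probes)
  expect_lt(max(abs(an - fd)), 1e-5 * max(abs(an)))
  # natural-spline constraint: exactly linear outside the boundary knots
  expect_identical(second_derivative(fit, fit$knots[1] - c(0.001, 1, 10)),
                   rep(0, 3))
  expect_identical(second_derivative(fit, fit$knots[5] + c(0.001, 1, 10)),
                   rep(0, 3))
})

test_that("planted inflection points are recovered exactly through a fit", {
  curve <- rcs_curve_from_d2(c(2, 4, 7, 11, 18), c(-0.4, 0.5, -0.3),
                             11.5, -0.08)
  # independent root oracle: interpolate f'' linearly between knot values
  k <- curve$knots
  v <- second_derivative(curve, k)
  v[c(1, 5)] <- 0
  roots_oracle <- unlist(lapply(1:4, function(i) {
    if (v[i] * v[i + 1] < 0)
      k[i] - v[i] * (k[i + 1] - k[i]) / (v[i + 1] - v[i])
  }))
  set.seed(23)
  x <- runif(2000, 2, 18)
  y <- rcs_predict(curve, x)            # noiseless
  fit <- fit_rcs(x, y, knots = k)
  got <- find_inflections(fit)
  expect_equal(got$stfr, sort(roots_oracle), tolerance = 1e-8)
  expect_equal(got$hb, rcs_predict(curve, sort(roots_oracle)),
               tolerance = 1e-8)
})

test_that("noisy sigmoid-like decline yields ordered inflections", {
  sc <- synth_config("child", seed = 24)
  set.seed(24)
  x <- qlnorm(runif(4000, 0, sc$stfr_qmax), sc$stfr_meanlog, sc$stfr_sdlog)
  y <- rcs_predict(sc$stfr_curve, x) + rnorm(4000, 0, 1)
  infl <- find_inflections(fit_rcs(x, y))
  expect_gte(nrow(infl), 2)
  expect_lt(infl$stfr[1], infl$stfr[2])
})

test_that("the fitted curve is scale equivariant in Hb", {
  set.seed(25)
  x <- rlnorm(600, log(6), 0.5)
  y <- 12 - 0.4 * x + 0.015 * x^2 + rnorm(600, 0, 0.6)
  f1 <- fit_rcs(x, y)
  f2 <- fit_rcs(x, 10 * y)
  probes <- seq(min(x), max(x), length.out = 50)
  expect_equal(rcs_predict(f2, probes), 10 * rcs_predict(f1, probes),
               tolerance = 1e-9)
  expect_equal(second_derivative(f2, probes),
               10 * second_derivative(f1, probes), tolerance = 1e-9)
})

test_that("degenerate sTfR spread is rejected", {
  expect_error(fit_rcs(rep(c(1, 1, 1, 2), 25), rnorm(100)), "degenerate")
})
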