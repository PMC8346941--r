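test_that("homogeneous surveys pool to the common value with no heterogeneity", {
  est <- make_estimates(c(10.2, 10.2), c(0.1, 0.1))
  pooled <- reml_pool(est)
  expect_equal(pooled$mu_hat, 10.2)
  expect_equal(pooled$tau2, 0)
  expect_equal(pooled$Q, 0)
  expect_equal(pooled$df, 1)
})

test_that("tau2 at zero recovers the closed-form inverse-variance mean", {
  # spread below sampling noise, so REML lands on the tau2 = 0 boundary
  y <- c(10.00, 10.02, 9.99, 10.01, 10.00)
  se <- c(0.12, 0.08, 0.15, 0.1, 0.09)
  pooled <- reml_pool(make_estimates(y, se))
  expect_equal(pooled$tau2, 0)
  w <- 1 / se^2
  expect_equal(pooled$mu_hat, sum(w * y) / sum(w), tolerance = 1e-12)
  expect_equal(pooled$se_mu, sqrt(1 / sum(w)), tolerance = 1e-12)
})

test_that("REML tau2 matches a grid search of the restricted likelihood", {
  set.seed(11)
  for (i in 1:5) {
    k <- sample(5:10, 1)
    y <- rnorm(k, 10, 0.5)
    se <- runif(k, 0.05, 0.3)
    pooled <- reml_pool(make_estimates(y, se))
    grid <- seq(0, 5, by = 1e-4)
    ll <- vapply(grid, hbref:::reml_loglik, numeric(1), y = y, v = se^2)
    expect_lt(abs(pooled$tau2 - grid[which.max(ll)]), 1e-3)
  }
})

test_that("REML pooling agrees with an independent meta-analysis implementation", {
  skip_if_not_installed("metafor")
  set.seed(12)
  y <- rnorm(8, 10, 0.6)
  se <- runif(8, 0.05, 0.25)
  pooled <- reml_pool(make_estimates(y, se))
  ref <- metafor::rma(yi = y, sei = se, method = "REML",
                      control = list(tol = 1e-10))
  expect_equal(pooled$tau2, unname(ref$tau2), tolerance = 1e-5)
  expect_equal(pooled$mu_hat, unname(as.numeric(ref$beta)), tolerance = 1e-7)
  expect_equal(pooled$Q, unname(ref$QE), tolerance = 1e-8)
})

test_that("Cochran Q follows the fixed-effect formula", {
  est <- make_estimates(c(0, 2), c(1, 1))
  q <- cochran_q(est)
  expect_equal(q$Q, 2)          # mu_FE = 1; (1)^2/1 + (1)^2/1
  expect_equal(q$df, 1)
  set.seed(13)
  y <- rnorm(6); se <- runif(6, 0.2, 1)
  q2 <- cochran_q(make_estimates(y, se))
  w <- 1 / se^2
  mu_fe <- sum(w * y) / sum(w)
  expect_equal(q2$Q, sum(w * (y - mu_fe)^2))
})

test_that("pooling is shift equivariant with invariant tau2 and Q", {
  set.seed(14)
  y <- rnorm(7, 10, 0.5); se <- runif(7, 0.05, 0.3)
  a <- reml_pool(make_estimates(y, se))
  b <- reml_pool(make_estimates(y + 1.7, se))
  expect_equal(b$mu_hat, a$mu_hat + 1.7, tolerance = 1e-7)
  expect_equal(b$tau2, a$tau2, tolerance = 1e-7)
  expect_equal(b$Q, a$Q)
})

test_that("forest table stacks per-survey rows plus a pooled row", {
  set.seed(15)
  est <- make_estimates(rnorm(22, 10, 0.4), runif(22, 0.05, 0.2))
  pooled <- reml_pool(est)
  tab <- forest_table(est, pooled)
  expect_equal(nrow(tab), 23)
  expect_equal(sum(tab$pooled), 1)
  expect_true(tab$pooled[23])
  by_est <- forest_table(est, pooled, sort_by = "estimate")
  expect_equal(by_est$estimate[1:22], sort(est$q_hat))
  expect_error(reml_pool(est[1, ]), "2 surveys")
})
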