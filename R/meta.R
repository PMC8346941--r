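# Random-effects pooling of survey quantile estimates by REML, with
# Cochran Q heterogeneity and a forest-table contract.

# Restricted log-likelihood of the random-effects model at a given tau2,
# profiling out mu. Used by the Fisher-scoring iteration and exposed for
# oracle-style verification.
reml_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

#' Pool survey estimates by REML random-effects meta-analysis
#'
#' Fits `y_i = mu + u_i + e_i` with `u_i ~ N(0, tau2)` and `e_i ~ N(0, v_i)`,
#' `v_i` the squared reported SEs. `tau2` maximizes the restricted likelihood
#' by Fisher scoring with nonnegativity projection (tolerance 1e-8, max 200
#' iterations, step-halving on non-improving steps); the pooled mean is the
#' inverse-variance weighted mean at the converged weights
#' `w_i = 1/(v_i + tau2)`, with `SE(mu) = (sum w_i)^{-1/2}` and a Wald
#' (normal-quantile) CI. Heterogeneity is reported as `tau = sqrt(tau2)`
#' (an SD on the measurement scale) and the fixed-effect Cochran Q.
#'
#' @param estimates data.frame with columns `q_hat` and `se_q` (as produced
#'   by [survey_quantiles()]), or columns `y` and `se`; at least 2 rows, all
#'   SEs positive.
#' @param level CI level (default 0.95).
#' @param tol convergence tolerance on tau2.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return object of class `meta_result`: `mu_hat`, `se_mu`, `ci_low`,
#'   `ci_high`, `tau2`, `tau`, `Q`, `df`, `Q_p`, `k`, `iterations`.
#' @export
reml_pool <- function(estimates, level = 0.95, tol = 1e-8, max_iter = 200) {
  y <- if ("q_hat" %in% names(estimates)) estimates$q_hat else estimates$y
  se <- if ("se_q" %in% names(estimates)) estimates$se_q else estimates$se
  k <- length(y)
  if (k < 2) stop("at least 2 surveys required to pool")
  if (any(!(se > 0))) stop("all standard errors must be positive")
  v <- se^2

  # DerSimonian-Laird start, then Fisher scoring on tau2 with projection.
  wfe <- 1 / v
  mu_fe <- sum(wfe * y) / sum(wfe)
  Q <- sum(wfe * (y - mu_fe)^2)
  c_dl <- sum(wfe) - sum(wfe^2) / sum(wfe)
  tau2 <- max(0, (Q - (k - 1)) / c_dl)

  converged <- FALSE
  iter <- 0
  ll <- reml_loglik(tau2, y, v)
  while (iter < max_iter) {
    iter <- iter + 1
    w <- 1 / (v + tau2)
    sw <- sum(w)
    mu <- sum(w * y) / sw
    # REML score and expected information in tau2 (mu profiled out).
    score <- 0.5 * (sum(w^2 * (y - mu)^2) - sum(w) + sum(w^2) / sw)
    info <- 0.5 * (sum(w^2) - 2 * sum(w^3) / sw + (sum(w^2) / sw)^2)
    if (info <= 0) break
    step <- score / info
    tau2_new <- max(0, tau2 + step)
    # Step-halve until the restricted likelihood does not decrease.
    ll_new <- reml_loglik(tau2_new, y, v)
    halvings <- 0
    while (ll_new < ll - 1e-12 && halvings < 30) {
      step <- step / 2
      tau2_new <- max(0, tau2 + step)
      ll_new <- reml_loglik(tau2_new, y, v)
      halvings <- halvings + 1
    }
    done <- abs(tau2_new - tau2) < tol
    tau2 <- tau2_new
    ll <- ll_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged) {
    # Boundary solutions oscillate at 0; accept if the projected score
    # condition holds (score <= 0 at tau2 = 0).
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    score <- 0.5 * (sum(w^2 * (y - mu)^2) - sum(w) + sum(w^2) / sum(w))
    if (tau2 == 0 && score <= 0) converged <- TRUE
  }
  if (!converged) stop("REML did not converge in ", max_iter, " iterations")

  w <- 1 / (v + tau2)
  mu_hat <- sum(w * y) / sum(w)
  se_mu <- sqrt(1 / sum(w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    mu_hat = mu_hat, se_mu = se_mu,
    ci_low = mu_hat - z * se_mu, ci_high = mu_hat + z * se_mu,
    tau2 = tau2, tau = sqrt(tau2),
    Q = Q, df = k - 1, Q_p = stats::pchisq(Q, k - 1, lower.tail = FALSE),
    k = k, level = level, iterations = iter,
    loglik = reml_loglik(tau2, y, v)
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Random-effects pool (REML), k = %d surveys\n", x$k))
  cat(sprintf("  pooled estimate: %.3f g/dL (%d%% CI %.3f-%.3f)\n",
              x$mu_hat, round(100 * x$level), x$ci_low, x$ci_high))
  cat(sprintf("  tau = %.4f g/dL (tau2 = %.5f)\n", x$tau, x$tau2))
  cat(sprintf("  Cochran Q = %.2f on %d df (p = %.3g)\n", x$Q, x$df, x$Q_p))
  invisible(x)
}

#' Cochran Q heterogeneity statistic
#'
#' `Q = sum (y_i - mu_FE)^2 / v_i` with `mu_FE` the fixed-effect
#' (inverse-variance) mean, on `k - 1` degrees of freedom. Fixed-effect
#' weights, the conventional choice.
#'
#' @inheritParams reml_pool
#' @return list with `Q`, `df`, `p_value`.
#' @export
cochran_q <- function(estimates) {
  y <- if ("q_hat" %in% names(estimates)) estimates$q_hat else estimates$y
  se <- if ("se_q" %in% names(estimates)) estimates$se_q else estimates$se
  if (length(y) < 2) stop("at least 2 surveys required")
  w <- 1 / se^2
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  list(Q = Q, df = length(y) - 1,
       p_value = stats::pchisq(Q, length(y) - 1, lower.tail = FALSE))
}

#' Forest table of per-survey and pooled estimates
#'
#' Per-survey rows plus a final pooled row, in the layout a forest plot
#' consumes.
#'
#' @param estimates per-survey estimates (from [survey_quantiles()]).
#' @param pooled the [reml_pool()] result from the same estimates.
#' @param sort_by `"survey_id"` or `"estimate"`.
#' @return data.frame with `label`, `estimate`, `ci_low`, `ci_high`, `n`,
#'   `pooled` flag.
#' @export
forest_table <- function(estimates, pooled, sort_by = c("survey_id", "estimate")) {
  sort_by <- match.arg(sort_by)
  stopifnot(inherits(pooled, "meta_result"), nrow(estimates) == pooled$k)
  rows <- data.frame(
    label = estimates$survey_id,
    estimate = estimates$q_hat,
    ci_low = estimates$ci_low,
    ci_high = estimates$ci_high,
    n = estimates$n,
    pooled = FALSE,
    stringsAsFactors = FALSE
  )
  rows <- rows[order(if (sort_by == "estimate") rows$estimate else rows$label), ]
  out <- rbind(rows, data.frame(
    label = "Pooled (REML)", estimate = pooled$mu_hat,
    ci_low = pooled$ci_low, ci_high = pooled$ci_high,
    n = sum(estimates$n), pooled = TRUE, stringsAsFactors = FALSE
  ))
  rownames(out) <- NULL
  out
}

#' Draw a forest plot
#'
#' Minimal base-graphics forest plot of a [forest_table()], with a reference
#' line (e.g. the WHO anemia cutoff).
#'
#' @param tab a [forest_table()] data.frame.
#' @param ref optional vertical reference value, g/dL.
#' @param xlab x-axis label.
#' @export
forest_plot <- function(tab, ref = NULL, xlab = "Hb fifth percentile (g/dL)") {
  k <- nrow(tab)
  ypos <- rev(seq_len(k))
  graphics::plot(tab$estimate, ypos, xlim = range(tab$ci_low, tab$ci_high, ref),
                 ylim = c(0.5, k + 0.5), pch = ifelse(tab$pooled, 18, 15),
                 cex = ifelse(tab$pooled, 1.6, 0.9), yaxt = "n",
                 xlab = xlab, ylab = "")
  graphics::segments(tab$ci_low, ypos, tab$ci_high, ypos)
  graphics::axis(2, at = ypos, labels = tab$label, las = 1, cex.axis = 0.7)
  if (!is.null(ref)) graphics::abline(v = ref, lty = 2)
  invisible(tab)
}
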