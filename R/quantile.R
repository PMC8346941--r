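# Survey-specific quantile estimation with Woodruff-type confidence
# intervals (Wald SE on the ECDF proportion, design effect 1, mapped back
# through the empirical quantile function).

#' Empirical quantile (inverse ECDF convention)
#'
#' Left-continuous inverse of the empirical CDF: the order statistic at rank
#' `ceiling(n * p)`. This is quantile "type 1" and makes the Woodruff mapping
#' self-consistent: the estimate and the CI endpoints come from the same
#' step function. Ties (e.g. Hb at 0.1 g/dL instrument resolution) are
#' handled by the same order-statistic rule, no jittering.
#'
#' @param x numeric vector (length at least 1).
#' @param p probability in (0, 1); vectorized.
#' @return quantile(s) of `x`.
#' @export
empirical_quantile <- function(x, p) {
  stopifnot(length(x) >= 1, all(p > 0), all(p < 1))
  xs <- sort(x)
  xs[pmin(length(xs), pmax(1L, ceiling(length(xs) * p)))]
}

#' Quantile estimate with Woodruff confidence interval
#'
#' Estimates the p-th quantile by [empirical_quantile()] and builds a CI by
#' inverting a Wald interval for the ECDF proportion: `SE(p_hat) =
#' sqrt(p (1 - p) / n)` at design effect 1 (simple random sampling), bounds
#' `p +/- z * SE` mapped through the empirical quantile function. The SE on
#' the measurement scale is reported as the CI half-width over z. When a
#' proportion bound leaves (0, 1) — n too small for the tail — the CI is
#' undefined and an error is raised rather than truncating.
#'
#' @param x numeric vector, length at least 2.
#' @param p probability in (0, 1).
#' @param level confidence level in (0, 1), default 0.95.
#' @param survey_id optional label carried into the output.
#' @return one-row data.frame with columns `survey_id`, `p`, `q_hat`,
#'   `se_q`, `ci_low`, `ci_high`, `n`.
#' @export
quantile_ci <- function(x, p, level = 0.95, survey_id = NA_character_) {
  stopifnot(length(x) >= 2, p > 0, p < 1, level > 0, level < 1)
  n <- length(x)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se_p <- sqrt(p * (1 - p) / n)
  lo_p <- p - z * se_p
  hi_p <- p + z * se_p
  if (lo_p <= 0 || hi_p >= 1) {
    stop(sprintf(
      "quantile CI undefined: proportion bound outside (0,1) at n=%d, p=%g",
      n, p))
  }
  q <- empirical_quantile(x, c(lo_p, p, hi_p))
  data.frame(
    survey_id = survey_id, p = p, q_hat = q[2],
    se_q = (q[3] - q[1]) / (2 * z),
    ci_low = q[1], ci_high = q[3], n = n,
    stringsAsFactors = FALSE
  )
}

#' Per-survey quantile estimates
#'
#' Applies [quantile_ci()] to the Hb values of each survey in a cohort.
#'
#' @param records record data.frame (typically the healthy cohort).
#' @param p probability (default 0.05, the lower reference limit).
#' @param level CI level.
#' @return data.frame of per-survey estimates, one row per survey, sorted by
#'   `survey_id`. This is the forest-plot data contract.
#' @export
survey_quantiles <- function(records, p = 0.05, level = 0.95) {
  stopifnot(nrow(records) > 0)
  ids <- sort(unique(records$survey_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    quantile_ci(records$hb[records$survey_id == id], p = p, level = level,
                survey_id = id)
  }))
  rownames(out) <- NULL
  out
}
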