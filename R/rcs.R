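# Restricted (natural) cubic spline fit of Hb on sTfR, analytic second
# derivative, and exact inflection-point location.

#' Restricted cubic spline basis
#'
#' Truncated-power natural-spline basis for 5 knots `t1 < ... < t5`:
#' besides intercept and linear terms, for `j = 1..3`
#' `C_j(x) = (x-t_j)+^3 - (x-t4)+^3 (t5-t_j)/(t5-t4) + (x-t5)+^3
#' (t4-t_j)/(t5-t4)`. The cubic and quadratic leading terms cancel beyond
#' the boundary knots, so the fitted function is linear outside `[t1, t5]`
#' and twice continuously differentiable everywhere.
#'
#' @param x evaluation points.
#' @param knots strictly increasing numeric vector of length 5.
#' @return matrix with columns `x, C1, C2, C3` (no intercept).
#' @export
rcs_basis <- function(x, knots) {
  stopifnot(length(knots) == 5, all(diff(knots) > 0))
  t4 <- knots[4]; t5 <- knots[5]
  pp <- function(u) pmax(u, 0)
  C <- sapply(1:3, function(j) {
    tj <- knots[j]
    pp(x - tj)^3 - pp(x - t4)^3 * (t5 - tj) / (t5 - t4) +
      pp(x - t5)^3 * (t4 - tj) / (t5 - t4)
  })
  cbind(x = x, matrix(C, ncol = 3, dimnames = list(NULL, paste0("C", 1:3))))
}

#' Fit a 5-knot restricted cubic spline of Hb on sTfR
#'
#' Least-squares fit of the natural cubic basis with knots at the standard
#' quantiles for 5 knots (0.05, 0.275, 0.50, 0.725, 0.95 of the sTfR
#' distribution) unless explicit knots are supplied.
#'
#' @param stfr predictor, mg/L, positive, length at least 50.
#' @param hb response, g/dL.
#' @param knots optional explicit knots (length 5, strictly increasing).
#' @return object of class `rcs_fit`: `knots`, `coef` (intercept, linear,
#'   C1..C3), `n`.
#' @export
fit_rcs <- function(stfr, hb, knots = NULL) {
  stopifnot(length(stfr) == length(hb), length(stfr) >= 50, all(stfr > 0))
  if (is.null(knots)) {
    knots <- unname(stats::quantile(stfr, c(0.05, 0.275, 0.50, 0.725, 0.95),
                                    type = 7))
  }
  if (length(knots) != 5 || any(diff(knots) <= 0)) {
    stop("degenerate sTfR spread: need 5 strictly increasing knots")
  }
  B <- cbind(intercept = 1, rcs_basis(stfr, knots))
  fit <- stats::lm.fit(B, hb)
  structure(list(knots = knots, coef = fit$coefficients, n = length(hb)),
            class = "rcs_fit")
}

#' Evaluate a fitted restricted cubic spline
#' @param fit an `rcs_fit`.
#' @param x evaluation points.
#' @return fitted Hb, g/dL.
#' @export
rcs_predict <- function(fit, x) {
  as.numeric(cbind(1, rcs_basis(x, fit$knots)) %*% fit$coef)
}

#' Analytic second derivative of a fitted restricted cubic spline
#'
#' `f''(x) = sum_j beta_j [6 (x-t_j)+ - 6 (x-t4)+ (t5-t_j)/(t5-t4) +
#' 6 (x-t5)+ (t4-t_j)/(t5-t4)]` over the three restricted basis terms:
#' piecewise linear in x with breakpoints at the knots, and exactly zero
#' outside the boundary knots (the natural-spline constraint).
#'
#' @param fit an `rcs_fit`.
#' @param x evaluation points, mg/L.
#' @return second derivative, g/dL per (mg/L)^2.
#' @export
second_derivative <- function(fit, x) {
  k <- fit$knots
  t4 <- k[4]; t5 <- k[5]
  pp <- function(u) pmax(u, 0)
  b <- fit$coef[c("C1", "C2", "C3")]
  d2 <- sapply(1:3, function(j) {
    tj <- k[j]
    6 * pp(x - tj) - 6 * pp(x - t4) * (t5 - tj) / (t5 - t4) +
      6 * pp(x - t5) * (t4 - tj) / (t5 - t4)
  })
  out <- as.numeric(matrix(d2, ncol = 3) %*% b)
  # the natural constraint holds identically; suppress roundoff residue so
  # linearity beyond the boundary knots is exact
  out[x <= k[1] | x >= k[5]] <- 0
  out
}

#' Locate inflection points of a fitted spline
#'
#' Finds every sign-change root of the piecewise-linear second derivative
#' between the boundary knots. On each knot interval the root of the linear
#' piece is closed-form, so locations are exact to floating point. Roots are
#' returned in increasing sTfR order, each paired with the fitted Hb there.
#'
#' @param fit an `rcs_fit`.
#' @param min_count minimum number of inflections required (default 2);
#'   fewer raises an "insufficient curvature" error.
#' @return data.frame with columns `stfr` and `hb`, one row per inflection.
#' @export
find_inflections <- function(fit, min_count = 2) {
  k <- fit$knots
  v <- second_derivative(fit, k)
  # the natural constraint makes f'' identically 0 at the boundary knots;
  # enforce exactly, and treat curvature at roundoff scale (e.g. a fit to
  # exactly linear data) as zero rather than as sign changes
  v[c(1, 5)] <- 0
  v[abs(v) < 1e-11 * max(abs(fit$coef), 1)] <- 0
  roots <- numeric(0)
  for (i in 1:4) {
    if (v[i] * v[i + 1] < 0) {
      roots <- c(roots,
                 k[i] - v[i] * (k[i + 1] - k[i]) / (v[i + 1] - v[i]))
    } else if (i %in% 2:3 && v[i + 1] == 0 && v[i] != 0 &&
               v[i] * v[i + 2] < 0) {
      # sign change through an interior knot where f'' is exactly 0
      roots <- c(roots, k[i + 1])
    }
  }
  roots <- sort(unique(roots))
  if (length(roots) < min_count) {
    stop("insufficient curvature: found ", length(roots),
         " inflection point(s), need ", min_count)
  }
  data.frame(stfr = roots, hb = rcs_predict(fit, roots))
}

#' Dump a fitted curve on a probe grid
#'
#' Writes the fitted Hb, first derivative (central difference on a fine
#' step), and analytic second derivative on an sTfR grid — the plotting
#' contract for the curve figure.
#'
#' @param fit an `rcs_fit`.
#' @param n_grid grid resolution.
#' @return data.frame `stfr`, `hb_fit`, `d1`, `d2`.
#' @export
curve_dump <- function(fit, n_grid = 200) {
  g <- seq(fit$knots[1], fit$knots[5], length.out = n_grid)
  h <- diff(range(g)) * 1e-6
  data.frame(
    stfr = g,
    hb_fit = rcs_predict(fit, g),
    d1 = (rcs_predict(fit, g + h) - rcs_predict(fit, g - h)) / (2 * h),
    d2 = second_derivative(fit, g)
  )
}
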