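# Synthetic multi-survey cohort generator. Emulates the hierarchical
# structure the analysis assumes — survey random intercepts, a healthy core
# with an unhealthy, biomarker-flagged, down-shifted mixture component,
# child age gradients, altitude/smoking increments that the adjustment
# stage removes, and a curvilinear Hb-sTfR relationship with two planted
# inflection points — with every planted parameter recorded in a truth table.

#' Construct a restricted cubic spline from curvature values at the knots
#'
#' Builds an exact `rcs_fit` whose analytic second derivative takes the given
#' values at the three interior knots (it is zero at and beyond the boundary
#' knots by the natural constraint), with prescribed level and slope at the
#' first knot. This is how the generator plants a true Hb-sTfR curve whose
#' inflection points are known in closed form.
#'
#' @param knots 5 strictly increasing sTfR values, mg/L.
#' @param d2_interior curvature `f''` at `knots[2:4]`, g/dL per (mg/L)^2.
#' @param level_t1 Hb at the first knot, g/dL.
#' @param slope_t1 slope at the first knot, g/dL per mg/L.
#' @return an `rcs_fit` object (usable with [rcs_predict()],
#'   [second_derivative()], [find_inflections()]).
#' @export
rcs_curve_from_d2 <- function(knots, d2_interior, level_t1, slope_t1) {
  stopifnot(length(knots) == 5, all(diff(knots) > 0),
            length(d2_interior) == 3)
  # Solve for the three restricted-basis coefficients from f'' at t2..t4.
  probe <- function(b) {
    f <- structure(list(knots = knots,
                        coef = c(intercept = 0, x = 0,
                                 C1 = b[1], C2 = b[2], C3 = b[3])),
                   class = "rcs_fit")
    second_derivative(f, knots[2:4])
  }
  A <- sapply(1:3, function(j) probe(as.numeric(1:3 == j)))
  bC <- solve(A, d2_interior)
  f0 <- structure(list(knots = knots,
                       coef = c(intercept = 0, x = 0,
                                C1 = bC[1], C2 = bC[2], C3 = bC[3])),
                  class = "rcs_fit")
  # Adjust linear part so f(t1) = level_t1 and f'(t1) = slope_t1 (the cubic
  # part has zero value/slope at t1 since all basis terms vanish below t1).
  h <- (knots[5] - knots[1]) * 1e-7
  s0 <- (rcs_predict(f0, knots[1] + h) - rcs_predict(f0, knots[1])) / h
  v0 <- rcs_predict(f0, knots[1])
  lin <- slope_t1 - s0
  int <- level_t1 - v0 - lin * knots[1]
  structure(list(knots = knots,
                 coef = c(intercept = int, x = lin,
                          C1 = bC[1], C2 = bC[2], C3 = bC[3]),
                 n = NA_integer_),
            class = "rcs_fit")
}

#' Synthetic cohort configuration
#'
#' Defaults are calibrated to look like a multinational anemia-survey
#' compilation — 22 surveys of 500-3000 individuals, a healthy Hb core with
#' a small between-survey SD, an unhealthy fraction of 0.60 (children) /
#' 0.44 (women) shifted down by 0.8 g/dL, a child age gradient of 0.19 g/dL
#' per year, and a two-inflection Hb-sTfR curve whose second inflection sits
#' near 9.6 (children) / 11.0 g/dL (women). These constants are illustrative
#' calibration, not reproduction targets.
#'
#' @param group `"child"` or `"woman"`.
#' @param n_surveys number of surveys.
#' @param n_per_survey length-2 range (uniform integer draw per survey) or a
#'   single fixed size.
#' @param mu_hb healthy-component Hb mean, g/dL.
#' @param sigma_within within-survey Hb SD, g/dL.
#' @param tau_between between-survey intercept SD, g/dL.
#' @param age_slope_p5 Hb age slope, g/dL per year (location-shift model, so
#'   the slope holds at every quantile including the fifth percentile).
#' @param frac_unhealthy mixture weight of the unhealthy component, in [0,1).
#' @param unhealthy_hb_shift additive Hb shift of the unhealthy component,
#'   g/dL (negative).
#' @param p_measure_vita,p_measure_malaria,p_has_altitude,p_has_smoking
#'   per-survey probabilities that the optional field is measured at all.
#' @param stfr_knots,stfr_d2,stfr_level,stfr_slope planted Hb-sTfR curve
#'   (see [rcs_curve_from_d2()]); validated to have exactly two inflections.
#' @param stfr_meanlog,stfr_sdlog lognormal marginal of sTfR, mg/L.
#' @param noise_stfr SD of Hb around the planted curve, g/dL.
#' @param noise one of `"normal"` (default) or `"ald"`; `"ald"` draws
#'   within-survey noise from the asymmetric Laplace at `ald_p`, the quantile
#'   mixed model's own error law (used for model-consistent parameter
#'   recovery).
#' @param ald_p quantile for `noise = "ald"`.
#' @param seed integer seed recorded in the truth table.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(group = c("child", "woman"),
                         n_surveys = if (group == "child") 22 else 21,
                         n_per_survey = c(500, 3000),
                         mu_hb = if (group == "child") 11.9 else 13.1,
                         sigma_within = 1.4,
                         tau_between = 0.55,
                         age_slope_p5 = if (group == "child") 0.19 else -0.03,
                         frac_unhealthy = if (group == "child") 0.60 else 0.44,
                         unhealthy_hb_shift = -0.8,
                         p_measure_vita = 0.8,
                         p_measure_malaria = 0.5,
                         p_has_altitude = 0.4,
                         p_has_smoking = if (group == "child") 0 else 0.5,
                         stfr_knots = NULL,
                         stfr_d2 = NULL,
                         stfr_level = if (group == "child") 11.80 else 12.95,
                         stfr_slope = if (group == "child") -0.12 else -0.20,
                         stfr_meanlog = if (group == "child")
                           log(6.5) else log(4.2),
                         stfr_sdlog = 0.45,
                         stfr_qmax = 0.975,
                         noise_stfr = 1.0,
                         noise = c("normal", "ald"),
                         ald_p = 0.05,
                         seed = 20260929L) {
  group <- match.arg(group)
  noise <- match.arg(noise)
  if (is.null(stfr_knots)) {
    # knots at the true quantiles of the (assay-range truncated) sTfR
    # marginal — the quantiles the fitting stage will estimate — so the
    # planted curve lives in (essentially) the fitted basis
    stfr_knots <- stats::qlnorm(c(0.05, 0.275, 0.50, 0.725, 0.95) * stfr_qmax,
                                stfr_meanlog, stfr_sdlog)
  }
  if (is.null(stfr_d2)) {
    stfr_d2 <- if (group == "child") c(-0.60, 0.72, -0.38)
               else c(-1.2, 1.45, -0.90)
  }
  stopifnot(tau_between >= 0, frac_unhealthy >= 0, frac_unhealthy < 1,
            sigma_within > 0, unhealthy_hb_shift <= 0)
  if (length(n_per_survey) == 1) n_per_survey <- rep(n_per_survey, 2)
  curve <- rcs_curve_from_d2(stfr_knots, stfr_d2, stfr_level, stfr_slope)
  infl <- tryCatch(find_inflections(curve, min_count = 2),
                   error = function(e) NULL)
  if (is.null(infl) || nrow(infl) != 2) {
    stop("stfr curve must have exactly two inflection points; got ",
         if (is.null(infl)) "<2" else nrow(infl))
  }
  structure(list(
    group = group, n_surveys = n_surveys, n_per_survey = n_per_survey,
    mu_hb = mu_hb, sigma_within = sigma_within, tau_between = tau_between,
    age_slope_p5 = age_slope_p5, frac_unhealthy = frac_unhealthy,
    unhealthy_hb_shift = unhealthy_hb_shift,
    p_measure_vita = p_measure_vita, p_measure_malaria = p_measure_malaria,
    p_has_altitude = p_has_altitude, p_has_smoking = p_has_smoking,
    stfr_curve = curve, stfr_inflections = infl,
    stfr_meanlog = stfr_meanlog, stfr_sdlog = stfr_sdlog,
    stfr_qmax = stfr_qmax,
    noise_stfr = noise_stfr, noise = noise, ald_p = ald_p,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# mean age (in years) of the uniform age distribution for a group
synth_mean_age_y <- function(group) {
  if (group == "child") mean(c(6, 59)) / 12 else mean(c(15, 49))
}

# draw within-survey noise with mean-zero location for normal; for "ald" the
# noise is centered so that its p-quantile is 0 (the planted quantile line).
draw_noise <- function(n, cfg) {
  if (cfg$noise == "normal") {
    stats::rnorm(n, 0, cfg$sigma_within)
  } else {
    p <- cfg$ald_p
    # ALD(0, sigma, p) via two exponentials; scale chosen so SD matches
    # sigma_within
    sigma <- cfg$sigma_within /
      sqrt((1 - 2 * p + 2 * p^2) / (p^2 * (1 - p)^2))
    e <- stats::rexp(n) / p - stats::rexp(n) / (1 - p)
    e * sigma
  }
}

# Analytic fifth percentile (or any p) of the healthy component: the
# quantile of b*(age - mean_age) + noise (+ survey intercept if
# include_tau), shifted by mu. Age integrated by Gauss-Legendre; numeric
# CDF inversion; no Monte Carlo.
mixture_quantile <- function(cfg, p = 0.05, include_tau = FALSE) {
  rng <- if (cfg$group == "child") c(6, 59) / 12 else c(15, 49)
  gl <- pracma::gaussLegendre(32, rng[1], rng[2])
  wa <- gl$w / diff(rng)
  b <- cfg$age_slope_p5
  mu_a <- synth_mean_age_y(cfg$group)
  s <- sqrt(cfg$sigma_within^2 + if (include_tau) cfg$tau_between^2 else 0)
  cdf <- if (cfg$noise == "normal") {
    function(x) sum(wa * stats::pnorm(x, b * (gl$x - mu_a), s))
  } else {
    pq <- cfg$ald_p
    sig <- s / sqrt((1 - 2 * pq + 2 * pq^2) / (pq^2 * (1 - pq)^2))
    pald <- function(q) ifelse(q < 0, pq * exp((1 - pq) * q / sig),
                               1 - (1 - pq) * exp(-pq * q / sig))
    function(x) sum(wa * pald(x - b * (gl$x - mu_a)))
  }
  stats::uniroot(function(x) cdf(x - cfg$mu_hb) - p,
                 interval = cfg$mu_hb + c(-15, 15), tol = 1e-10)$root
}

# truncated lognormal draws via inverse-CDF, above or below a bound
rlnorm_trunc <- function(n, meanlog, sdlog, lower = NULL, upper = NULL) {
  plo <- if (is.null(lower)) 0 else stats::plnorm(lower, meanlog, sdlog)
  phi <- if (is.null(upper)) 1 else stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

#' Generate a synthetic multi-survey cohort
#'
#' Draws survey intercepts `u_j ~ N(0, tau_between^2)`, individual Hb
#' `mu + u_j + slope * (age_y - mean_age_y) + noise`, a down-shifted
#' unhealthy mixture component whose members violate at least one
#' apparently-healthy threshold (low ferritin, low vitamin A, raised CRP or
#' AGP, or malaria), and healthy members whose biomarkers all pass. Surveys
#' measuring altitude or smoking have the corresponding physiological Hb
#' increment added, so the adjustment stage removes exactly what was
#' planted. The returned truth table records every planted parameter,
#' including the analytic healthy-component fifth percentile and the
#' model-consistent between-survey variance fraction at that quantile.
#'
#' @param cfg a [synth_config()].
#' @return list with `records` (validated record data.frame) and `truth`
#'   (data.frame of `param`, `value`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  crit <- healthy_criteria()
  fer_min <- if (cfg$group == "child") crit$ferritin_min_child else
    crit$ferritin_min_woman
  mu_a <- synth_mean_age_y(cfg$group)
  policy <- adjustment_policy()

  svy <- sprintf("SVY%02d", seq_len(cfg$n_surveys))
  u <- stats::rnorm(cfg$n_surveys, 0, cfg$tau_between)
  ns <- sample.int(cfg$n_per_survey[2] - cfg$n_per_survey[1] + 1L,
                   cfg$n_surveys, replace = TRUE) + cfg$n_per_survey[1] - 1L
  m_vita <- stats::runif(cfg$n_surveys) < cfg$p_measure_vita
  m_mal <- stats::runif(cfg$n_surveys) < cfg$p_measure_malaria
  m_alt <- stats::runif(cfg$n_surveys) < cfg$p_has_altitude
  m_smk <- stats::runif(cfg$n_surveys) < cfg$p_has_smoking
  alt_base <- ifelse(m_alt, stats::runif(cfg$n_surveys, 0, 2600), NA)

  recs <- lapply(seq_len(cfg$n_surveys), function(j) {
    n <- ns[j]
    age <- if (cfg$group == "child") stats::runif(n, 6, 59) else
      stats::runif(n, 15, 49)
    age_y <- if (cfg$group == "child") age / 12 else age
    sex <- if (cfg$group == "child")
      sample(c("male", "female"), n, replace = TRUE) else rep("female", n)
    unhealthy <- stats::runif(n) < cfg$frac_unhealthy
    hb <- cfg$mu_hb + u[j] + cfg$age_slope_p5 * (age_y - mu_a) +
      draw_noise(n, cfg) + ifelse(unhealthy, cfg$unhealthy_hb_shift, 0)

    # biomarkers: healthy pass everything measured; unhealthy violate >= 1
    ferritin <- rlnorm_trunc(n, log(40), 0.5, lower = fer_min)
    vita <- if (m_vita[j]) rlnorm_trunc(n, log(35), 0.3, lower = crit$vita_min)
            else rep(NA_real_, n)
    crp <- rlnorm_trunc(n, log(0.15), 0.7, upper = crit$crp_max)
    agp <- rlnorm_trunc(n, log(0.6), 0.3, upper = crit$agp_max)
    malaria <- if (m_mal[j]) rep("negative", n) else rep(NA_character_, n)
    iu <- which(unhealthy)
    if (length(iu)) {
      vmask <- cbind(
        fer = stats::runif(length(iu)) < 0.45,
        vita = m_vita[j] & stats::runif(length(iu)) < 0.30,
        crp = stats::runif(length(iu)) < 0.40,
        agp = stats::runif(length(iu)) < 0.25,
        mal = m_mal[j] & stats::runif(length(iu)) < 0.20
      )
      none <- rowSums(vmask) == 0
      vmask[none, "fer"] <- TRUE  # guarantee at least one violation
      ferritin[iu[vmask[, "fer"]]] <-
        rlnorm_trunc(sum(vmask[, "fer"]), log(6), 0.5, upper = fer_min * 0.999)
      if (m_vita[j]) vita[iu[vmask[, "vita"]]] <-
        rlnorm_trunc(sum(vmask[, "vita"]), log(13), 0.3,
                     upper = crit$vita_min * 0.999)
      crp[iu[vmask[, "crp"]]] <-
        rlnorm_trunc(sum(vmask[, "crp"]), log(1.5), 0.6,
                     lower = crit$crp_max * 1.001)
      agp[iu[vmask[, "agp"]]] <-
        rlnorm_trunc(sum(vmask[, "agp"]), log(1.4), 0.25,
                     lower = crit$agp_max * 1.001)
      if (m_mal[j]) malaria[iu[vmask[, "mal"]]] <- "positive"
    }

    altitude <- if (m_alt[j])
      pmax(0, alt_base[j] + stats::runif(n, -150, 150)) else rep(NA_real_, n)
    smoker <- if (m_smk[j])
      ifelse(stats::runif(n) < 0.15, "positive", "negative")
      else rep(NA_character_, n)

    # plant the physiological increments the adjustment stage removes
    if (m_alt[j]) {
      hi <- altitude >= policy$altitude_floor
      A <- altitude[hi] * policy$altitude_unit_factor
      hb[hi] <- hb[hi] + policy$altitude_coeff_linear * A +
        policy$altitude_coeff_quad * A^2
    }
    if (m_smk[j]) {
      hb[smoker == "positive"] <- hb[smoker == "positive"] +
        policy$smoking_decrement
    }

    data.frame(
      survey_id = svy[j], group = cfg$group, age = age, sex = sex,
      hb = pmin(pmax(hb, 0.5), 24.5), ferritin = ferritin, vita = vita,
      crp = crp, agp = agp, malaria = malaria, stfr = NA_real_,
      altitude = altitude, smoker = smoker,
      blood_source = sample(c("venous", "capillary"), n, replace = TRUE),
      hb_method = sample(c("analyzer", "hemocue_201", "hemocue_301"), n,
                         replace = TRUE, prob = c(0.2, 0.65, 0.15)),
      healthy_true = !unhealthy,
      stringsAsFactors = FALSE
    )
  })
  records <- do.call(rbind, recs)
  healthy_true <- records$healthy_true
  records$healthy_true <- NULL
  v <- validate_records(records)
  stopifnot(nrow(v$rejected) == 0)
  records <- v$records
  records$healthy_true <- healthy_true

  p <- 0.05
  ald_var_factor <- (1 - 2 * p + 2 * p^2) / (p^2 * (1 - p)^2)
  # pseudo-true ALD scale for normal noise: sigma_w * dnorm(qnorm(p));
  # for "ald" noise the planted scale itself.
  sigma_ald <- if (cfg$noise == "normal") {
    cfg$sigma_within * stats::dnorm(stats::qnorm(p))
  } else {
    cfg$sigma_within / sqrt(ald_var_factor)
  }
  sig_e2 <- sigma_ald^2 * ald_var_factor
  truth <- data.frame(
    param = c("seed", "group_child", "n_surveys", "mu_hb", "sigma_within",
              "tau_between", "age_slope_p5", "frac_unhealthy",
              "unhealthy_hb_shift", "true_p5_survey", "true_p5_marginal",
              "true_icc_p5", "var_frac_between"),
    value = c(cfg$seed, as.numeric(cfg$group == "child"), cfg$n_surveys,
              cfg$mu_hb, cfg$sigma_within, cfg$tau_between,
              cfg$age_slope_p5, cfg$frac_unhealthy, cfg$unhealthy_hb_shift,
              mixture_quantile(cfg, p, include_tau = FALSE),
              mixture_quantile(cfg, p, include_tau = TRUE),
              cfg$tau_between^2 / (cfg$tau_between^2 + sig_e2),
              cfg$tau_between^2 / (cfg$tau_between^2 + cfg$sigma_within^2)),
    stringsAsFactors = FALSE
  )
  list(records = records, truth = truth)
}

#' Generate sTfR and curve-linked Hb for a record set
#'
#' Draws a right-skewed (lognormal) sTfR marginal spanning both planted
#' inflections and replaces Hb with the planted restricted-cubic-spline
#' curve value plus Gaussian noise, so that `E[Hb | sTfR]` is exactly the
#' configured curve. Intended for the erythropoiesis-curve analysis, whose
#' inclusion rule (all participants with sTfR and Hb) differs from the
#' healthy-cohort percentile analyses; use on a fresh cohort.
#'
#' @param cfg a [synth_config()].
#' @param records record data.frame.
#' @param seed optional seed (default derives from `cfg$seed`).
#' @return records with `stfr` filled and `hb` drawn from the curve; truth
#'   rows for the planted inflections attached as attribute `"stfr_truth"`.
#' @export
generate_stfr <- function(cfg, records, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed)
  n <- nrow(records)
  stfr <- stats::qlnorm(stats::runif(n, 0, cfg$stfr_qmax),
                        cfg$stfr_meanlog, cfg$stfr_sdlog)
  records$stfr <- stfr
  records$hb <- rcs_predict(cfg$stfr_curve, stfr) +
    stats::rnorm(n, 0, cfg$noise_stfr)
  records$hb <- pmin(pmax(records$hb, 0.5), 24.5)
  infl <- cfg$stfr_inflections
  attr(records, "stfr_truth") <- data.frame(
    param = c("infl1_stfr", "infl1_hb", "infl2_stfr", "infl2_hb",
              "noise_stfr", "stfr_seed"),
    value = c(infl$stfr[1], infl$hb[1], infl$stfr[2], infl$hb[2],
              cfg$noise_stfr, seed),
    stringsAsFactors = FALSE
  )
  records
}
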