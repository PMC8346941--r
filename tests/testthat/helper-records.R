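# Builders for small in-code fixtures.

make_records <- function(n = 1, survey_id = "S1", group = "child",
                         age = if (group[1] == "child") 30 else 30,
                         sex = if (group[1] == "woman") "female" else "male",
                         hb = 11, ferritin = 30, vita = NA_real_,
                         crp = 0.2, agp = NA_real_, malaria = NA_character_,
                         stfr = NA_real_, altitude = NA_real_,
                         smoker = NA_character_, blood_source = "venous",
                         hb_method = "analyzer") {
  data.frame(survey_id = survey_id, group = group, age = age, sex = sex,
             hb = hb, ferritin = ferritin, vita = vita, crp = crp, agp = agp,
             malaria = malaria, stfr = stfr, altitude = altitude,
             smoker = smoker, blood_source = blood_source,
             hb_method = hb_method, stringsAsFactors = FALSE)[rep(1, n), ]
}

# Twelve-record panel with the healthy subset enumerated by hand:
# rows 1, 4, 6, 8, 10, 12 pass the default criteria.
hand_panel <- function() {
  r <- function(group, ferritin, vita, crp, agp, malaria) {
    make_records(group = group, ferritin = ferritin, vita = vita, crp = crp,
                 agp = agp, malaria = malaria)
  }
  panel <- rbind(
    r("child", 12.0, 25,        0.3, 0.8,  "negative"),  # 1 all pass (fer boundary)
    r("child", 11.9, 25,        0.3, 0.8,  "negative"),  # 2 ferritin below 12
    r("child", 30,   20.0,      0.3, 0.8,  "negative"),  # 3 vita below 20.1
    r("child", 30,   NA,        0.2, 0.9,  NA),          # 4 vita/malaria unmeasured
    r("child", 15,   25,        0.51, 0.8, "negative"),  # 5 crp above 0.5
    r("child", 15,   25,        NA,  1.0,  "negative"),  # 6 crp unmeasured, agp boundary
    r("child", 15,   25,        0.5, 1.01, "negative"),  # 7 agp above 1
    r("child", 15,   25,        0.4, NA,   "negative"),  # 8 agp unmeasured
    r("child", 20,   25,        0.3, 0.8,  "positive"),  # 9 malaria positive
    r("woman", 15.0, 20.1,      0.5, 1.0,  "negative"),  # 10 all boundaries inclusive
    r("woman", 14.9, 50,        0.1, 0.5,  "negative"),  # 11 ferritin below 15
    r("woman", 100,  50,        0.1, 0.5,  NA)           # 12 all pass
  )
  panel$survey_id <- "S1"
  rownames(panel) <- NULL
  panel
}

hand_panel_expected <- c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE,
                         FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)

# Independent integrate()-based oracle for the ALD marginal log-likelihood
# (adaptive quadrature around the posterior peak of each cluster).
lqmm_loglik_oracle <- function(beta, sigma, psi, y, X, cluster, p) {
  e <- as.numeric(y - X %*% beta)
  sum(vapply(split(e, cluster), function(ec) {
    lg <- function(u) vapply(u, function(ui)
      sum(hbref:::ald_logdens(ec - ui, sigma, p)), numeric(1)) +
      stats::dnorm(u, 0, psi, log = TRUE)
    # locate the peak so the log-scaled integrand never underflows
    lo <- -10 * psi - 5
    hi <- 10 * psi + 5
    opt <- stats::optimize(lg, c(lo, hi), maximum = TRUE, tol = 1e-10)
    m <- opt$objective
    u0 <- opt$maximum
    # the log-integrand is concave, so it is monotone on each side of the
    # peak: restrict integration to where the integrand is within e^-60 of
    # the peak, then split at the peak
    drop_to <- function(a, b) {
      if (lg(b) - m > -60) return(b)
      stats::uniroot(function(u) lg(u) - m + 60, c(a, b), tol = 1e-12)$root
    }
    l_eff <- drop_to(u0, lo)
    h_eff <- drop_to(u0, hi)
    f <- function(u) exp(lg(u) - m)
    int1 <- function(a, b) {
      tryCatch(
        stats::integrate(f, a, b, rel.tol = 1e-9,
                         subdivisions = 1000L)$value,
        error = function(e) stats::integrate(f, a, b, rel.tol = 1e-7,
                                             subdivisions = 1000L)$value)
    }
    m + log(int1(l_eff, u0) + int1(u0, h_eff))
  }, numeric(1)))
}

make_estimates <- function(y, se) data.frame(
  survey_id = paste0("S", seq_along(y)), p = 0.05, q_hat = y, se_q = se,
  ci_low = y - 1.96 * se, ci_high = y + 1.96 * se, n = 1000L)
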