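test_that("hand-enumerated 12-record panel reproduces the exact healthy subset", {
  panel <- hand_panel()
  expect_equal(is_healthy(panel), hand_panel_expected)
})

test_that("missing ferritin or both inflammation markers is an error", {
  panel <- make_records(2)
  panel$ferritin[2] <- NA
  expect_error(is_healthy(panel), "ferritin")
  panel$ferritin[2] <- 20
  panel$crp <- NA
  panel$agp <- NA
  expect_error(is_healthy(panel), "inflammation")
})

test_that("threshold monotonicity: stricter criteria never grow the healthy set", {
  set.seed(7)
  recs <- make_records(400)
  recs$ferritin <- rlnorm(400, log(15), 0.8)
  recs$vita <- rlnorm(400, log(22), 0.4)
  recs$crp <- rlnorm(400, log(0.4), 0.8)
  recs$agp <- rlnorm(400, log(0.9), 0.4)
  for (i in 1:20) {
    base <- healthy_criteria(
      ferritin_min_child = runif(1, 5, 30), vita_min = runif(1, 10, 30),
      crp_max = runif(1, 0.2, 2), agp_max = runif(1, 0.5, 2))
    n_base <- sum(is_healthy(recs, base))
    stricter <- healthy_criteria(
      ferritin_min_child = base$ferritin_min_child + runif(1, 0, 10),
      vita_min = base$vita_min + runif(1, 0, 10),
      crp_max = base$crp_max - runif(1, 0, base$crp_max / 2),
      agp_max = base$agp_max - runif(1, 0, base$agp_max / 2))
    expect_lte(sum(is_healthy(recs, stricter)), n_base)
  }
})

test_that("deleting an optional column can only grow the healthy set", {
  set.seed(8)
  recs <- make_records(200)
  recs$ferritin <- rlnorm(200, log(20), 0.6)
  recs$vita <- rlnorm(200, log(20), 0.4)
  recs$malaria <- sample(c("positive", "negative"), 200, replace = TRUE)
  with_vita <- is_healthy(recs)
  recs2 <- recs
  recs2$vita <- NA_real_
  recs2$malaria <- NA_character_
  expect_true(all(is_healthy(recs2) >= with_vita))
})

test_that("surveys below the minimum healthy count are dropped and reported", {
  set.seed(9)
  big <- make_records(500, survey_id = "BIG")
  small <- make_records(500, survey_id = "SMALL")
  # plant pass rates: BIG ~60% healthy, SMALL has 99 healthy of 500
  big$ferritin <- ifelse(seq_len(500) <= 300, 30, 5)
  small$ferritin <- ifelse(seq_len(500) <= 99, 30, 5)
  recs <- rbind(big, small)
  out <- build_healthy_cohort(recs, healthy_criteria(min_healthy_per_survey = 100))
  expect_equal(out$report$surveys_dropped, "SMALL")
  expect_equal(sort(unique(out$healthy$survey_id)), "BIG")
  expect_equal(out$report$n_healthy, 300)
  # per-survey counts match direct enumeration and sum to the global counts
  per <- out$report$per_survey_counts
  expect_equal(per$n_healthy[per$survey_id == "SMALL"], 99)
  expect_equal(sum(per$n_total), out$report$n_total)
  expect_equal(out$report$pct_excluded,
               100 * (1 - out$report$n_healthy / out$report$n_total))
  expect_error(
    build_healthy_cohort(recs, healthy_criteria(min_healthy_per_survey = 1e9)),
    "empty cohort")
})

test_that("vacuous criteria keep every record", {
  recs <- hand_panel()
  recs$ferritin <- abs(recs$ferritin)
  crit <- healthy_criteria(ferritin_min_child = 1e-9, ferritin_min_woman = 1e-9,
                           vita_min = 1e-9, crp_max = Inf, agp_max = Inf,
                           require_no_malaria = FALSE,
                           min_healthy_per_survey = 1)
  out <- build_healthy_cohort(recs, crit)
  expect_equal(out$report$n_healthy, nrow(recs))
  expect_equal(out$report$pct_excluded, 0)
})

test_that("anemia classification uses strict group-specific cutoffs", {
  recs <- rbind(
    make_records(hb = 10.99), make_records(hb = 11.0),
    make_records(group = "woman", sex = "female", hb = 11.99),
    make_records(group = "woman", sex = "female", hb = 12.0))
  expect_equal(classify_anemia(recs), c(TRUE, FALSE, TRUE, FALSE))
  # planted prevalence matches direct counting
  set.seed(10)
  cohort <- make_records(1000, group = "woman", sex = "female")
  cohort$hb <- rnorm(1000, 12.5, 1.3)
  expect_equal(mean(classify_anemia(cohort)), mean(cohort$hb < 12.0))
})
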