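test_that("write then read round-trips records field for field", {
  recs <- make_records(3)
  recs$hb <- c(10.1, 11.2, 12.3)
  recs$ferritin <- c(20, NA, 35)
  recs$malaria <- c("positive", NA, "negative")
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(recs, path)
  back <- read_records(path)
  expect_equal(nrow(attr(back, "rejected")), 0)
  attr(back, "rejected") <- NULL
  rownames(recs) <- NULL
  expect_equal(as.data.frame(back), recs)
})

test_that("invalid rows are rejected with one row-numbered diagnostic each", {
  recs <- rbind(
    make_records(hb = 11),
    make_records(hb = -1),            # nonpositive hb
    make_records(age = 70),           # child age out of range
    make_records(ferritin = -5),      # negative optional marker
    make_records(group = "woman", sex = "female", age = 30, hb = 12)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(recs, path, row.names = FALSE, na = "")
  got <- read_records(path)
  rej <- attr(got, "rejected")
  expect_equal(nrow(got), 2)
  expect_equal(rej$row, c(2L, 3L, 4L))
  expect_match(rej$rule[1], "hb")
  expect_match(rej$rule[2], "age")
  expect_match(rej$rule[3], "ferritin")
  # validation is total: every row accepted or diagnosed exactly once
  expect_equal(nrow(got) + nrow(rej), nrow(recs))
})

test_that("column aliases map and mandatory columns are enforced", {
  recs <- make_records(2)
  names(recs)[names(recs) == "hb"] <- "hemoglobin"
  names(recs)[names(recs) == "ferritin"] <- "sf"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(recs, path, row.names = FALSE, na = "")
  got <- read_records(path)
  expect_equal(got$hb, recs$hemoglobin)
  expect_equal(got$ferritin, recs$sf)

  no_hb <- recs[, setdiff(names(recs), "hemoglobin")]
  utils::write.csv(no_hb, path, row.names = FALSE, na = "")
  expect_error(read_records(path), "mandatory")
})

test_that("a file without ferritin loads but the healthy filter refuses it", {
  recs <- make_records(3)
  recs$ferritin <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(recs, path, row.names = FALSE, na = "")
  got <- read_records(path)
  expect_true(all(is.na(got$ferritin)))
  expect_error(is_healthy(got), "ferritin required")
})

test_that("survey summaries match brute-force missingness counts", {
  set.seed(42)
  recs <- do.call(rbind, lapply(c("A", "B", "C"), function(id) {
    r <- make_records(20, survey_id = id)
    r$vita <- ifelse(runif(20) < 0.5, 25, NA)
    r$malaria <- ifelse(runif(20) < 0.3, "negative", NA)
    r$altitude <- NA_real_
    r
  }))
  recs$vita[recs$survey_id == "B"] <- NA       # B never measures vitamin A
  meta <- summarize_surveys(recs)
  expect_equal(meta$survey_id, c("A", "B", "C"))
  for (i in seq_len(nrow(meta))) {
    s <- recs[recs$survey_id == meta$survey_id[i], ]
    expect_equal(meta$measures_vita[i], sum(!is.na(s$vita)) > 0)
    expect_equal(meta$measures_malaria[i], sum(!is.na(s$malaria)) > 0)
    expect_false(meta$has_altitude[i])
    expect_equal(meta$n[i], nrow(s))
  }
})
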