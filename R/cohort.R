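# Apparently-healthy case definition, minimum-survey-size rule, anemia
# classification, and data-loss accounting.

#' Apparently-healthy criteria
#'
#' Thresholds defining the apparently healthy subpopulation: iron replete
#' (ferritin at or above a group-specific minimum), no vitamin A deficiency
#' (RBP or retinol at or above `vita_min`, where measured), no inflammation
#' (CRP at or below `crp_max` and AGP at or below `agp_max`, each where
#' measured; when only one marker is measured that one decides), and no known
#' malaria. Comparisons are inclusive on the healthy side. Surveys whose
#' healthy count falls below `min_healthy_per_survey` are dropped from
#' percentile analyses.
#'
#' @param ferritin_min_child ng/mL (default 12).
#' @param ferritin_min_woman ng/mL (default 15).
#' @param vita_min ug/dL RBP or retinol (default 20.1).
#' @param crp_max mg/dL (default 0.5).
#' @param agp_max g/L (default 1).
#' @param require_no_malaria drop malaria-positive records (default TRUE).
#' @param min_healthy_per_survey minimum healthy n to keep a survey
#'   (default 100).
#' @return object of class `healthy_criteria`.
#' @export
healthy_criteria <- function(ferritin_min_child = 12,
                             ferritin_min_woman = 15,
                             vita_min = 20.1,
                             crp_max = 0.5,
                             agp_max = 1,
                             require_no_malaria = TRUE,
                             min_healthy_per_survey = 100) {
  stopifnot(ferritin_min_child > 0, ferritin_min_woman > 0, vita_min > 0,
            crp_max > 0, agp_max > 0, min_healthy_per_survey >= 1)
  structure(list(
    ferritin_min_child = ferritin_min_child,
    ferritin_min_woman = ferritin_min_woman,
    vita_min = vita_min,
    crp_max = crp_max,
    agp_max = agp_max,
    require_no_malaria = isTRUE(require_no_malaria),
    min_healthy_per_survey = min_healthy_per_survey
  ), class = "healthy_criteria")
}

#' Classify records as apparently healthy
#'
#' Vectorized predicate. Ferritin and at least one inflammation marker must
#' be measured (percentile surveys must have Hb, ferritin, and inflammation);
#' optional markers follow "where measured" semantics — an unmeasured vitamin
#' A, malaria, or second inflammation marker never excludes a record.
#' Ferritin and vitamin A are used unadjusted for inflammation, because
#' inflamed individuals are excluded outright.
#'
#' @param records record data.frame.
#' @param crit a [healthy_criteria()].
#' @return logical vector, one flag per record.
#' @export
is_healthy <- function(records, crit = healthy_criteria()) {
  if (any(is.na(records$ferritin))) {
    stop("ferritin required for the healthy-subpopulation definition")
  }
  if (any(is.na(records$crp) & is.na(records$agp))) {
    stop("at least one inflammation marker (crp or agp) required per record")
  }
  fer_min <- ifelse(records$group == "child",
                    crit$ferritin_min_child, crit$ferritin_min_woman)
  ok <- records$ferritin >= fer_min
  ok <- ok & (is.na(records$vita) | records$vita >= crit$vita_min)
  ok <- ok & (is.na(records$crp) | records$crp <= crit$crp_max)
  ok <- ok & (is.na(records$agp) | records$agp <= crit$agp_max)
  if (crit$require_no_malaria) {
    ok <- ok & (is.na(records$malaria) | records$malaria == "negative")
  }
  ok
}

#' Build the apparently-healthy analysis cohort
#'
#' Applies [is_healthy()], then drops every record from surveys whose healthy
#' count is below `crit$min_healthy_per_survey`. The report accounts for all
#' data loss: totals, percentage excluded, per-survey counts, and the list of
#' dropped surveys.
#'
#' @param records record data.frame (nonempty).
#' @param crit a [healthy_criteria()].
#' @return list with `healthy` (record data.frame) and `report` (class
#'   `cohort_report`: `n_total`, `n_healthy`, `pct_excluded`,
#'   `surveys_dropped`, `per_survey_counts`).
#' @export
build_healthy_cohort <- function(records, crit = healthy_criteria()) {
  stopifnot(nrow(records) > 0)
  flag <- is_healthy(records, crit)
  per <- stats::aggregate(
    cbind(n_total = rep(1L, nrow(records)), n_healthy = as.integer(flag)),
    by = list(survey_id = records$survey_id), FUN = sum)
  per <- per[order(per$survey_id), ]
  rownames(per) <- NULL
  dropped <- per$survey_id[per$n_healthy < crit$min_healthy_per_survey]
  keep <- flag & !(records$survey_id %in% dropped)
  healthy <- records[keep, , drop = FALSE]
  rownames(healthy) <- NULL
  if (nrow(healthy) == 0) {
    stop("empty cohort: every survey fell below min_healthy_per_survey (",
         crit$min_healthy_per_survey, ")")
  }
  report <- structure(list(
    n_total = nrow(records),
    n_healthy = nrow(healthy),
    pct_excluded = 100 * (1 - nrow(healthy) / nrow(records)),
    surveys_dropped = as.character(dropped),
    per_survey_counts = per
  ), class = "cohort_report")
  attr(healthy, "hb_adjusted") <- attr(records, "hb_adjusted")
  list(healthy = healthy, report = report)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort: %d of %d records apparently healthy (%.1f%% excluded)\n",
              x$n_healthy, x$n_total, x$pct_excluded))
  if (length(x$surveys_dropped)) {
    cat("Surveys dropped (healthy n below minimum):",
        paste(x$surveys_dropped, collapse = ", "), "\n")
  } else cat("No surveys dropped.\n")
  invisible(x)
}

#' Classify anemia by the WHO cutoffs
#'
#' Anemia is adjusted Hb below 11.0 g/dL for children aged 6-59 months and
#' below 12.0 g/dL for nonpregnant women (strict inequality).
#'
#' @param records record data.frame with adjusted Hb.
#' @param cutoff_child,cutoff_woman g/dL cutoffs (WHO defaults).
#' @return logical vector.
#' @export
classify_anemia <- function(records, cutoff_child = 11.0, cutoff_woman = 12.0) {
  stopifnot(all(!is.na(records$hb)))
  ifelse(records$group == "child",
         records$hb < cutoff_child, records$hb < cutoff_woman)
}

#' Sensitivity ladder over healthy-criteria thresholds
#'
#' Re-runs the full fifth-percentile pipeline (cohort filter, per-survey
#' quantile estimation, REML pooling) under each criteria set in `grid` and
#' tabulates analytic sample size, percentage of the original sample, number
#' of retained surveys, and the pooled quantile with its CI — the layout of a
#' threshold-ladder sensitivity table.
#'
#' @param records adjusted record data.frame.
#' @param grid named list of [healthy_criteria()] objects; names label rows.
#' @param p quantile (default 0.05).
#' @param level CI level (default 0.95).
#' @return data.frame, one row per criteria set.
#' @export
sensitivity_grid <- function(records, grid, p = 0.05, level = 0.95) {
  stopifnot(length(grid) > 0)
  labels <- names(grid)
  if (is.null(labels)) labels <- paste0("criteria_", seq_along(grid))
  out <- lapply(seq_along(grid), function(i) {
    ch <- build_healthy_cohort(records, grid[[i]])
    est <- survey_quantiles(ch$healthy, p = p, level = level)
    pooled <- reml_pool(est, level = level)
    data.frame(
      criteria = labels[i],
      n_analytic = ch$report$n_healthy,
      pct_of_original = 100 * ch$report$n_healthy / ch$report$n_total,
      k_surveys = pooled$k,
      pooled_q = pooled$mu_hat,
      ci_low = pooled$ci_low,
      ci_high = pooled$ci_high,
      tau = pooled$tau,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
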