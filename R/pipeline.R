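# End-to-end orchestration from a single YAML config: adjust -> cohort ->
# per-survey quantiles -> REML pool; quantile-mixed ICC; sTfR curve; the
# ferritin/vitamin-A sensitivity ladder. Every run emits a manifest that
# fully determines a re-run (config hash + seed).

#' Default pipeline configuration
#'
#' Nested list with sections `io` (column aliases), `adjustment`, `healthy`,
#' `quantile`, `meta`, `lqmm`, `spline`, and `synthetic`, mirroring the YAML
#' layout in `inst/extdata/config_default.yaml`.
#' @return named list.
#' @export
default_config <- function() {
  list(
    io = list(aliases = default_aliases()),
    adjustment = list(enabled = TRUE, altitude_coeff_linear = -0.032,
                      altitude_coeff_quad = 0.022, altitude_floor = 1000,
                      smoking_decrement = 0.3,
                      altitude_unit_factor = 0.0032808),
    healthy = list(ferritin_min_child = 12, ferritin_min_woman = 15,
                   vita_min = 20.1, crp_max = 0.5, agp_max = 1,
                   require_no_malaria = TRUE, min_healthy_per_survey = 100),
    quantile = list(p = 0.05, level = 0.95),
    meta = list(level = 0.95, tol = 1e-8, max_iter = 200),
    lqmm = list(p = 0.05, method = "exact", nodes = 11, restarts = 3,
                covariates = c("age", "age2", "sex"), age_unit = "years"),
    spline = list(B = 5000, level = 0.95, knots = NULL),
    synthetic = list(group = "child", seed = 20260929)
  )
}

# recursively overlay user values on the defaults
merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else user[[nm]]
  }
  base
}

#' Read a pipeline config, overlaying the defaults
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return full config list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  cfg
}

config_policy <- function(cfg) {
  a <- cfg$adjustment
  adjustment_policy(a$altitude_coeff_linear, a$altitude_coeff_quad,
                    a$altitude_floor, a$smoking_decrement,
                    a$altitude_unit_factor)
}

config_criteria <- function(cfg, overrides = list()) {
  h <- merge_config(cfg$healthy, overrides)
  healthy_criteria(h$ferritin_min_child, h$ferritin_min_woman, h$vita_min,
                   h$crp_max, h$agp_max, h$require_no_malaria,
                   h$min_healthy_per_survey)
}

# Manifest: config digest + seed + input digest fully determine a re-run.
run_manifest <- function(cfg, seed, inputs = character(0),
                         outputs = character(0)) {
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, null = "null", digits = NA)
  on.exit(unlink(tf))
  list(
    config_hash = unname(tools::md5sum(tf)),
    seed = seed,
    input_digest = if (length(inputs))
      unname(tools::md5sum(inputs)) else character(0),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("hbref"))
  )
}

# obtain records: from a CSV path or the synthetic generator
resolve_records <- function(cfg, records = NULL, input_csv = NULL,
                            seed = NULL) {
  if (!is.null(records)) return(list(records = records, truth = NULL))
  if (!is.null(input_csv)) {
    return(list(records = read_records(input_csv, aliases = cfg$io$aliases),
                truth = NULL))
  }
  sc <- synth_config(group = cfg$synthetic$group,
                     seed = if (is.null(seed)) cfg$synthetic$seed else seed)
  generate_cohort(sc)
}

#' Run the fifth-percentile pooling pipeline
#'
#' Adjust Hb (altitude, smoking) -> apparently-healthy cohort -> per-survey
#' quantile estimates with Woodruff CIs -> REML random-effects pool. Writes
#' the cohort report, forest table CSV, meta summary, and manifest when
#' `out_dir` is given, and logs record counts in and out of every filter.
#'
#' @param config config list from [read_config()] (default: defaults).
#' @param records optional in-memory record data.frame (skips input reading).
#' @param input_csv optional CSV path; when both are `NULL` a synthetic
#'   cohort is generated from the `synthetic` config section.
#' @param seed overrides the synthetic seed.
#' @param out_dir optional output directory for artifacts.
#' @param quiet suppress log lines.
#' @return list: `meta` (class `meta_result`), `estimates`, `report`,
#'   `forest`, `truth` (synthetic runs), `manifest`.
#' @export
run_p5_pipeline <- function(config = read_config(), records = NULL,
                            input_csv = NULL, seed = NULL, out_dir = NULL,
                            quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  src <- resolve_records(config, records, input_csv, seed)
  recs <- src$records
  say("input: %d records, %d surveys", nrow(recs),
      length(unique(recs$survey_id)))
  recs <- adjust_hb_records(recs, config_policy(config),
                            enabled = isTRUE(config$adjustment$enabled))
  ch <- build_healthy_cohort(recs, config_criteria(config))
  say("healthy cohort: %d of %d records (%.1f%% excluded); %d surveys dropped",
      ch$report$n_healthy, ch$report$n_total, ch$report$pct_excluded,
      length(ch$report$surveys_dropped))
  est <- survey_quantiles(ch$healthy, p = config$quantile$p,
                          level = config$quantile$level)
  pooled <- reml_pool(est, level = config$meta$level, tol = config$meta$tol,
                      max_iter = config$meta$max_iter)
  say("pooled P%d = %.3f g/dL (CI %.3f-%.3f), tau = %.3f, Q/df = %.1f/%d",
      round(100 * config$quantile$p), pooled$mu_hat, pooled$ci_low,
      pooled$ci_high, pooled$tau, pooled$Q, pooled$df)
  forest <- forest_table(est, pooled)
  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    outputs <- file.path(out_dir, c("cohort_report.csv", "forest.csv",
                                    "meta_summary.csv"))
    utils::write.csv(ch$report$per_survey_counts, outputs[1], row.names = FALSE)
    utils::write.csv(forest, outputs[2], row.names = FALSE)
    utils::write.csv(data.frame(
      quantity = c("pooled", "se", "ci_low", "ci_high", "tau2", "tau", "Q",
                   "df", "k"),
      value = c(pooled$mu_hat, pooled$se_mu, pooled$ci_low, pooled$ci_high,
                pooled$tau2, pooled$tau, pooled$Q, pooled$df, pooled$k)),
      outputs[3], row.names = FALSE)
  }
  manifest <- run_manifest(config, seed %||% config$synthetic$seed,
                           inputs = if (is.null(input_csv)) character(0)
                                    else input_csv,
                           outputs = outputs)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(meta = pooled, estimates = est, report = ch$report, forest = forest,
       truth = src$truth, manifest = manifest)
}

#' Run the quantile-mixed ICC analysis
#'
#' Builds the healthy cohort as in [run_p5_pipeline()] and fits the
#' asymmetric-Laplace quantile mixed model, emitting a fixed-effects +
#' variance-decomposition summary table.
#'
#' @inheritParams run_p5_pipeline
#' @param p target quantile override (e.g. 0.95 for the upper-tail check).
#' @return list: `fit` (class `quantile_mixed_fit`), `table`, `truth`,
#'   `manifest`.
#' @export
run_icc <- function(config = read_config(), records = NULL, input_csv = NULL,
                    seed = NULL, p = NULL, out_dir = NULL, quiet = FALSE) {
  src <- resolve_records(config, records, input_csv, seed)
  recs <- adjust_hb_records(src$records, config_policy(config),
                            enabled = isTRUE(config$adjustment$enabled))
  ch <- build_healthy_cohort(recs, config_criteria(config))
  p_use <- p %||% config$lqmm$p
  fit <- fit_lqmm(ch$healthy, p = p_use,
                  covariates = config$lqmm$covariates,
                  age_unit = config$lqmm$age_unit,
                  method = config$lqmm$method,
                  nodes = config$lqmm$nodes,
                  restarts = config$lqmm$restarts)
  tab <- data.frame(
    term = c(names(fit$beta), "icc_between_pct", "icc_within_pct"),
    value = c(unname(fit$beta), 100 * fit$icc_between, 100 * fit$icc_within),
    stringsAsFactors = FALSE
  )
  if (!quiet) print(fit)
  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    outputs <- file.path(out_dir, "icc_summary.csv")
    utils::write.csv(tab, outputs, row.names = FALSE)
  }
  list(fit = fit, table = tab, truth = src$truth,
       manifest = run_manifest(config, seed %||% config$synthetic$seed,
                               outputs = outputs))
}

#' Run the Hb-sTfR inflection analysis
#'
#' Generates (or accepts) records with sTfR, adjusts Hb, and runs
#' [run_hb_stfr_analysis()]. No healthy filter is applied: the curve uses
#' all participants with sTfR and Hb.
#'
#' @inheritParams run_p5_pipeline
#' @param B bootstrap resamples override.
#' @return list: `result` (class `inflection_result`), `curve` (probe-grid
#'   dump), `truth`, `manifest`.
#' @export
run_stfr <- function(config = read_config(), records = NULL, input_csv = NULL,
                     seed = NULL, B = NULL, out_dir = NULL, quiet = FALSE) {
  seed_use <- seed %||% config$synthetic$seed
  if (is.null(records) && is.null(input_csv)) {
    sc <- synth_config(group = config$synthetic$group, seed = seed_use)
    base <- generate_cohort(sc)$records
    recs <- generate_stfr(sc, base)
    truth <- attr(recs, "stfr_truth")
  } else {
    src <- resolve_records(config, records, input_csv, seed)
    recs <- src$records
    truth <- NULL
  }
  recs <- adjust_hb_records(recs, config_policy(config),
                            enabled = isTRUE(config$adjustment$enabled))
  recs <- recs[!is.na(recs$stfr) & !is.na(recs$hb), , drop = FALSE]
  res <- run_hb_stfr_analysis(recs, B = B %||% config$spline$B,
                              seed = seed_use, level = config$spline$level,
                              knots = config$spline$knots,
                              jackknife_groups = config$spline$jackknife_groups)
  if (!quiet) print(res)
  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    outputs <- file.path(out_dir, c("stfr_curve.csv", "stfr_result.json"))
    utils::write.csv(curve_dump(res$fit), outputs[1], row.names = FALSE)
    jsonlite::write_json(list(
      first = as.list(res$first), second = as.list(res$second),
      hb_ci_second = as.list(res$hb_ci_second), boot_reps = res$boot_reps,
      n_failed = res$n_failed, n = res$n, seed = seed_use),
      outputs[2], auto_unbox = TRUE, digits = NA)
  }
  list(result = res, curve = curve_dump(res$fit), truth = truth,
       manifest = run_manifest(config, seed_use, outputs = outputs))
}

#' Run the threshold-ladder sensitivity analysis
#'
#' Re-runs the full P5 pipeline under progressively stricter ferritin (and
#' vitamin A) thresholds, mirroring the sensitivity table layout: analytic
#' n, percent of original, pooled estimate with CI.
#'
#' @inheritParams run_p5_pipeline
#' @param ladder named list of healthy-criteria override lists; default is
#'   the conventional ferritin ladder for the configured group.
#' @return list: `table`, `truth`, `manifest`.
#' @export
run_sensitivity <- function(config = read_config(), records = NULL,
                            input_csv = NULL, seed = NULL, ladder = NULL,
                            out_dir = NULL, quiet = FALSE) {
  src <- resolve_records(config, records, input_csv, seed)
  recs <- adjust_hb_records(src$records, config_policy(config),
                            enabled = isTRUE(config$adjustment$enabled))
  grp <- unique(recs$group)
  if (is.null(ladder)) {
    ladder <- if (identical(grp, "child")) {
      list(base = list(),
           ferritin_20 = list(ferritin_min_child = 20),
           ferritin_30 = list(ferritin_min_child = 30))
    } else {
      list(base = list(),
           ferritin_30 = list(ferritin_min_woman = 30),
           ferritin_50 = list(ferritin_min_woman = 50))
    }
  }
  grid <- lapply(ladder, function(ov) config_criteria(config, ov))
  tab <- sensitivity_grid(recs, grid, p = config$quantile$p,
                          level = config$quantile$level)
  if (!quiet) print(tab)
  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    outputs <- file.path(out_dir, "sensitivity.csv")
    utils::write.csv(tab, outputs, row.names = FALSE)
  }
  list(table = tab, truth = src$truth,
       manifest = run_manifest(config, seed %||% config$synthetic$seed,
                               outputs = outputs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
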