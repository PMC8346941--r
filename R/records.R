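#' @keywords internal
"_PACKAGE"

# Canonical record columns. Units follow the survey convention throughout:
# Hb g/dL, ferritin ng/mL, vitamin A (RBP or retinol) ug/dL, CRP mg/dL,
# AGP g/L, sTfR mg/L, altitude m. Child age is months, woman age years.
RECORD_COLS <- c(
  "survey_id", "group", "age", "sex", "hb", "ferritin", "vita", "crp",
  "agp", "malaria", "stfr", "altitude", "smoker", "blood_source", "hb_method"
)
MANDATORY_COLS <- c("survey_id", "group", "age", "hb")
TRISTATE_LEVELS <- c("positive", "negative")
BLOOD_SOURCES <- c("venous", "capillary", "unknown")
HB_METHODS <- c("analyzer", "hemocue_hbb", "hemocue_201", "hemocue_301", "unknown")

#' Unit conversion constants
#'
#' Documented multiplicative factors between the units used here and SI-style
#' alternatives, provided as named constants and never applied implicitly:
#' Hb g/dL to g/L multiply by 10; ferritin ng/mL to ug/L multiply by 1;
#' retinol/RBP ug/dL to umol/L multiply by 0.0349; CRP mg/dL to mg/L
#' multiply by 10.
#' @export
hb_unit_factors <- c(
  hb_gdl_to_gl = 10,
  ferritin_ngml_to_ugl = 1,
  vita_ugdl_to_umoll = 0.0349,
  crp_mgdl_to_mgl = 10
)

default_aliases <- function() {
  list(
    survey_id = c("survey_id", "survey", "svy"),
    group = c("group", "target_group"),
    age = c("age", "age_months", "age_years"),
    sex = c("sex"),
    hb = c("hb", "hemoglobin", "hb_gdl"),
    ferritin = c("ferritin", "sf", "ferritin_ngml"),
    vita = c("vita", "rbp", "retinol", "vitamin_a"),
    crp = c("crp", "crp_mgdl"),
    agp = c("agp", "agp_gl"),
    malaria = c("malaria", "malaria_flag"),
    stfr = c("stfr", "tfr", "stfr_mgl"),
    altitude = c("altitude", "altitude_m", "elevation"),
    smoker = c("smoker", "smoking", "smokes"),
    blood_source = c("blood_source", "blood_draw", "draw"),
    hb_method = c("hb_method", "assay", "hb_assay")
  )
}

age_range <- function(group) {
  if (group == "child") c(6, 59) else c(15, 49)
}

# Validate a raw data.frame of individual records. Returns list(records,
# rejected) where rejected is a data.frame(row, rule) with one diagnostic per
# rejected row (validation is total: every row is accepted or diagnosed once).
validate_records <- function(df, group = NULL) {
  stopifnot(is.data.frame(df))
  miss <- setdiff(MANDATORY_COLS, names(df))
  if (length(miss) > 0) {
    stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  }
  for (col in setdiff(RECORD_COLS, names(df))) df[[col]] <- NA
  df <- df[RECORD_COLS]
  n <- nrow(df)

  df$survey_id <- as.character(df$survey_id)
  df$group <- as.character(df$group)
  for (col in c("age", "hb", "ferritin", "vita", "crp", "agp", "stfr", "altitude")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  for (col in c("sex", "malaria", "smoker", "blood_source", "hb_method")) {
    v <- as.character(df[[col]])
    v[!is.na(v) & v == ""] <- NA
    df[[col]] <- v
  }
  df$blood_source[is.na(df$blood_source)] <- "unknown"
  df$hb_method[is.na(df$hb_method)] <- "unknown"

  rule <- rep(NA_character_, n)
  flag <- function(cond, msg) {
    hit <- which(is.na(rule) & cond)
    rule[hit] <<- msg
  }
  if (!is.null(group)) flag(df$group != group, paste0("group != '", group, "'"))
  flag(is.na(df$survey_id) | df$survey_id == "", "missing survey_id")
  flag(!(df$group %in% c("child", "woman")), "group must be 'child' or 'woman'")
  flag(is.na(df$hb), "missing hb")
  flag(!is.na(df$hb) & (df$hb <= 0 | df$hb >= 25), "hb outside (0, 25) g/dL")
  flag(is.na(df$age), "missing age")
  ok_grp <- df$group %in% c("child", "woman")
  lo <- ifelse(df$group == "child", 6, 15)
  hi <- ifelse(df$group == "child", 59, 49)
  flag(ok_grp & !is.na(df$age) & (df$age < lo | df$age > hi),
       "age out of range for group (child 6-59 mo, woman 15-49 y)")
  flag(df$group == "woman" & !is.na(df$sex) & df$sex != "female",
       "woman records must have sex = female")
  flag(!is.na(df$sex) & !(df$sex %in% c("male", "female")), "invalid sex")
  for (col in c("ferritin", "vita", "crp", "agp", "stfr")) {
    flag(!is.na(df[[col]]) & df[[col]] < 0, paste0("negative ", col))
  }
  flag(!is.na(df$altitude) & df$altitude < 0, "negative altitude")
  for (col in c("malaria", "smoker")) {
    flag(!is.na(df[[col]]) & !(df[[col]] %in% TRISTATE_LEVELS),
         paste0("invalid ", col, " (positive/negative/empty)"))
  }
  flag(!(df$blood_source %in% BLOOD_SOURCES), "invalid blood_source")
  flag(!(df$hb_method %in% HB_METHODS), "invalid hb_method")
  df$sex[df$group == "woman"] <- "female"

  bad <- which(!is.na(rule))
  rejected <- data.frame(row = bad, rule = rule[bad], stringsAsFactors = FALSE)
  recs <- df[setdiff(seq_len(n), bad), , drop = FALSE]
  rownames(recs) <- NULL
  list(records = recs, rejected = rejected)
}

#' Read individual survey records from a delimited file
#'
#' Reads a CSV (RFC-4180, UTF-8, header row) of individual-level survey
#' records, maps column names through an alias table, coerces types, and
#' validates every row against the hard record invariants. Rows violating an
#' invariant are dropped; a data.frame of row-numbered diagnostics is attached
#' as the `"rejected"` attribute. Missing optional fields stay missing (`NA`),
#' never zero; sentinel numerics are not interpreted.
#'
#' @param path path to a CSV file.
#' @param group optional target group (`"child"` or `"woman"`); when given,
#'   rows of any other group are rejected with a diagnostic.
#' @param aliases named list mapping canonical column names to accepted
#'   header spellings (default [default_aliases()]-style map, overridable via
#'   the `io: aliases:` config section).
#' @return data.frame of validated records with attribute `"rejected"`.
#' @export
read_records <- function(path, group = NULL, aliases = default_aliases()) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  nm <- names(raw)
  for (canon in names(aliases)) {
    hit <- which(tolower(nm) %in% tolower(aliases[[canon]]))
    if (length(hit) >= 1) nm[hit[1]] <- canon
  }
  names(raw) <- nm
  v <- validate_records(raw, group = group)
  structure(v$records, rejected = v$rejected)
}

#' Write records to CSV
#'
#' Inverse of [read_records()]: canonical column order, empty cells for
#' missing values, UTF-8. Round-trips field-for-field.
#' @param records record data.frame.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records[RECORD_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarize surveys present in a record set
#'
#' One row per distinct `survey_id`, with availability flags computed from
#' observed missingness: a survey "measures" a field iff it is nonmissing for
#' at least one of its records.
#'
#' @param records record data.frame (nonempty).
#' @return data.frame with columns `survey_id`, `n`, `measures_vita`,
#'   `measures_malaria`, `has_altitude`, `has_smoking`.
#' @export
summarize_surveys <- function(records) {
  stopifnot(nrow(records) > 0)
  ids <- sort(unique(records$survey_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    s <- records[records$survey_id == id, ]
    data.frame(
      survey_id = id,
      n = nrow(s),
      measures_vita = any(!is.na(s$vita)),
      measures_malaria = any(!is.na(s$malaria)),
      has_altitude = any(!is.na(s$altitude)),
      has_smoking = any(!is.na(s$smoker)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
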