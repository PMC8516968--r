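AGE_LEVELS <- c("5to14", "under5")   # reference first
SEX_LEVELS <- c("male", "female")    # reference first

PANEL_COLS <- c("area", "district", "month_index", "age_group", "sex",
                "cases", "population")
CLIMATE_COLS <- c("district", "month_index", "rainfall_mm", "rh_percent",
                  "tmin_c", "tmax_c")

#' Validate and normalize a stratified count panel
#'
#' A count panel holds observed disease counts per area x month x
#' age-group x sex stratum together with the stratum population. Each
#' combination must appear exactly once, months must be contiguous from 1,
#' counts non-negative integers and populations positive. Rows are sorted
#' deterministically by (area, month, age, sex) so that all downstream
#' computation (including MCMC) is reproducible.
#'
#' @param df data frame with columns `area`, `district`, `month_index`,
#'   `age_group` (`under5` / `5to14`), `sex` (`male` / `female`), `cases`,
#'   `population`.
#' @return the validated data frame with class `count_panel`.
#' @export
count_panel <- function(df) {
  miss <- setdiff(PANEL_COLS, names(df))
  if (length(miss)) {
    stop_spzip(paste0("missing column(s): ", paste(miss, collapse = ", ")),
               "spzip_schema_error")
  }
  df <- as.data.frame(df)[PANEL_COLS]
  df$area <- as.character(df$area)
  df$district <- as.character(df$district)
  if (!all(df$age_group %in% AGE_LEVELS)) {
    stop_spzip("age_group must be one of 'under5', '5to14'",
               "spzip_schema_error")
  }
  if (!all(df$sex %in% SEX_LEVELS)) {
    stop_spzip("sex must be one of 'male', 'female'", "spzip_schema_error")
  }
  if (any(!is.finite(df$cases)) || any(df$cases < 0) ||
      any(df$cases != round(df$cases))) {
    stop_spzip("cases must be non-negative integers", "spzip_integrity_error")
  }
  if (any(!is.finite(df$population)) || any(df$population <= 0)) {
    stop_spzip("population must be positive", "spzip_integrity_error")
  }
  months <- sort(unique(df$month_index))
  if (!identical(as.integer(months), seq_len(length(months)))) {
    stop_spzip("month_index must be contiguous integers starting at 1",
               "spzip_integrity_error")
  }
  key <- paste(df$area, df$month_index, df$age_group, df$sex, sep = "|")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop_spzip(paste0("duplicate stratum key(s): ",
                      paste(head(dups, 5), collapse = "; ")),
               "spzip_integrity_error")
  }
  n_exp <- length(unique(df$area)) * length(months) * 4L
  if (nrow(df) != n_exp) {
    stop_spzip(sprintf(
      "incomplete panel: expected %d strata (areas x months x 2 ages x 2 sexes), got %d",
      n_exp, nrow(df)), "spzip_integrity_error")
  }
  ord <- order(df$area, df$month_index,
               match(df$age_group, AGE_LEVELS), match(df$sex, SEX_LEVELS))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("count_panel", "data.frame")
  df
}

#' Read / write a count panel as CSV
#'
#' @param path CSV file with a header row matching the [count_panel()]
#'   schema.
#' @return [read_count_panel()] returns a validated `count_panel`;
#'   [write_count_panel()] returns `path` invisibly.
#' @export
read_count_panel <- function(path) {
  if (!file.exists(path)) {
    stop_spzip(paste0("file not found: ", path), "spzip_io_error")
  }
  count_panel(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_count_panel
#' @param panel a `count_panel`.
#' @export
write_count_panel <- function(panel, path) {
  write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Validate a district-level monthly climate panel
#'
#' One record per district x month with monthly rainfall (mm), relative
#' humidity (%), and minimum/maximum temperature (deg C). Climate is
#' broadcast district -> area when the design is assembled (climate is
#' assumed homogeneous within a district).
#'
#' @param df data frame with columns `district`, `month_index`,
#'   `rainfall_mm`, `rh_percent`, `tmin_c`, `tmax_c`.
#' @return the validated data frame with class `climate_panel`.
#' @export
climate_panel <- function(df) {
  miss <- setdiff(CLIMATE_COLS, names(df))
  if (length(miss)) {
    stop_spzip(paste0("missing column(s): ", paste(miss, collapse = ", ")),
               "spzip_schema_error")
  }
  df <- as.data.frame(df)[CLIMATE_COLS]
  df$district <- as.character(df$district)
  key <- paste(df$district, df$month_index, sep = "|")
  if (anyDuplicated(key)) {
    stop_spzip("duplicate district x month record", "spzip_integrity_error")
  }
  df <- df[order(df$district, df$month_index), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("climate_panel", "data.frame")
  df
}

#' @rdname climate_panel
#' @param path CSV file path.
#' @export
read_climate_panel <- function(path) {
  if (!file.exists(path)) {
    stop_spzip(paste0("file not found: ", path), "spzip_io_error")
  }
  climate_panel(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname climate_panel
#' @param climate a `climate_panel`.
#' @export
write_climate_panel <- function(climate, path) {
  write.csv(as.data.frame(climate), path, row.names = FALSE)
  invisible(path)
}

#' Assemble the model design from panel, climate and altitude
#'
#' Joins district climate onto the stratified count panel (with the
#' requested per-variable lags), applies the covariate unit scalings
#' exactly once, and attaches the log-expected-count offset. Covariate
#' units follow the reporting convention of the model: altitude in 100 m
#' units, rainfall in 10 mm units, relative humidity in 10% units, maximum
#' temperature in deg C. Indicator coding: `age` = 1 for under-5 (5-14 is
#' the reference), `sex` = 1 for female (male is the reference). The
#' `trend` column is the raw 1-based month index; [fit_zip()] centres it
#' at its midpoint internally and reports the intercept back in the
#' uncentred frame.
#'
#' Applying a lag of `k` months means the covariate value for month `j` is
#' the district value at month `j - k`; the first `max(lags)` months are
#' dropped so every retained row has fully defined lagged covariates.
#'
#' @param panel a `count_panel`.
#' @param climate a `climate_panel` covering every district and month of
#'   the panel.
#' @param altitude named numeric vector of area altitudes in metres.
#' @param lags named integer vector of lags in months (0-3) for
#'   `rainfall`, `humidity`, `tempmax`.
#' @param expected optional per-row expected counts aligned with the
#'   validated panel; defaults to [expected_counts()] of the full panel
#'   (internal standardization, so the offsets sum to the observed total).
#' @return a `zip_design` data frame: stratum identifiers, indicator and
#'   scaled covariate columns, `expected`, `offset` = log(expected) and
#'   `cases`, with attribute `lags`. Passing a `zip_design` back in is an
#'   error (scaling is applied exactly once).
#' @export
assemble_design <- function(panel, climate, altitude,
                            lags = c(rainfall = 0, humidity = 3, tempmax = 0),
                            expected = NULL) {
  if (inherits(panel, "zip_design")) {
    stop_spzip("input is already an assembled design; scaling is applied exactly once",
               "spzip_invalid_argument")
  }
  panel <- count_panel(panel)
  climate <- climate_panel(climate)
  lag_def <- c(rainfall = 0, humidity = 3, tempmax = 0)
  lag_def[names(lags)] <- lags
  lags <- lag_def
  if (any(lags < 0 | lags > 3 | lags != round(lags))) {
    stop_spzip("lags must be integers in 0..3", "spzip_invalid_argument")
  }
  areas <- unique(panel$area)
  if (!all(areas %in% names(altitude))) {
    stop_spzip(paste0("area(s) with no altitude: ",
                      paste(setdiff(areas, names(altitude)), collapse = ", ")),
               "spzip_linkage_error")
  }
  n_months <- max(panel$month_index)
  dist_of <- panel$district[match(areas, panel$area)]
  need <- unique(dist_of)
  have <- unique(climate$district)
  if (!all(need %in% have)) {
    stop_spzip(paste0("district(s) with no climate: ",
                      paste(setdiff(need, have), collapse = ", ")),
               "spzip_linkage_error")
  }
  ckey <- paste(climate$district, climate$month_index, sep = "|")
  if (!all(paste(rep(need, each = n_months), rep(seq_len(n_months), length(need)),
                 sep = "|") %in% ckey)) {
    stop_spzip("climate does not cover every district x month of the panel",
               "spzip_linkage_error")
  }

  if (is.null(expected)) expected <- expected_counts(panel)
  if (length(expected) != nrow(panel) || any(expected <= 0)) {
    stop_spzip("expected must be positive and aligned with the panel rows",
               "spzip_invalid_argument")
  }

  lag_lookup <- function(var_col, k) {
    src_month <- panel$month_index - k
    idx <- match(paste(panel$district, src_month, sep = "|"), ckey)
    climate[[var_col]][idx]   # NA where src_month < 1
  }
  d <- data.frame(
    area = panel$area, district = panel$district,
    month_index = panel$month_index,
    age_group = panel$age_group, sex = panel$sex,
    cases = panel$cases, population = panel$population,
    age = as.integer(panel$age_group == "under5"),
    sexf = as.integer(panel$sex == "female"),
    trend = as.numeric(panel$month_index),
    altitude = unname(altitude[panel$area]) / 100,
    rainfall = lag_lookup("rainfall_mm", lags[["rainfall"]]) / 10,
    humidity = lag_lookup("rh_percent", lags[["humidity"]]) / 10,
    tempmax = lag_lookup("tmax_c", lags[["tempmax"]]),
    expected = expected,
    stringsAsFactors = FALSE)
  d$offset <- log(d$expected)
  keep <- d$month_index > max(lags)
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL
  message(sprintf("assemble_design: %d rows retained (%d dropped by lag truncation)",
                  nrow(d), sum(!keep)))
  attr(d, "lags") <- lags
  attr(d, "n_months") <- n_months
  class(d) <- c("zip_design", "data.frame")
  d
}
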