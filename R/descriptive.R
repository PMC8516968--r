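#' Incidence rate per population base
#'
#' `rate = per * cases / person_time`. Incidence is linear in cases and
#' inversely linear in person-time; tables conventionally report it to two
#' decimals (see [incidence_table()]).
#'
#' @param cases non-negative case total.
#' @param person_time positive person-time denominator (person-years for
#'   yearly tables).
#' @param per scaling base, default 1000.
#' @return the unrounded rate.
#' @examples
#' incidence(9204, 53147)  # 173.18 per 1000 once rounded
#' @export
incidence <- function(cases, person_time, per = 1000) {
  if (any(person_time <= 0)) {
    stop_spzip("person_time must be positive", "spzip_invalid_argument")
  }
  if (any(cases < 0)) {
    stop_spzip("cases must be non-negative", "spzip_invalid_argument")
  }
  per * cases / person_time
}

#' Yearly incidence table with overall rates
#'
#' Takes a yearly summary (one row per year x age group, with cases and
#' mid-year population) and returns per-year incidence plus an overall
#' rate per age group computed as total cases over summed person-years.
#'
#' @param yearly data frame with columns `year`, `age_group`, `cases`,
#'   `population`.
#' @param per scaling base, default 1000.
#' @param digits decimals for the reported rates, default 2.
#' @return list with `by_year` (the input plus an `incidence` column) and
#'   `overall` (per age group: total cases, person-years, incidence).
#' @export
incidence_table <- function(yearly, per = 1000, digits = 2) {
  stopifnot(all(c("year", "age_group", "cases", "population") %in% names(yearly)))
  yearly <- as.data.frame(yearly)
  yearly$incidence <- round(incidence(yearly$cases, yearly$population, per),
                            digits)
  agg_c <- tapply(yearly$cases, yearly$age_group, sum)
  agg_p <- tapply(yearly$population, yearly$age_group, sum)
  overall <- data.frame(age_group = names(agg_c),
                        cases = as.numeric(agg_c),
                        person_years = as.numeric(agg_p),
                        incidence = round(incidence(as.numeric(agg_c),
                                                    as.numeric(agg_p), per),
                                          digits),
                        stringsAsFactors = FALSE)
  rownames(overall) <- NULL
  list(by_year = yearly, overall = overall)
}

#' Crude standardized morbidity ratios by area
#'
#' For each area, `SMR_i = O_i / E_i` where `O_i` is the observed case
#' total over the whole study window and `E_i` is the expected total
#' obtained by applying the national rate (total cases over total
#' person-time) to the area's person-time - equivalently, the national
#' incidence times the area's average population times the study length.
#' Because the expectation is internally standardized, the
#' population-weighted mean SMR is exactly 1 (`sum O = sum E`). Areas with
#' zero expected count get `smr = NA` and `undefined = TRUE`.
#'
#' @param panel a `count_panel`.
#' @return data frame of class `smr_table`: `area`, `observed`,
#'   `expected`, `smr`, `undefined`.
#' @export
smr <- function(panel) {
  panel <- count_panel(panel)
  obs <- tapply(panel$cases, panel$area, sum)
  pm <- tapply(panel$population, panel$area, sum)  # person-months
  rate <- sum(panel$cases) / sum(panel$population)
  expected <- rate * pm
  out <- data.frame(area = names(obs),
                    observed = as.numeric(obs),
                    expected = as.numeric(expected),
                    stringsAsFactors = FALSE)
  out$undefined <- out$expected == 0
  out$smr <- ifelse(out$undefined, NA_real_, out$observed / out$expected)
  rownames(out) <- NULL
  class(out) <- c("smr_table", "data.frame")
  out
}

#' Seasonal-trend decomposition of a monthly count series
#'
#' Log-transforms the series (`log(y + log_offset)`, the offset guarding
#' against zero months) and decomposes it with loess-based STL into
#' seasonal, trend and remainder components satisfying the additive
#' identity `observed = seasonal + trend + remainder` exactly.
#'
#' @param series numeric vector of monthly counts, length at least two
#'   full periods.
#' @param period cycle length in months, default 12.
#' @param log_offset constant added before the log transform, default 1.
#' @param s_window seasonal loess window; the default `"periodic"`
#'   constrains the seasonal component to be identical across cycles.
#' @return data frame of class `stl_components` with columns `month`,
#'   `observed` (log scale), `seasonal`, `trend`, `remainder`; the period
#'   is kept as an attribute.
#' @export
stl_decompose <- function(series, period = 12, log_offset = 1,
                          s_window = "periodic") {
  if (length(series) < 2 * period) {
    stop_spzip("series must span at least two full periods",
               "spzip_invalid_argument")
  }
  if (any(series < 0)) {
    stop_spzip("series must be non-negative counts", "spzip_invalid_argument")
  }
  y <- log(series + log_offset)
  fit <- stl(ts(y, frequency = period), s.window = s_window)
  comp <- fit$time.series
  out <- data.frame(month = seq_along(series),
                    observed = as.numeric(y),
                    seasonal = as.numeric(comp[, "seasonal"]),
                    trend = as.numeric(comp[, "trend"]),
                    remainder = as.numeric(comp[, "remainder"]))
  attr(out, "period") <- period
  class(out) <- c("stl_components", "data.frame")
  out
}
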