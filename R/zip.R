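#' Zero-inflated Poisson log probability mass
#'
#' The ZIP mixture places probability `omega` on a structural zero and
#' `1 - omega` on a Poisson(`mu`) draw, so
#' `P(Y = 0) = omega + (1 - omega) exp(-mu)` and, for `y > 0`,
#' `P(Y = y) = (1 - omega) exp(-mu) mu^y / y!`. With `omega = 0` this is
#' exactly the Poisson pmf.
#'
#' @param y non-negative integer count(s).
#' @param mu positive Poisson mean(s).
#' @param omega structural-zero probability in `[0, 1]` (scalar or vector).
#' @return log probability, vectorized over the longest argument.
#' @examples
#' zip_logpmf(0, 2, 0.169)  # log(0.169 + 0.831 * exp(-2))
#' @export
zip_logpmf <- function(y, mu, omega) {
  n <- max(length(y), length(mu), length(omega))
  y <- rep_len(y, n); mu <- rep_len(mu, n); omega <- rep_len(omega, n)
  if (any(y < 0) || any(y != round(y))) {
    stop_spzip("y must be non-negative integers", "spzip_invalid_argument")
  }
  if (any(mu <= 0)) {
    stop_spzip("mu must be positive", "spzip_invalid_argument")
  }
  if (any(omega < 0 | omega > 1)) {
    stop_spzip("omega must lie in [0, 1]", "spzip_invalid_argument")
  }
  out <- numeric(n)
  z0 <- y == 0
  out[z0] <- log(omega[z0] + (1 - omega[z0]) * exp(-mu[z0]))
  if (any(!z0)) {
    out[!z0] <- log1p(-omega[!z0]) + dpois(y[!z0], mu[!z0], log = TRUE)
  }
  out
}

#' Expected counts under internal standardization
#'
#' Computes the per-stratum expected count used as the model offset:
#' the overall rate (total cases divided by total person-months across all
#' strata) times the stratum person-months. By construction the expected
#' counts sum exactly to the observed total, so the linear predictor acts
#' on the relative-risk scale.
#'
#' @param panel a `count_panel` (or data frame passing its validation).
#' @return numeric vector of expected counts aligned with the validated,
#'   deterministically ordered panel rows.
#' @export
expected_counts <- function(panel) {
  panel <- count_panel(panel)
  pt <- sum(panel$population)   # person-months: one row = one month
  if (pt <= 0) {
    stop_spzip("total person-time must be positive", "spzip_invalid_argument")
  }
  rate <- sum(panel$cases) / pt
  rate * panel$population
}

#' Evaluate the ZIP linear predictor over a design
#'
#' Computes, for every design row, the log relative risk
#' `theta = alpha + beta_age*age + beta_sex*sex + beta_trend*trend +
#' beta_altitude*altitude + beta_rainfall*rainfall +
#' beta_humidity*humidity + beta_tempmax*tempmax + u_i + s_i +
#' delta_i * (trend - trend_center)` and the Poisson mean
#' `mu = expected * exp(theta)`. The area random effects `u` (exchangeable),
#' `s` (spatially structured) and the area trend slopes `delta` default to
#' zero when absent from `state`; `delta` multiplies the centred trend so
#' that `delta_i = 0` is the national-average trend.
#'
#' @param state list with `alpha` (scalar), `beta` (vector named with any
#'   of `age`, `sex`, `trend`, `altitude`, `rainfall`, `humidity`,
#'   `tempmax`), and optionally `u`, `s`, `delta` (named by area id, or
#'   unnamed in the order of `sort(unique(design$area))`) and
#'   `trend_center` (defaults to `mean(design$trend)`).
#' @param design a `zip_design` from [assemble_design()].
#' @return list with `theta` and `mu` vectors aligned with `design`.
#' @export
linear_predictor <- function(state, design) {
  stopifnot(is.data.frame(design))
  areas <- sort(unique(design$area))
  get_effect <- function(x) {
    if (is.null(x)) return(numeric(length(areas)))
    if (!is.null(names(x))) {
      if (!all(areas %in% names(x))) {
        stop_spzip("effect vector does not cover all areas",
                   "spzip_invalid_argument")
      }
      return(unname(x[areas]))
    }
    if (length(x) != length(areas)) {
      stop_spzip("effect vector length must equal the number of areas",
                 "spzip_invalid_argument")
    }
    x
  }
  beta <- state$beta %||% numeric(0)
  bval <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
  tc <- state$trend_center %||% mean(design$trend)
  ai <- match(design$area, areas)
  u <- get_effect(state$u); s <- get_effect(state$s)
  delta <- get_effect(state$delta)
  theta <- (state$alpha %||% 0) +
    bval("age") * design$age + bval("sex") * design$sexf +
    bval("trend") * design$trend + bval("altitude") * design$altitude +
    bval("rainfall") * design$rainfall + bval("humidity") * design$humidity +
    bval("tempmax") * design$tempmax +
    u[ai] + s[ai] + delta[ai] * (design$trend - tc)
  list(theta = theta, mu = design$expected * exp(theta))
}
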