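#' Ground-truth parameter set for the ZIP generative model
#'
#' Bundles the parameters of the generative ZIP spatio-temporal model:
#' intercept, covariate coefficients (on the unit-scaled covariates),
#' structural-zero probability, per-area random effects and per-area trend
#' slopes. The defaults describe a childhood-pneumonia-like surveillance
#' process: a roughly 14-fold higher risk in under-5s than 5-14s, a small
#' female deficit, a slow monthly decline, weak climate effects, about 17%
#' structural zeros, substantial unexplained area heterogeneity (variance
#' 1.694 on the log-risk scale) and modest area-to-area spread in trend
#' slopes (sd 0.003 per month, commensurate with the mean trend itself).
#'
#' Area effects not supplied are drawn here: `u` exchangeable
#' `N(0, sigma_u^2)`; `s` and `delta` from the ICAR prior over `graph`
#' when a graph is given (sum-to-zero on each connected component),
#' otherwise exchangeable Gaussians recentred to mean zero. `s` and
#' `delta` always satisfy the sum-to-zero identifiability convention.
#'
#' @param n_areas number of areas (ignored if `graph` given).
#' @param graph optional `adjacency_graph` used to draw spatially
#'   structured `s` and `delta`.
#' @param alpha intercept on the log relative-risk scale.
#' @param beta named coefficient vector for `age`, `sex`, `trend`,
#'   `altitude`, `rainfall`, `humidity`, `tempmax` (units: indicator,
#'   indicator, month, 100 m, 10 mm, 10%, deg C).
#' @param omega structural-zero probability in `[0, 1]`.
#' @param sigma_u marginal sd of the unstructured effects (0 disables).
#' @param sigma_s pairwise-difference sd of the structured effects
#'   (0 disables).
#' @param sigma_delta sd of the area trend slopes per month (0 disables).
#' @param u,s,delta optional explicit per-area vectors overriding the
#'   draws.
#' @return list of class `ground_truth` with elements `alpha`, `beta`,
#'   `omega`, `u`, `s`, `delta`, `tau_u`, `tau_s`, `tau_w`.
#' @export
ground_truth <- function(n_areas,
                         graph = NULL,
                         alpha = -2.28,
                         beta = c(age = 2.658, sex = -0.120,
                                  trend = -3.43e-3, altitude = 1.32e-5,
                                  rainfall = 7.67e-4, humidity = -1.25e-3,
                                  tempmax = 1.31e-2),
                         omega = 0.169,
                         sigma_u = sqrt(1.694),
                         sigma_s = 0,
                         sigma_delta = 0.003,
                         u = NULL, s = NULL, delta = NULL) {
  if (!is.null(graph)) n_areas <- length(graph$ids)
  stopifnot(n_areas >= 1)
  if (omega < 0 || omega > 1) {
    stop_spzip("omega must lie in [0, 1]", "spzip_invalid_argument")
  }
  draw_structured <- function(sigma) {
    if (sigma <= 0) return(numeric(n_areas))
    if (!is.null(graph)) {
      sample_icar(graph, 1 / sigma^2)
    } else {
      x <- rnorm(n_areas, 0, sigma)
      x - mean(x)
    }
  }
  if (is.null(u)) u <- if (sigma_u > 0) rnorm(n_areas, 0, sigma_u) else numeric(n_areas)
  if (is.null(s)) s <- draw_structured(sigma_s)
  if (is.null(delta)) {
    if (sigma_delta <= 0) {
      delta <- numeric(n_areas)
    } else if (!is.null(graph) && sigma_s > 0) {
      delta <- sample_icar(graph, 1 / sigma_delta^2)
    } else {
      delta <- rnorm(n_areas, 0, sigma_delta)
      delta <- delta - mean(delta)
    }
  }
  for (v in list(u, s, delta)) {
    if (length(v) != n_areas) {
      stop_spzip("u, s and delta must have one entry per area",
                 "spzip_invalid_argument")
    }
  }
  s <- s - mean(s)
  delta <- delta - mean(delta)
  structure(list(alpha = alpha, beta = beta, omega = omega,
                 u = u, s = s, delta = delta,
                 tau_u = if (sigma_u > 0) 1 / sigma_u^2 else Inf,
                 tau_s = if (sigma_s > 0) 1 / sigma_s^2 else Inf,
                 tau_w = if (sigma_delta > 0) 1 / sigma_delta^2 else Inf),
            class = "ground_truth")
}

#' Write / read a ground truth as YAML
#' @param truth a `ground_truth`.
#' @param path YAML file path.
#' @return [read_ground_truth()] returns a `ground_truth`;
#'   [write_ground_truth()] returns `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  x$beta <- as.list(x$beta)   # keep coefficient names as a YAML map
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- yaml::read_yaml(path)
  x$beta <- unlist(x$beta)
  structure(x, class = "ground_truth")
}

#' Simulate district-level monthly climate
#'
#' Generates seasonal climate series shared by all areas of a district:
#' maximum temperature as an annual sinusoid (period 12 months) plus
#' Gaussian noise, relative humidity as an offset sinusoid clamped to
#' `[0, 100]`%, rainfall as an exponentiated sinusoid (non-negative,
#' monsoon-like peaks), and minimum temperature trailing the maximum.
#' Districts differ by small random phase and level offsets. With all
#' noise standard deviations zero the series are exactly 12-periodic.
#'
#' @param geography a `lattice_geography` (or list with `district_of`).
#' @param n_months number of months to simulate.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param tmax_mean,tmax_amp,tmax_sd maximum-temperature level (deg C),
#'   seasonal amplitude and noise sd.
#' @param rh_mean,rh_amp,rh_sd relative-humidity level (%), amplitude and
#'   noise sd.
#' @param rain_log_mean,rain_log_amp,rain_log_sd log-rainfall level
#'   (log mm), amplitude and noise sd.
#' @return a `climate_panel`.
#' @export
simulate_climate <- function(geography, n_months, seed = NULL,
                             tmax_mean = 20, tmax_amp = 7, tmax_sd = 1,
                             rh_mean = 70, rh_amp = 15, rh_sd = 3,
                             rain_log_mean = 4, rain_log_amp = 1.5,
                             rain_log_sd = 0.3) {
  if (n_months < 1) {
    stop_spzip("n_months must be at least 1", "spzip_invalid_argument")
  }
  if (!is.null(seed)) set.seed(seed)
  districts <- unique(unname(geography$district_of))
  rows <- list()
  for (d in districts) {
    phase <- runif(1, -0.3, 0.3)
    lvl_t <- rnorm(1, 0, 1.5)
    lvl_r <- rnorm(1, 0, 0.2)
    m <- seq_len(n_months)
    ang_t <- 2 * pi * (m - 4) / 12 + phase
    ang_w <- 2 * pi * (m - 7) / 12 + phase
    tmax <- tmax_mean + lvl_t + tmax_amp * sin(ang_t) +
      rnorm(n_months, 0, tmax_sd)
    rh <- rh_mean + rh_amp * sin(ang_w) + rnorm(n_months, 0, rh_sd)
    rh <- pmin(100, pmax(0, rh))
    rain <- exp(rain_log_mean + lvl_r + rain_log_amp * sin(ang_w) +
                  rnorm(n_months, 0, rain_log_sd))
    rows[[d]] <- data.frame(district = d, month_index = m,
                            rainfall_mm = rain, rh_percent = rh,
                            tmin_c = tmax - 10 - 2 * abs(sin(ang_t)),
                            tmax_c = tmax, stringsAsFactors = FALSE)
  }
  climate_panel(do.call(rbind, rows))
}

#' Simulate stratified area populations
#'
#' Draws a log-normal child population per area and splits it 30% / 70%
#' between the under-5 and 5-14 age groups, each half male / half female -
#' the approximate age split seen in national child-population tables.
#' Populations are held constant over months (yearly denominators are
#' interpolated as constant within the year).
#'
#' @param geography a `lattice_geography`.
#' @param mean_pop median child population per area, default 900.
#' @param sdlog log-scale sd of area sizes, default 0.5.
#' @param seed optional integer seed.
#' @return data frame with `area`, `age_group`, `sex`, `population`.
#' @export
simulate_populations <- function(geography, mean_pop = 900, sdlog = 0.5,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  areas <- geography$areas
  tot <- rlnorm(length(areas), log(mean_pop), sdlog)
  grid <- expand.grid(area = areas, age_group = AGE_LEVELS, sex = SEX_LEVELS,
                      stringsAsFactors = FALSE)
  share <- ifelse(grid$age_group == "under5", 0.30, 0.70) * 0.5
  grid$population <- tot[match(grid$area, areas)] * share
  grid[order(grid$area, match(grid$age_group, AGE_LEVELS),
             match(grid$sex, SEX_LEVELS)), , drop = FALSE]
}

#' Simulate per-area altitude
#'
#' One draw per area, uniform between 75 m and 7000 m (a Himalayan
#' altitude span); the design matrix later scales it to 100 m units.
#'
#' @param geography a `lattice_geography`.
#' @param seed optional integer seed.
#' @return named numeric vector of altitudes in metres.
#' @export
simulate_altitude <- function(geography, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  setNames(runif(length(geography$areas), 75, 7000), geography$areas)
}

#' Simulate ZIP counts from ground truth
#'
#' Generative inversion of the fitted model: for each area x month x age x
#' sex stratum the log relative risk `theta` is computed from the ground
#' truth over the unit-scaled covariates (humidity entering with the
#' fitting lag, clamped to month 1 for the first `lag` months, which the
#' model fit later drops anyway), the Poisson mean is
#' `mu = E * exp(theta)` with `E = base_rate * population` person-months,
#' a structural zero is drawn with probability `omega`, and otherwise the
#' count is Poisson(`mu`). The realized latent structural-zero indicators
#' are returned for test introspection; they are never observable in real
#' surveillance data.
#'
#' @param geography a `lattice_geography`.
#' @param climate a `climate_panel` covering all months.
#' @param populations data frame from [simulate_populations()] (columns
#'   `area`, `age_group`, `sex`, `population`).
#' @param altitude named numeric vector of altitudes in metres.
#' @param truth a `ground_truth`.
#' @param n_months number of months to simulate (defaults to the full
#'   climate window).
#' @param base_rate baseline incidence per person-month used to form the
#'   generative expected counts; the default 0.0032 yields a zero fraction
#'   around 72% at the default ground truth.
#' @param lags per-variable lags used in the generative predictor,
#'   matching the default fitting lags.
#' @param seed optional integer seed.
#' @return list of class `zip_simulation`: `panel` (a `count_panel`),
#'   `latent` (0/1 structural-zero indicators aligned with the panel
#'   rows), `theta`, `mu`, `expected`, and the `truth` used.
#' @export
simulate_counts <- function(geography, climate, populations, altitude,
                            truth, n_months = max(climate$month_index),
                            base_rate = 0.0032,
                            lags = c(rainfall = 0, humidity = 3, tempmax = 0),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  climate <- climate_panel(climate)
  if (max(climate$month_index) < n_months) {
    stop_spzip("climate does not cover all requested months",
               "spzip_invalid_argument")
  }
  areas <- geography$areas
  if (length(truth$u) != length(areas)) {
    stop_spzip("truth dimensions do not match the geography",
               "spzip_invalid_argument")
  }
  if (!all(areas %in% populations$area)) {
    stop_spzip("populations do not cover all areas", "spzip_invalid_argument")
  }
  grid <- expand.grid(sex = SEX_LEVELS, age_group = AGE_LEVELS,
                      month_index = seq_len(n_months), area = areas,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("area", "month_index", "age_group", "sex")]
  grid$district <- unname(geography$district_of[grid$area])
  pkey <- paste(populations$area, populations$age_group, populations$sex,
                sep = "|")
  grid$population <- populations$population[
    match(paste(grid$area, grid$age_group, grid$sex, sep = "|"), pkey)]

  ckey <- paste(climate$district, climate$month_index, sep = "|")
  clim_at <- function(col, lag) {
    src <- pmax(1L, grid$month_index - lag)  # clamp: months <= lag reuse month 1
    climate[[col]][match(paste(grid$district, src, sep = "|"), ckey)]
  }
  expected <- base_rate * grid$population
  tc <- (n_months + 1) / 2
  ai <- match(grid$area, areas)
  beta <- truth$beta
  theta <- truth$alpha +
    beta[["age"]] * (grid$age_group == "under5") +
    beta[["sex"]] * (grid$sex == "female") +
    beta[["trend"]] * grid$month_index +
    beta[["altitude"]] * altitude[grid$area] / 100 +
    beta[["rainfall"]] * clim_at("rainfall_mm", lags[["rainfall"]]) / 10 +
    beta[["humidity"]] * clim_at("rh_percent", lags[["humidity"]]) / 10 +
    beta[["tempmax"]] * clim_at("tmax_c", lags[["tempmax"]]) +
    truth$u[ai] + truth$s[ai] + truth$delta[ai] * (grid$month_index - tc)
  theta <- unname(theta)
  mu <- expected * exp(theta)
  n <- nrow(grid)
  z <- rbinom(n, 1L, truth$omega)
  y <- ifelse(z == 1L, 0L, rpois(n, mu))
  panel <- count_panel(data.frame(
    area = grid$area, district = grid$district,
    month_index = grid$month_index, age_group = grid$age_group,
    sex = grid$sex, cases = as.integer(y), population = grid$population,
    stringsAsFactors = FALSE))
  # reorder the latent draws to the panel's deterministic row order
  key_sim <- paste(grid$area, grid$month_index, grid$age_group, grid$sex,
                   sep = "|")
  key_pan <- paste(panel$area, panel$month_index, panel$age_group, panel$sex,
                   sep = "|")
  ord <- match(key_pan, key_sim)
  structure(list(panel = panel, latent = z[ord], theta = theta[ord],
                 mu = mu[ord], expected = expected[ord], truth = truth),
            class = "zip_simulation")
}
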