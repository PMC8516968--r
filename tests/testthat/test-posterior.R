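# a minimal hand-made fit object with point-mass coefficient draws
point_mass_fit <- function(coefs, n = 200) {
  m <- matrix(rep(c(0, unname(coefs), 0, 100), each = n), nrow = n)
  colnames(m) <- c("alpha", paste0("beta_", names(coefs)), "omega",
                   "deviance")
  structure(list(draws = list(m), trend_center = 0,
                 areas = character(0), has_u = FALSE, has_s = FALSE,
                 has_delta = FALSE, sample_omega = TRUE,
                 covariates = names(coefs)),
            class = "zip_fit")
}

test_that("point-mass coefficients transform to the published relative risks", {
  fit <- point_mass_fit(c(age = 2.658, sex = -0.120, trend = -3.43e-3))
  s <- summarize_posterior(fit)
  expect_equal(round(s$rr[s$parameter == "beta_age"], 3), 14.268)
  expect_equal(round(s$rr[s$parameter == "beta_sex"], 3), 0.887)
  expect_equal(round(s$rr[s$parameter == "beta_trend"], 4), 0.9966)
  # a zero coefficient is RR 1 and not significant
  s0 <- summarize_posterior(point_mass_fit(c(age = 0)))
  expect_equal(s0$rr[s0$parameter == "beta_age"], 1)
  expect_false(s0$significant[s0$parameter == "beta_age"])
})

test_that("credible intervals are exp-equivariant, nested and flag significance", {
  set.seed(13)
  draws <- rnorm(4000, 0.4, 0.1)
  m <- cbind(alpha = 0, beta_age = draws, omega = 0.1, deviance = 100)
  fit <- structure(list(draws = list(m), trend_center = 0,
                        areas = character(0), has_u = FALSE, has_s = FALSE,
                        has_delta = FALSE, sample_omega = TRUE,
                        covariates = "age"),
                   class = "zip_fit")
  s95 <- summarize_posterior(fit, level = 0.95)
  s90 <- summarize_posterior(fit, level = 0.90)
  r <- function(tab, col) tab[tab$parameter == "beta_age", col]
  # CrI of exp(beta) is exactly exp of CrI of beta (quantile equivariance)
  expect_equal(r(s95, "rr_lower"), exp(r(s95, "lower")), tolerance = 1e-12)
  expect_equal(r(s95, "rr_upper"), exp(r(s95, "upper")), tolerance = 1e-12)
  # 90% interval nests inside the 95%
  expect_gt(r(s90, "lower"), r(s95, "lower"))
  expect_lt(r(s90, "upper"), r(s95, "upper"))
  # interval excludes 1 -> significant
  expect_true(r(s95, "significant"))
})

test_that("trend classification is driven by exceedance probabilities", {
  mk <- function(draws_by_area) {
    cols <- do.call(cbind, draws_by_area)
    colnames(cols) <- paste0("delta_", names(draws_by_area))
    m <- cbind(alpha = 0, cols, deviance = 100)
    structure(list(draws = list(m), trend_center = 0,
                   areas = names(draws_by_area), has_u = FALSE,
                   has_s = FALSE, has_delta = TRUE, sample_omega = FALSE,
                   covariates = character(0)),
              class = "zip_fit")
  }
  set.seed(14)
  fit <- mk(list(a1 = abs(rnorm(500)) + 0.01,      # all positive
                 a2 = rnorm(500),                   # symmetric about 0
                 a3 = -abs(rnorm(500)) - 0.01))     # all negative
  tc <- classify_trends(fit)
  expect_equal(tc$class, c("above", "indeterminate", "below"))
  expect_equal(tc$p_above[1], 1)
  expect_lt(abs(tc$p_above[2] - 0.5), 0.1)
  # label-permutation equivariance
  fit_perm <- mk(list(a3 = -abs(rnorm(500)) - 0.01,
                      a1 = abs(rnorm(500)) + 0.01,
                      a2 = rnorm(500)))
  tc_perm <- classify_trends(fit_perm)
  expect_equal(tc_perm$class[match(tc$area, tc_perm$area)], tc$class)
})

test_that("known area trends are recovered and classified from data", {
  # 5 areas rising at +0.02/month, 5 falling at -0.02, 10 flat; a 72-month
  # window gives the +-0.02 slopes enough leverage to be detectable
  geo <- make_lattice(4, 5, 2)
  cl <- simulate_climate(geo, 72, seed = 15)
  pop <- simulate_populations(geo, seed = 16)
  alt <- simulate_altitude(geo, seed = 17)
  delta_true <- c(rep(0.02, 5), rep(-0.02, 5), rep(0, 10))
  delta_true <- delta_true - mean(delta_true)
  set.seed(18)
  tr <- ground_truth(20, sigma_u = 0.5, delta = delta_true)
  sim <- simulate_counts(geo, cl, pop, alt, tr, seed = 19)
  d <- quiet_design(sim$panel, cl, alt)
  fit <- quiet_fit(d, variant = "I", config = mcmc_config(1000, 6000, 3, 2),
                   seed = 20)
  tc <- classify_trends(fit)
  # areas are ordered lexicographically (a1, a10, a11, ..., a9)
  truth_by_area <- setNames(delta_true, geo$areas)[tc$area]
  hits <- sum(tc$class[truth_by_area > 0.01] == "above") +
    sum(tc$class[truth_by_area < -0.01] == "below")
  expect_gte(hits, 8)
})

test_that("random-effect maps join, export and round-trip exactly", {
  geo <- make_lattice(2, 2, 1)
  m <- cbind(alpha = 0,
             u_a1 = rep(log(2), 300), u_a2 = 0, u_a3 = -0.5, u_a4 = 0.25,
             tau_u = 1, deviance = 10)
  fit <- structure(list(draws = list(m), trend_center = 0,
                        areas = paste0("a", 1:4), has_u = TRUE,
                        has_s = FALSE, has_delta = FALSE,
                        sample_omega = FALSE, covariates = character(0)),
                   class = "zip_fit")
  path <- tempfile(fileext = ".geojson")
  fc <- map_random_effects(fit, geo, path = path)
  props <- fc$features[[1]]$properties
  expect_equal(props$re_mean, 2)          # point mass at log 2
  expect_equal(props$re_exceed, 1)
  p2 <- fc$features[[2]]$properties
  expect_equal(p2$re_mean, 1)             # draws all 0
  expect_equal(p2$re_exceed, 0.5)         # degenerate ties split evenly
  # written file re-reads with identical property values
  gj <- read_geojson(path)
  expect_equal(gj$features[[1]]$properties$re_mean, 2, tolerance = 1e-12)
  expect_equal(gj$features[[4]]$properties$re_mean, exp(0.25),
               tolerance = 1e-12)
  # unmatched ids are a join error
  fit$areas <- c(fit$areas[-1], "zz")
  colnames(fit$draws[[1]])[2:5] <- paste0("u_", fit$areas)
  expect_error(map_random_effects(fit, geo), class = "spzip_join_error")
})
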