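# small intercept-only design used by several sampler checks
conjugate_design <- function(n = 100, theta = 0.3, seed = 71,
                             n_area = 1) {
  set.seed(seed)
  n_months <- n / (4 * n_area)
  p <- toy_panel(n_area, n_months)
  p$cases <- rpois(nrow(p), exp(theta) * 2)
  p <- count_panel(as.data.frame(p))
  cl <- flat_climate("d1", n_months)
  alt <- setNames(rep(500, n_area), paste0("a", seq_len(n_area)))
  quiet_design(p, cl, alt, lags = c(humidity = 0),
               expected = rep(2, nrow(p)))
}

test_that("a degenerate run with no retained draws is rejected", {
  expect_error(mcmc_config(burnin = 100, iterations = 100),
               class = "spzip_invalid_argument")
  d <- conjugate_design(40, n_area = 1)
  expect_error(fit_zip(d, variant = "II", config = mcmc_config(10, 20, 1, 1)),
               regexp = "adjacency", class = "spzip_invalid_argument")
})

test_that("MCMC posterior of the intercept matches a quadrature oracle", {
  # Poisson submodel: omega fixed at 0, no random effects, intercept only.
  # Flat prior => posterior density for alpha is proportional to
  # exp(alpha * sum(y) - e^alpha * sum(E)); integrate it numerically.
  d <- conjugate_design(100, theta = 0.3)
  fit <- quiet_fit(d, variant = "null", config = mcmc_config(1000, 9000, 2, 2),
                   seed = 5, omega_fixed = 0, covariates = character(0))
  draws <- unlist(lapply(fit$draws, function(m) m[, "alpha"]))

  sy <- sum(d$cases); sE <- sum(d$expected)
  grid <- seq(-2, 2, length.out = 20001)
  logpost <- grid * sy - exp(grid) * sE
  w <- exp(logpost - max(logpost)); w <- w / sum(w)
  post_mean <- sum(grid * w)
  post_sd <- sqrt(sum((grid - post_mean)^2 * w))

  ess <- sum(vapply(fit$draws, function(m) effective_size(m[, "alpha"]), 0))
  mcse <- sd(draws) / sqrt(ess)
  expect_lt(abs(mean(draws) - post_mean), 2 * mcse + 1e-4)
  expect_equal(sd(draws), post_sd, tolerance = 0.1)
})

test_that("structural-zero augmentation matches the analytic posterior", {
  # fixed omega: the Gibbs step for z at an observed zero is Bernoulli
  # with p = omega / (omega + (1 - omega) e^{-mu}); the retained-draw
  # frequency of z = 1 must match it at the posterior-mean mu
  d <- conjugate_design(200, theta = 0.1, seed = 81)
  fit <- quiet_fit(d, variant = "null", config = mcmc_config(1000, 11000, 2, 1),
                   seed = 6, omega_fixed = 0.3, covariates = character(0))
  a_hat <- mean(fit$draws[[1]][, "alpha"])
  mu_hat <- d$expected * exp(a_hat)
  zero <- d$cases == 0
  p_analytic <- 0.3 / (0.3 + 0.7 * exp(-mu_hat[zero]))
  expect_true(all(fit$zbar[!zero] == 0))
  expect_lt(max(abs(fit$zbar[zero] - p_analytic)), 0.05)
})

test_that("omega posterior matches Beta conjugacy when zeros are separable", {
  # make mu huge so Poisson zeros are impossible: every observed zero is
  # structural and omega | data ~ Beta(1 + n0, 1 + n - n0)
  d <- conjugate_design(200, theta = 0.1, seed = 91)
  d$expected <- rep(50, nrow(d))
  d$offset <- log(d$expected)
  set.seed(92)
  zstruct <- rbinom(nrow(d), 1, 0.25)
  d$cases <- ifelse(zstruct == 1, 0L, rpois(nrow(d), 50))
  fit <- quiet_fit(d, variant = "null", config = mcmc_config(500, 8000, 3, 1),
                   seed = 7, covariates = character(0))
  n0 <- sum(d$cases == 0); n <- nrow(d)
  omega_draws <- fit$draws[[1]][, "omega"]
  expect_equal(mean(omega_draws), (1 + n0) / (2 + n), tolerance = 0.02)
  expect_equal(sd(omega_draws),
               sqrt((1 + n0) * (1 + n - n0) / ((2 + n)^2 * (3 + n))),
               tolerance = 0.2)
})

test_that("marginal ZIP deviance stored by the sampler matches direct arithmetic", {
  # 50-stratum toy: recompute the deviance of stored draws analytically
  d <- conjugate_design(48, theta = 0.2, seed = 93)
  fit <- quiet_fit(d, variant = "null", config = mcmc_config(200, 1200, 2, 1),
                   seed = 8, covariates = character(0))
  m <- fit$draws[[1]]
  for (r in c(1, 50, 250, 500)) {
    mu <- d$expected * exp(m[r, "alpha"])
    dev <- -2 * sum(zip_logpmf(d$cases, mu, m[r, "omega"]))
    expect_equal(unname(m[r, "deviance"]), dev, tolerance = 1e-8)
  }
})

test_that("DIC is Dbar for a point-mass posterior and ~1 effective parameter
           for the intercept-only Poisson model", {
  d <- conjugate_design(100, theta = 0.3)
  fit <- quiet_fit(d, variant = "null", config = mcmc_config(1000, 11000, 2, 2),
                   seed = 9, omega_fixed = 0, covariates = character(0))
  out <- dic(fit)
  # one free parameter => pD close to 1
  expect_equal(out$p_d, 1, tolerance = 0.1)
  expect_equal(out$dic, out$dbar + out$p_d, tolerance = 1e-12)

  # collapse the chains to a point mass: pD = 0 and DIC = Dbar exactly
  fit2 <- fit
  a_bar <- mean(unlist(lapply(fit$draws, function(m) m[, "alpha"])))
  mu <- d$expected * exp(a_bar)
  dev <- -2 * sum(zip_logpmf(d$cases, mu, 0))
  for (ch in seq_along(fit2$draws)) {
    m <- fit2$draws[[ch]]
    m[, "alpha"] <- a_bar
    m[, "deviance"] <- dev
    fit2$draws[[ch]] <- m
  }
  out2 <- dic(fit2)
  expect_equal(out2$p_d, 0, tolerance = 1e-9)
  expect_equal(out2$dic, out2$dbar, tolerance = 1e-9)
})

test_that("dic refuses short or broken chains", {
  d <- conjugate_design(48, theta = 0, seed = 94)
  fit <- quiet_fit(d, variant = "null", config = mcmc_config(100, 200, 2, 1),
                   seed = 10, covariates = character(0))
  expect_error(dic(fit), class = "spzip_invalid_argument")
})
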