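#' Univariable Poisson screen of one covariate
#'
#' Fits a maximum-likelihood Poisson regression with log link,
#' `cases ~ covariate` plus a log-expected-count offset, and reports the
#' slope, its Wald standard error and p-value, and the model AIC
#' (`2k - 2 logL` with `k = 2`). This is the screening fit applied to each
#' candidate climate/altitude covariate at each lag.
#'
#' @param cases non-negative integer counts per stratum.
#' @param covariate numeric covariate values (already unit-scaled); must
#'   take at least two distinct values.
#' @param offset log expected counts per stratum.
#' @return list with `coefficient`, `se`, `p_value`, `aic`, `loglik`.
#' @export
univariable_poisson <- function(cases, covariate, offset) {
  if (length(unique(covariate)) < 2) {
    stop_spzip("covariate must take at least two distinct values",
               "spzip_invalid_argument")
  }
  df <- data.frame(y = cases, x = covariate, off = offset)
  fit <- glm(y ~ x + offset(off), family = poisson(), data = df)
  if (!fit$converged) {
    stop_spzip(paste0("Poisson screening fit did not converge after ",
                      fit$iter, " IRLS iterations"),
               "spzip_fit_error")
  }
  sm <- summary(fit)$coefficients
  list(coefficient = unname(sm["x", "Estimate"]),
       se = unname(sm["x", "Std. Error"]),
       p_value = unname(sm["x", "Pr(>|z|)"]),
       aic = AIC(fit),
       loglik = as.numeric(logLik(fit)))
}

#' Screen climate covariates over a lag grid
#'
#' Builds, for each candidate variable and each lag in `lags`, the design
#' with only that lag applied, runs [univariable_poisson()], and returns
#' the screening grid ready for [select_lags()].
#'
#' @param panel a `count_panel`.
#' @param climate a `climate_panel`.
#' @param altitude named numeric vector of area altitudes in metres.
#' @param variables character subset of
#'   `c("rainfall", "humidity", "tempmax", "altitude")`.
#' @param lags integer lags to scan, default `0:3` (altitude, which does
#'   not vary in time, is screened at lag 0 only).
#' @return data frame of class `screen_result`: `variable`, `lag`,
#'   `coefficient`, `se`, `p_value`, `aic`.
#' @export
screen_covariates <- function(panel, climate, altitude,
                              variables = c("rainfall", "humidity",
                                            "tempmax", "altitude"),
                              lags = 0:3) {
  panel <- count_panel(panel)
  rows <- list()
  for (v in variables) {
    vlags <- if (v == "altitude") 0L else as.integer(lags)
    for (k in vlags) {
      lg <- c(rainfall = 0, humidity = 0, tempmax = 0)
      if (v %in% names(lg)) lg[[v]] <- k
      d <- suppressMessages(assemble_design(panel, climate, altitude, lags = lg))
      # drop max(lags) months uniformly so AICs are comparable across lags
      d <- d[d$month_index > max(lags), , drop = FALSE]
      f <- univariable_poisson(d$cases, d[[v]], d$offset)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, lag = k, coefficient = f$coefficient, se = f$se,
        p_value = f$p_value, aic = f$aic, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Select covariate lags from a screening grid
#'
#' A variable is retained only if some lag reaches `p < alpha`; among its
#' significant lags the one with the lowest AIC is kept, ties broken
#' toward the smaller lag. Time-invariant variables (a single lag-0 row)
#' follow the same rule.
#'
#' @param results a `screen_result` (or data frame with `variable`, `lag`,
#'   `p_value`, `aic`); the lag grid must be complete (every lag in
#'   `lag_grid`) for each time-varying variable.
#' @param alpha significance threshold, default 0.05.
#' @param lag_grid lags required for completeness, default `0:3`.
#' @return data frame with one row per retained variable: `variable`,
#'   `lag`, `coefficient` (if present), `p_value`, `aic`.
#' @export
select_lags <- function(results, alpha = 0.05, lag_grid = 0:3) {
  stopifnot(all(c("variable", "lag", "p_value", "aic") %in% names(results)))
  out <- list()
  for (v in unique(results$variable)) {
    r <- results[results$variable == v, , drop = FALSE]
    if (nrow(r) > 1L && !setequal(r$lag, lag_grid)) {
      stop_spzip(sprintf("incomplete lag grid for '%s': have {%s}, need {%s}",
                         v, paste(sort(r$lag), collapse = ","),
                         paste(lag_grid, collapse = ",")),
                 "spzip_invalid_argument")
    }
    sig <- r[r$p_value < alpha, , drop = FALSE]
    if (nrow(sig) == 0L) next
    sig <- sig[order(sig$aic, sig$lag), , drop = FALSE]
    out[[length(out) + 1L]] <- sig[1L, , drop = FALSE]
  }
  if (!length(out)) {
    res <- results[0, , drop = FALSE]
  } else {
    res <- do.call(rbind, out)
  }
  rownames(res) <- NULL
  as.data.frame(res)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` is the coefficient of
#' determination from regressing covariate `k` on all the others (with an
#' intercept). A perfectly collinear column yields `Inf` rather than an
#' error. VIF is invariant to affine rescaling of any single covariate.
#'
#' @param design numeric matrix or data frame of covariates (no intercept
#'   column, no constant column), more rows than columns.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) <= ncol(X)) {
    stop_spzip("need more rows than covariates", "spzip_invalid_argument")
  }
  if (any(apply(X, 2, function(c) length(unique(c)) < 2))) {
    stop_spzip("constant covariate column", "spzip_invalid_argument")
  }
  if (ncol(X) < 2) return(setNames(1, colnames(X)))
  out <- vapply(seq_len(ncol(X)), function(k) {
    fit <- lm(X[, k] ~ X[, -k, drop = FALSE])
    # a perfect fit is a handled outcome (infinite VIF), not a warning
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}
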