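#' Posterior summary table with relative risks
#'
#' For every scalar parameter: posterior mean and equal-tailed credible
#' interval. Coefficient rows additionally carry relative-risk summaries
#' computed on the exp-transformed draws (so the RR interval endpoints are
#' exactly the exponentials of the coefficient interval endpoints -
#' quantile transform equivariance) and a significance flag: an RR
#' credible interval excluding 1. The intercept is reported in the
#' uncentred trend frame (`alpha - beta_trend * mean(trend)`).
#'
#' @param fit a `zip_fit` with at least 100 retained draws.
#' @param level credible level, default 0.95.
#' @return data frame of class `posterior_summary`: `parameter`, `mean`,
#'   `lower`, `upper`, `rr`, `rr_lower`, `rr_upper`, `significant`.
#' @export
summarize_posterior <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "zip_fit"))
  all_draws <- do.call(rbind, fit$draws)
  if (nrow(all_draws) < 100) {
    stop_spzip("need at least 100 retained draws", "spzip_invalid_argument")
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  pars <- setdiff(colnames(all_draws), "deviance")
  get <- function(p) all_draws[, p]

  # intercept back in the uncentred trend frame
  if ("beta_trend" %in% pars) {
    all_draws[, "alpha"] <- all_draws[, "alpha"] -
      all_draws[, "beta_trend"] * fit$trend_center
  }
  rows <- lapply(pars, function(p) {
    x <- get(p)
    q <- unname(quantile(x, probs))
    is_beta <- grepl("^beta_", p)
    if (is_beta) {
      rr <- exp(x)
      # endpoints via the monotone transform: CrI(exp b) = exp(CrI(b))
      rq <- exp(q)
      sig <- rq[1] > 1 || rq[2] < 1
      data.frame(parameter = p, mean = mean(x), lower = q[1], upper = q[2],
                 rr = mean(rr), rr_lower = rq[1], rr_upper = rq[2],
                 significant = sig, stringsAsFactors = FALSE)
    } else {
      data.frame(parameter = p, mean = mean(x), lower = q[1], upper = q[2],
                 rr = NA_real_, rr_lower = NA_real_, rr_upper = NA_real_,
                 significant = NA, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Classify area trends by exceedance probability
#'
#' For each area computes `P(delta_i > 0)`, the posterior probability that
#' the area's trend is steeper than the national average (the trend
#' slopes are centred during sampling, so 0 is the national-average
#' trend). Areas with probability at or above `threshold` are classified
#' `above`, at or below `1 - threshold` `below`, otherwise
#' `indeterminate`.
#'
#' @param fit a `zip_fit` with trend slopes.
#' @param threshold exceedance threshold, default 0.95.
#' @return data frame of class `trend_classification`: `area`,
#'   `p_above`, `class`.
#' @export
classify_trends <- function(fit, threshold = 0.95) {
  stopifnot(inherits(fit, "zip_fit"))
  cols <- paste0("delta_", fit$areas)
  if (!all(cols %in% colnames(fit$draws[[1]]))) {
    stop_spzip("fit has no area trend slopes", "spzip_invalid_argument")
  }
  all_draws <- do.call(rbind, fit$draws)
  # ties at exactly zero split evenly (only reachable for degenerate draws)
  p <- vapply(cols, function(cl)
    mean(all_draws[, cl] > 0) + 0.5 * mean(all_draws[, cl] == 0), 0)
  cls <- ifelse(p >= threshold, "above",
                ifelse(p <= 1 - threshold, "below", "indeterminate"))
  out <- data.frame(area = fit$areas, p_above = unname(p),
                    class = unname(cls), stringsAsFactors = FALSE)
  class(out) <- c("trend_classification", "data.frame")
  out
}

#' Join posterior random-effect summaries onto a geography
#'
#' Computes, per area, the posterior mean of `exp(u_i)` (residual
#' relative risk) and the exceedance probability `P(exp(u_i) > 1)`, and
#' the analogous quantities for the structured effect `s_i` when present,
#' and writes them as feature properties (`re_mean`, `re_exceed`,
#' `s_mean`, `s_exceed`) of the supplied geography. Optionally also joins
#' the trend classification (`trend_class`).
#'
#' @param fit a `zip_fit`.
#' @param geography a `lattice_geography` or the result of
#'   [read_geojson()]; feature `area_id`s must cover the fit's areas.
#' @param path optional file to write the joined GeoJSON to.
#' @param trends logical, also join [classify_trends()] output.
#' @return the joined feature list (a FeatureCollection-shaped list);
#'   written to `path` when given.
#' @export
map_random_effects <- function(fit, geography, path = NULL, trends = TRUE) {
  stopifnot(inherits(fit, "zip_fit"))
  feats <- as_features(geography)
  ids <- vapply(feats, function(f) as.character(f$properties$area_id), "")
  missing_ids <- setdiff(fit$areas, ids)
  if (length(missing_ids)) {
    stop_spzip(paste0("geography lacks area id(s): ",
                      paste(missing_ids, collapse = ", ")),
               "spzip_join_error")
  }
  all_draws <- do.call(rbind, fit$draws)
  props <- data.frame(area_id = fit$areas, stringsAsFactors = FALSE)
  exceed1 <- function(v) mean(v > 0) + 0.5 * mean(v == 0)
  if (fit$has_u) {
    ud <- all_draws[, paste0("u_", fit$areas), drop = FALSE]
    props$re_mean <- colMeans(exp(ud))
    props$re_exceed <- apply(ud, 2, exceed1)
  }
  if (fit$has_s) {
    sd_ <- all_draws[, paste0("s_", fit$areas), drop = FALSE]
    props$s_mean <- colMeans(exp(sd_))
    props$s_exceed <- apply(sd_, 2, exceed1)
  }
  if (trends && fit$has_delta) {
    tc <- classify_trends(fit)
    props$trend_p_above <- tc$p_above[match(props$area_id, tc$area)]
    props$trend_class <- tc$class[match(props$area_id, tc$area)]
  }
  idx <- match(ids, props$area_id)
  for (i in seq_along(feats)) {
    if (is.na(idx[i])) next
    for (nm in setdiff(names(props), "area_id")) {
      feats[[i]]$properties[[nm]] <- props[[nm]][idx[i]]
    }
  }
  fc <- list(type = "FeatureCollection", features = feats)
  if (!is.null(path)) {
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  }
  fc
}
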