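# Loess trend estimation of diversity metrics and CWM values against depth,
# with permutation inference. A logit-scale loess stands in for beta-likelihood
# GAM fits of proportions: it respects the (0, 1) range while staying free of
# distributional assumptions.

#' Loess trend of a metric against depth
#'
#' Local polynomial regression (tricube weights) of a response on depth, with
#' a variance-explained summary `R2 = max(0, 1 - SSE/SST)` and a permutation
#' p-value obtained by shuffling the response against depth and recomputing
#' `R2`.
#'
#' @param x numeric predictor (depth, m).
#' @param y numeric response.
#' @param span loess span (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @param n_perm permutations for the p-value (default 199).
#' @param seed integer seed.
#' @param grid_n grid points for the fitted curve, spread over the observed
#'   depth range.
#' @return Object of class `trend_fit`: list with `grid`, `fit`, `se`,
#'   `r_squared`, `p_value`, `fitted`, `settings`.
#' @export
loess_trend <- function(x, y, span = 0.75, degree = 2, n_perm = 199,
                        seed = 1, grid_n = 100) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop("need at least 10 points", call. = FALSE)
  fit_r2 <- function(yy) {
    fit <- tryCatch(
      stats::loess(yy ~ x, span = span, degree = degree,
                   family = "gaussian"),
      error = function(e) stop("loess failed (span too small?): ",
                               conditionMessage(e), call. = FALSE))
    sse <- sum(stats::residuals(fit)^2)
    sst <- sum((yy - mean(yy))^2)
    r2 <- if (sst == 0) 0 else max(0, 1 - sse / sst)
    list(fit = fit, r2 = r2)
  }
  obs <- fit_r2(y)
  set.seed(seed)
  null_r2 <- vapply(seq_len(n_perm), function(b) fit_r2(sample(y))$r2,
                    numeric(1))
  grid <- seq(min(x), max(x), length.out = grid_n)
  pred <- stats::predict(obs$fit, newdata = data.frame(x = grid), se = TRUE)
  structure(list(grid = grid, fit = pred$fit, se = pred$se.fit,
                 r_squared = obs$r2,
                 p_value = (1 + sum(null_r2 >= obs$r2)) / (1 + n_perm),
                 fitted = stats::fitted(obs$fit),
                 settings = list(span = span, degree = degree,
                                 n_perm = n_perm, seed = seed)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Trend fit: R2 =", round(x$r_squared, 3),
      ", permutation p =", signif(x$p_value, 3),
      "(span", x$settings$span, ", degree", x$settings$degree, ")\n")
  invisible(x)
}

#' Loess trend of a proportion (CWM) against depth on the logit scale
#'
#' Proportions are clamped to `[eps, 1 - eps]`, logit-transformed, smoothed
#' with [loess_trend()], and back-transformed, so fitted values always stay in
#' `(0, 1)`.
#'
#' @param x numeric predictor (depth, m).
#' @param y proportions in `[0, 1]` (e.g. per-category CWM values).
#' @param span loess span.
#' @param eps clamping margin (default 1e-4).
#' @param ... passed to [loess_trend()].
#' @return A `trend_fit` whose `fit`, `se` bands and `fitted` values are on
#'   the proportion scale (`se` reported as the back-transformed band
#'   half-widths via the delta method).
#' @export
cwm_trend <- function(x, y, span = 0.75, eps = 1e-4, ...) {
  if (any(y < 0 | y > 1, na.rm = TRUE)) {
    stop("CWM values must lie in [0, 1]", call. = FALSE)
  }
  yc <- pmin(pmax(y, eps), 1 - eps)
  lt <- loess_trend(x, stats::qlogis(yc), span = span, ...)
  inv <- stats::plogis(lt$fit)
  lt$se <- lt$se * inv * (1 - inv)
  lt$fit <- inv
  lt$fitted <- stats::plogis(lt$fitted)
  lt$settings$eps <- eps
  lt
}

#' Depth trends of metrics, pooled and per site
#'
#' Fits [loess_trend()] to one metric column of a [community_metrics()] table,
#' pooled across sites and (when at least 10 points are available) separately
#' per site, approximating a depth-by-site interaction.
#'
#' @param metrics data.frame from [community_metrics()].
#' @param metric name of the metric column.
#' @param ... passed to [loess_trend()].
#' @return list with `pooled` (a `trend_fit`) and `per_site` (named list).
#' @export
metric_depth_trends <- function(metrics, metric, ...) {
  pooled <- loess_trend(metrics$depth_mid, metrics[[metric]], ...)
  per_site <- list()
  for (s in unique(metrics$site)) {
    sub <- metrics[metrics$site == s, ]
    if (sum(stats::complete.cases(sub$depth_mid, sub[[metric]])) >= 10) {
      per_site[[s]] <- loess_trend(sub$depth_mid, sub[[metric]], ...)
    }
  }
  list(pooled = pooled, per_site = per_site)
}
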