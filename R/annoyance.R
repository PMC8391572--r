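#' Three-parameter logistic curve and its reciprocal parameterization
#'
#' The exposure--response curves are logistic functions
#' `f(x) = L / (1 + exp(-k (x - x0)))`, equivalently written in the
#' reciprocal form `f(x) = 1 / (1/L + a * b^x)` with `a = exp(k * x0) / L`
#' and `b = exp(-k)`. The reciprocal form is how the fitted annoyance models
#' are reported: a curve maximum `L`, a scale coefficient `a`, and an
#' exponential-decay base `b` in (0, 1).
#'
#' @param L Curve maximum (> 0).
#' @param k Growth rate (> 0 for an increasing curve).
#' @param x0 Midpoint.
#' @param a Scale coefficient (> 0) of the reciprocal form.
#' @param b Decay base in (0, 1) of the reciprocal form.
#' @return `logistic_params` returns an object of class `logistic_params`
#'   holding both parameterizations.
#' @export
#' @examples
#' p <- logistic_params(L = 10, k = 0.0661, x0 = 23.2)
#' logistic(p$x0, p) # L/2
logistic_params <- function(L, k = NULL, x0 = NULL, a = NULL, b = NULL) {
  if (L <= 0) stop("curve maximum L must be positive")
  if (!is.null(k) && !is.null(x0)) {
    a <- exp(k * x0) / L
    b <- exp(-k)
  } else if (!is.null(a) && !is.null(b)) {
    if (a <= 0) stop("scale coefficient a must be positive")
    if (b <= 0 || b >= 1) stop("base b must lie in (0, 1)")
    k <- -log(b)
    x0 <- log(a * L) / k
  } else {
    stop("supply either (k, x0) or (a, b)")
  }
  structure(list(L = L, k = k, x0 = x0, a = a, b = b),
            class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("Logistic: L = %.4g, k = %.4g, x0 = %.4g  (a = %.4g, b = %.4g)\n",
              x$L, x$k, x$x0, x$a, x$b))
  invisible(x)
}

#' Evaluate a logistic curve
#'
#' @param x Numeric vector.
#' @param params A [logistic_params()] object.
#' @return Values in (0, L), strictly increasing in `x` for `k > 0`.
#' @export
logistic <- function(x, params) {
  stopifnot(inherits(params, "logistic_params"))
  1 / (1 / params$L + params$a * params$b^x)
}

#' Short-term annoyance from loudness
#'
#' Fitted jury-test exposure--response model on the 11-point (0--10) ICBEN
#' scale: `Annoyance = 1 / (0.1 + 0.463 * 0.936^Loudness)`. The curve rises
#' from about 1.8 at zero loudness toward the scale maximum of 10.
#'
#' @param loudness Loudness in sones (>= 0).
#' @return Annoyance score in (0, 10].
#' @export
#' @examples
#' short_term_annoyance(c(0, 20, 40))
short_term_annoyance <- function(loudness) {
  if (any(loudness < 0)) stop("loudness must be non-negative")
  logistic(loudness, short_term_params())
}

#' @rdname short_term_annoyance
#' @export
short_term_params <- function() logistic_params(L = 10, a = 0.463, b = 0.936)

#' Long-term percentage highly annoyed from loudness
#'
#' Fitted field-survey exposure--response model:
#' `%HA = 1 / (0.01 + 0.043 * 0.97^Loudness)`. Nonzero (about 18.9 %) even at
#' zero loudness — some residents report high annoyance regardless of the
#' modelled exposure — rising toward 100 %.
#'
#' @param loudness Loudness in sones (>= 0).
#' @return Percentage of highly annoyed residents in (0, 100].
#' @export
#' @examples
#' long_term_pct_ha(c(0, 20, 40))
long_term_pct_ha <- function(loudness) {
  if (any(loudness < 0)) stop("loudness must be non-negative")
  logistic(loudness, long_term_params())
}

#' @rdname long_term_pct_ha
#' @export
long_term_params <- function() logistic_params(L = 100, a = 0.043, b = 0.97)

#' Fit a logistic exposure--response model
#'
#' Nonlinear least-squares (Levenberg--Marquardt) fit of the three-parameter
#' logistic in its reciprocal parameterization `1 / (1/L + a b^x)`. The
#' maximum is initialized at (and bounded above by) the response scale
#' maximum; `b` is initialized from a log-linear regression of
#' `log(1/y - 1/L)`.
#'
#' @param x Predictor (loudness, sones); at least 4 distinct values.
#' @param y Response (mean rating or %HA), strictly inside (0, scale_max).
#' @param scale_max Response scale maximum: 10 for ratings, 100 for %HA.
#' @param weights Optional nonnegative fit weights.
#' @param kind Label stored on the result, `"short_term"` or `"long_term"`.
#' @return Object of class `annoyance_model`: list with `kind`, `params`
#'   (a [logistic_params()]), `r_squared`, and the `fit` object.
#' @export
fit_logistic <- function(x, y, scale_max, weights = NULL,
                         kind = c("short_term", "long_term")) {
  kind <- match.arg(kind)
  if (length(unique(x)) < 4) stop("need at least 4 distinct x values")
  if (stats::sd(y) == 0) stop("degenerate response: y is constant")
  if (any(y <= 0 | y >= scale_max))
    stop("responses must lie strictly inside (0, scale_max)")
  if (is.null(weights)) weights <- rep(1, length(y))

  L0 <- scale_max
  z <- log(pmax(1 / y - 1 / L0, 1e-12))
  lf <- stats::lm(z ~ x)
  b0 <- min(max(exp(stats::coef(lf)[[2]]), 1e-4), 0.9999)
  a0 <- exp(stats::coef(lf)[[1]])

  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 1 / (1 / L + a * b^x), data = df, weights = weights,
      start = list(L = L0, a = a0, b = b0),
      lower = c(L = max(y) + 1e-9, a = 1e-12, b = 1e-6),
      upper = c(L = scale_max, a = Inf, b = 1 - 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("logistic fit failed to converge: ", conditionMessage(e)))

  cf <- stats::coef(fit)
  params <- logistic_params(L = cf[["L"]], a = cf[["a"]], b = cf[["b"]])
  fitted_y <- logistic(x, params)
  r2 <- 1 - sum(weights * (y - fitted_y)^2) /
            sum(weights * (y - stats::weighted.mean(y, weights))^2)
  structure(list(kind = kind, params = params, r_squared = r2, fit = fit),
            class = "annoyance_model")
}

#' @export
print.annoyance_model <- function(x, ...) {
  cat(sprintf("Annoyance model (%s): 1/(1/%.4g + %.4g * %.4g^x), R^2 = %.4f\n",
              x$kind, x$params$L, x$params$a, x$params$b, x$r_squared))
  invisible(x)
}

#' Serialize / read a fitted annoyance model
#'
#' Writes the parameterization tag, coefficients, R-squared and the
#' highly-annoyed cutoff to a structured JSON file.
#'
#' @param model An `annoyance_model`.
#' @param path File path.
#' @param ha_cutoff Highly-annoyed rating cutoff stored with the model.
#' @return `model_to_file` returns `path` invisibly; `model_from_file`
#'   returns an `annoyance_model` (without the original `fit` object).
#' @export
model_to_file <- function(model, path, ha_cutoff = 8) {
  stopifnot(inherits(model, "annoyance_model"))
  jsonlite::write_json(
    list(parameterization = "reciprocal_logistic", kind = model$kind,
         L = model$params$L, a = model$params$a, b = model$params$b,
         r_squared = model$r_squared, ha_cutoff = ha_cutoff),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname model_to_file
#' @export
model_from_file <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kind = x$kind,
                 params = logistic_params(L = x$L, a = x$a, b = x$b),
                 r_squared = x$r_squared, ha_cutoff = x$ha_cutoff),
            class = "annoyance_model")
}

#' Percentage of highly annoyed respondents
#'
#' Share of ratings at or above the highly-annoyed cutoff (default 8, i.e.
#' ratings 8--10 on the 0--10 ICBEN scale, the conventional top-27 % cut).
#'
#' @param ratings Integer ratings in 0--10.
#' @param cutoff Highly-annoyed cutoff (rating >= cutoff counts).
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' pct_highly_annoyed(c(8, 9, 10, 0)) # 75
pct_highly_annoyed <- function(ratings, cutoff = 8) {
  if (length(ratings) == 0) stop("no ratings supplied")
  if (any(ratings < 0 | ratings > 10)) stop("ratings must lie in 0..10")
  100 * mean(ratings >= cutoff)
}

#' Bin survey records by loudness and tabulate %HA
#'
#' Groups records into contiguous half-open loudness bins `[0, w), [w, 2w), …`
#' (default width 5 sones) covering the data and reports the per-bin count and
#' percentage highly annoyed.
#'
#' @param loudness Loudness per record, sones (>= 0).
#' @param highly_annoyed Logical (or 0/1) highly-annoyed indicator per record.
#' @param width Bin width in sones.
#' @param cutoff Unused when `highly_annoyed` is logical; retained for
#'   symmetry with [pct_highly_annoyed()].
#' @return Data frame with columns `lower`, `upper`, `n`, `pct_ha`
#'   (empty bins inside the covered range are kept with `n = 0`,
#'   `pct_ha = NA`).
#' @export
bin_by_loudness <- function(loudness, highly_annoyed, width = 5, cutoff = 8) {
  if (any(loudness < 0)) stop("loudness must be non-negative")
  stopifnot(length(loudness) == length(highly_annoyed), width > 0)
  ha <- as.logical(highly_annoyed)
  n_bins <- floor(max(loudness) / width) + 1
  lower <- (seq_len(n_bins) - 1) * width
  idx <- pmin(floor(loudness / width) + 1, n_bins)
  n <- tabulate(idx, nbins = n_bins)
  pct <- rep(NA_real_, n_bins)
  for (i in which(n > 0)) pct[i] <- 100 * mean(ha[idx == i])
  data.frame(lower = lower, upper = lower + width, n = n, pct_ha = pct)
}

#' Indoor level from an outdoor facade level
#'
#' Outdoor-to-indoor correction for a slightly opened window: 15.0 dBA for
#' aircraft noise and 15.8 dBA for road-traffic noise are subtracted. No
#' flooring is applied; the caller decides audibility of negative results.
#'
#' @param outdoor_dba Outdoor level in dBA.
#' @param source `"aircraft"` or `"road"`.
#' @return Indoor level in dBA.
#' @export
#' @examples
#' indoor_level(70, "aircraft") # 55.0
#' indoor_level(70, "road")     # 54.2
indoor_level <- function(outdoor_dba, source = c("aircraft", "road")) {
  source <- match.arg(source)
  outdoor_dba - switch(source, aircraft = 15.0, road = 15.8)
}
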