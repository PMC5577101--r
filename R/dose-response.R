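# Four-parameter logistic dose-response fitting and cross-experiment
# geometric-mean summaries.

#' The four-parameter logistic (4PL) curve
#'
#' `y = bottom + (top - bottom) / (1 + (ec50 / x)^hill)`. At `x = ec50` the
#' response is exactly `(top + bottom) / 2`.
#'
#' @param x concentrations (> 0).
#' @param bottom,top,ec50,hill curve parameters.
#' @return response values.
#' @export
fourPL <- function(x, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / x)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least squares via Levenberg-Marquardt (minpack.lm) with multi-start
#' initialisation over a log-spaced EC50 grid spanning the dose range;
#' EC50 is fitted on the log scale. The fitted orientation is normalised so
#' `top >= bottom` (swapping the asymptotes and negating the Hill slope is
#' an exact reparameterisation of the same curve). Flat (zero-variance)
#' responses return a degenerate fit with `bottom == top` and
#' `converged = FALSE` rather than an error. Zero/vehicle concentrations
#' are not accepted: exclude them from the fit and use them as the
#' unstimulated anchor.
#'
#' @param concentrations positive doses (>= 4 distinct values).
#' @param responses finite responses, same length.
#' @param weighting `"none"` (default) or `"inverse_y2"` (1/y^2 weights).
#' @param unit concentration unit label carried through unconverted.
#' @return a [Fit4PL-class].
#' @export
fit4PL <- function(concentrations, responses, weighting = c("none",
                   "inverse_y2"), unit = NA_character_) {
  weighting <- match.arg(weighting)
  x <- as.numeric(concentrations)
  y <- as.numeric(responses)
  if (length(x) != length(y)) stop("lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("concentrations and responses must be finite")
  if (any(x <= 0))
    stop("concentrations must be positive; map zero/vehicle wells to the unstimulated anchor instead")
  if (length(unique(x)) < 4L)
    stop("need at least 4 distinct concentrations")
  w <- if (weighting == "inverse_y2") 1 / pmax(y^2, 1e-12) else rep(1, length(y))

  if (sd(y) == 0)
    return(new("Fit4PL", bottom = y[1], top = y[1],
               ec50 = exp(mean(log(x))), hill = 1, rss = 0,
               converged = FALSE, nPoints = length(y), unit = unit))

  grid <- exp(seq(log(min(x)), log(max(x)), length.out = 7))
  increasing <- stats::cor(log(x), y) >= 0
  hillStarts <- if (increasing) c(0.5, 1, 2) else c(-0.5, -1, -2)
  span <- max(y) - min(y)
  best <- NULL
  df <- data.frame(x = x, y = y, w = w)
  for (e0 in grid) for (h0 in hillStarts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b + (t - b) / (1 + exp(h * (loge - log(x)))),
        data = df, weights = df$w,
        start = list(b = min(y) - 0.05 * span, t = max(y) + 0.05 * span,
                     loge = log(e0), h = h0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(new("Fit4PL", bottom = mean(y), top = mean(y),
               ec50 = exp(mean(log(x))), hill = 1, rss = sum(w * (y - mean(y))^2),
               converged = FALSE, nPoints = length(y), unit = unit))
  p <- coef(best$fit)
  bottom <- unname(p["b"]); top <- unname(p["t"])
  ec <- exp(unname(p["loge"])); hill <- unname(p["h"])
  if (top < bottom) {  # exact reparameterisation of the same curve
    tmp <- bottom; bottom <- top; top <- tmp; hill <- -hill
  }
  new("Fit4PL", bottom = bottom, top = top, ec50 = ec, hill = hill,
      rss = best$rss, converged = TRUE, nPoints = length(y), unit = unit)
}

#' Predicted response of a fitted 4PL curve
#'
#' @param fit a [Fit4PL-class].
#' @param x concentrations.
#' @return predicted responses.
#' @export
predict4PL <- function(fit, x) {
  stopifnot(is(fit, "Fit4PL"))
  fourPL(x, fit@bottom, fit@top, fit@ec50, fit@hill)
}

#' Fit an IC50 from percent-inhibition data
#'
#' Fits the 4PL to percent inhibition versus antagonist concentration; the
#' reported `ec50` is the IC50 in the response-declining orientation (the
#' underlying signal falls as inhibition rises). Inhibition clamped at a
#' constant (e.g. 0% everywhere) yields `converged = FALSE`.
#'
#' @param concentrations antagonist doses (> 0).
#' @param percentInhibition percent-inhibition values.
#' @param unit concentration unit label (e.g. `"nM"`).
#' @return a [Fit4PL-class]; `ec50(fit)` is the IC50.
#' @export
ic50FromInhibition <- function(concentrations, percentInhibition,
                               unit = "nM") {
  fit4PL(concentrations, percentInhibition, unit = unit)
}

#' Geometric-mean summary of per-experiment potency values
#'
#' The cross-experiment summary shape: geometric mean with the min, max and
#' experiment count.
#'
#' @param values strictly positive per-experiment EC50/IC50 values.
#' @return one-row data.frame: `geometric_mean`, `min`, `max`, `n`.
#' @export
summarizeExperiments <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("potency values must be strictly positive")
  data.frame(geometric_mean = geometricMean(values), min = min(values),
             max = max(values), n = length(values))
}
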