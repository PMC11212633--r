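# Subpixel model fits: Gaussian peaks and sigmoid edges.
#
# These are the precision-critical primitives of the whole pipeline. Both use
# Levenberg-Marquardt least squares (minpack.lm) with box constraints keeping
# the localization parameter inside the fitted window, and report convergence
# so callers can fall back to integer-precision estimates.

#' Fit a Gaussian peak with constant offset
#'
#' Least-squares fit of `offset + amplitude * exp(-(x - center)^2 / (2 sigma^2))`
#' to a short window of samples, used for subpixel localization of band
#' centers and autocorrelation peaks. The center is constrained to lie inside
#' the window.
#'
#' @param x Sample positions (pixels or lags).
#' @param y Sample values.
#' @param center_init Optional starting value for the center (default:
#'   position of the maximum).
#' @param weights Optional least-squares weights (e.g. inverse-variance
#'   weights for photon-counting data, where the variance scales with the
#'   intensity); default unweighted.
#' @param baseline `"constant"` (default) or `"linear"`. A linear baseline
#'   absorbs a smooth slanted background under the peak, which would
#'   otherwise bias the fitted center; used for autocorrelation peaks, whose
#'   pedestal is slightly sloped near the secondary maximum.
#' @return A list with elements `amplitude`, `center`, `sigma`, `offset`,
#'   and `converged` (logical; `FALSE` means the caller should fall back to
#'   the integer-precision maximum).
#' @export
fit_gaussian <- function(x, y, center_init = NULL, weights = NULL,
                         baseline = c("constant", "linear")) {
  baseline <- match.arg(baseline)
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (is.null(weights)) weights <- rep(1, length(x))
  if (is.null(center_init)) center_init <- x[which.max(y)]
  rng <- range(x)
  span <- diff(rng)
  x0 <- mean(rng)
  start <- list(
    amplitude = max(y) - min(y),
    center    = center_init,
    sigma     = span / 4,
    offset    = min(y)
  )
  fit <- if (baseline == "constant") {
    tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ offset + amplitude * exp(-(x - center)^2 / (2 * sigma^2)),
        start = start, weights = weights,
        lower = c(amplitude = 0, center = rng[1], sigma = span / 50, offset = -Inf),
        upper = c(amplitude = Inf, center = rng[2], sigma = span * 2, offset = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 100)
      )),
      error = function(e) NULL
    )
  } else {
    tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ offset + slope * (x - x0) + amplitude * exp(-(x - center)^2 / (2 * sigma^2)),
        start = c(start, list(slope = 0)), weights = weights,
        lower = c(amplitude = 0, center = rng[1], sigma = span / 50,
                  offset = -Inf, slope = -Inf),
        upper = c(amplitude = Inf, center = rng[2], sigma = span * 2,
                  offset = Inf, slope = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 100)
      )),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    return(list(amplitude = start$amplitude, center = center_init,
                sigma = start$sigma, offset = start$offset, converged = FALSE))
  }
  p <- as.list(stats::coef(fit))
  conv <- p$center > rng[1] && p$center < rng[2] && p$amplitude > 0
  list(amplitude = p$amplitude, center = p$center, sigma = p$sigma,
       offset = p$offset, converged = conv)
}

#' Fit a sigmoid edge
#'
#' Least-squares fit of `low + (high - low) / (1 + exp(-(x - midpoint)/slope))`.
#' A positive `slope` describes an ascending edge, a negative one a
#' descending edge. The midpoint parameter is the inflection point, i.e. the
#' position where the curve reaches 50% of its plateau; crossings of other
#' thresholds follow from [sigmoid_threshold_position()].
#'
#' @param x Sample positions.
#' @param y Sample values.
#' @param ascending Logical; direction of the edge.
#' @return List with `low`, `high`, `midpoint`, `slope`, `converged`.
#' @export
fit_sigmoid <- function(x, y, ascending = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  rng <- range(x)
  span <- diff(rng)
  half <- min(y) + (max(y) - min(y)) / 2
  # starting midpoint: first crossing of the half level in the edge direction
  above <- y > half
  idx <- if (ascending) which(!above[-length(above)] & above[-1]) else
    which(above[-length(above)] & !above[-1])
  mid0 <- if (length(idx)) x[idx[1]] else mean(rng)
  s0 <- if (ascending) span / 10 else -span / 10
  start <- list(low = min(y), high = max(y), midpoint = mid0, slope = s0)
  lower <- c(low = -Inf, high = -Inf, midpoint = rng[1],
             slope = if (ascending) span / 1e3 else -span)
  upper <- c(low = Inf, high = Inf, midpoint = rng[2],
             slope = if (ascending) span else -span / 1e3)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      y ~ low + (high - low) / (1 + exp(-(x - midpoint) / slope)),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(c(start, list(converged = FALSE)))
  }
  p <- as.list(stats::coef(fit))
  conv <- p$midpoint > rng[1] && p$midpoint < rng[2] && p$high > p$low
  list(low = p$low, high = p$high, midpoint = p$midpoint, slope = p$slope,
       converged = conv)
}

#' Position where a fitted sigmoid crosses a threshold
#'
#' For a sigmoid fit, returns the position at which the curve reaches
#' `low + threshold * (high - low)`. With `threshold = 0.5` this is the
#' midpoint parameter itself.
#'
#' @param fit A fit returned by [fit_sigmoid()].
#' @param threshold Fraction of the plateau height, in (0, 1).
#' @return Position (same units as the fitted `x`).
#' @export
sigmoid_threshold_position <- function(fit, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  fit$midpoint + fit$slope * log(threshold / (1 - threshold))
}
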