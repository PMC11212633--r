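# Synthetic validation images: ladders of bands, blocks, or
# block-with-middle-band motifs, rendered on an oversampled grid, blurred
# with a Gaussian point-spread function, integrated down to camera pixels,
# and corrupted with Poisson noise.

#' Simulation configuration
#'
#' Parameters of the synthetic image generator. The defaults reproduce the
#' validation geometry used throughout the package: a ladder of 10 single
#' bands 25 pixels apart on a 42 nm/px grid.
#'
#' The operational definition of SNR used everywhere in this package is the
#' band peak amplitude (photons above background) divided by the Poisson
#' noise standard deviation at the band peak, i.e. `snr = A / sqrt(A + B)`
#' with `A` the peak amplitude and `B` the constant background level in
#' photons.
#'
#' @param n_repeats Number of pattern repeats (default 10).
#' @param spacing Repeat spacing in final pixels (default 25).
#' @param pattern_kind One of `"bands"`, `"blocks"`, `"block_with_middle_band"`.
#' @param band_offsets For `"bands"`: offsets of the band(s) within one
#'   repeat, relative to the repeat center (default a single centered band).
#' @param block_width Plateau width in pixels for block-type motifs.
#' @param middle_band_amplitude Amplitude of the central band relative to the
#'   plateau for the block-with-middle-band motif.
#' @param snr Target signal-to-noise ratio; `Inf` disables noise.
#' @param background Constant background level, photons (default 4).
#' @param intensity_sd Standard deviation of per-repeat intensity factors
#'   (normal, mean 1); 0 means all repeats equally bright.
#' @param position_sd Standard deviation of per-repeat position shifts, pixels.
#' @param psf_sigma Gaussian point-spread-function sd in final pixels
#'   (default 1.8, about 76 nm at 42 nm/px — the Gaussian approximation
#'   `0.21 * lambda / NA` of a 1.4 NA objective's PSF at green emission).
#' @param oversample Oversampling factor for rendering (integer, >= 4).
#' @param pixel_size_nm Physical pixel size, nm (default 42).
#' @param image_height Image height in pixels (default 15, so linewidths up
#'   to 12 can be swept).
#' @param seed Integer seed; the image is deterministic given the seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_repeats = 10, spacing = 25,
                              pattern_kind = c("bands", "blocks",
                                               "block_with_middle_band"),
                              band_offsets = 0, block_width = 12,
                              middle_band_amplitude = 1,
                              snr = 4, background = 4,
                              intensity_sd = 0, position_sd = 0,
                              psf_sigma = 1.8, oversample = 8,
                              pixel_size_nm = 42, image_height = 15,
                              seed = 1L) {
  pattern_kind <- match.arg(pattern_kind)
  if (snr <= 0) stop_pk("config_error", "snr must be positive")
  if (intensity_sd < 0 || position_sd < 0)
    stop_pk("config_error", "intensity_sd and position_sd must be >= 0")
  if (oversample < 4) stop_pk("config_error", "oversample must be >= 4")
  motif_width <- switch(pattern_kind,
    bands = diff(range(band_offsets)) + 6 * psf_sigma,
    blocks = block_width,
    block_with_middle_band = block_width
  )
  if (motif_width > spacing)
    stop_pk("config_error", "motif (width %.1f px) is wider than the spacing (%.1f px)",
            motif_width, spacing)
  structure(
    list(n_repeats = n_repeats, spacing = spacing, pattern_kind = pattern_kind,
         band_offsets = band_offsets, block_width = block_width,
         middle_band_amplitude = middle_band_amplitude,
         snr = snr, background = background,
         intensity_sd = intensity_sd, position_sd = position_sd,
         psf_sigma = psf_sigma, oversample = as.integer(oversample),
         pixel_size_nm = pixel_size_nm, image_height = image_height,
         seed = seed),
    class = "simulation_config"
  )
}

# Peak amplitude A solving snr = A / sqrt(A + B).
snr_to_amplitude <- function(snr, background) {
  if (!is.finite(snr)) return(100)
  (snr^2 + snr * sqrt(snr^2 + 4 * background)) / 2
}

# Expected peak value of a unit-mass impulse after Gaussian blur of sd
# `sigma` (final pixels) and integration over the central 1-px bin.
unit_band_peak <- function(sigma) {
  stats::pnorm(0.5, 0, sigma) - stats::pnorm(-0.5, 0, sigma)
}

# Render the noiseless expected 1-d profile (photons per final pixel,
# background excluded) for a set of repeat centers and intensity factors.
render_profile <- function(config, centers, factors, width) {
  os <- config$oversample
  n_os <- width * os
  # oversampled bin m (0-based) has center ((m + 0.5)/os - 0.5) in final px
  signal <- numeric(n_os)
  add_impulse <- function(pos, mass) {
    # split the mass linearly over the two neighboring oversampled bins so
    # the rendered center is subpixel-exact, not snapped to the grid
    mf <- (pos + 0.5) * os - 0.5
    m0 <- floor(mf); fr <- mf - m0
    if (m0 >= 0 && m0 < n_os) signal[m0 + 1] <<- signal[m0 + 1] + mass * (1 - fr)
    if (m0 + 1 >= 0 && m0 + 1 < n_os) signal[m0 + 2] <<- signal[m0 + 2] + mass * fr
  }
  add_block <- function(center, halfwidth, height) {
    m0 <- max(0, ceiling((center - halfwidth + 0.5) * os - 0.5))
    m1 <- min(n_os - 1, floor((center + halfwidth + 0.5) * os - 0.5))
    if (m1 >= m0) {
      idx <- (m0:m1) + 1
      signal[idx] <<- signal[idx] + height / os
    }
  }
  for (i in seq_along(centers)) {
    ci <- centers[i]; fi <- factors[i]
    switch(config$pattern_kind,
      bands = for (off in config$band_offsets) add_impulse(ci + off, fi),
      blocks = add_block(ci, config$block_width / 2, fi),
      block_with_middle_band = {
        add_block(ci, config$block_width / 2, fi)
        add_impulse(ci, fi * config$middle_band_amplitude)
      }
    )
  }
  # PSF blur on the oversampled grid (reflective boundary), then bin down
  blurred <- gaussian_blur_1d(signal, config$psf_sigma * os)
  colSums(matrix(blurred, nrow = os))
}

#' Simulate a synthetic pattern image
#'
#' Renders the configured motif ladder on an oversampled grid, blurs it with
#' the Gaussian point-spread function, integrates down to final pixels,
#' scales photon counts so the realized SNR matches `config$snr`, replicates
#' the profile over `image_height` rows and applies per-pixel Poisson noise.
#' The result is deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with `image` (an [image_data()] of one frame, one channel)
#'   and `truth` (a `ground_truth` object: band/edge positions, spacings,
#'   and the period-variation class in percent).
#' @export
simulate_image <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_image_impl(config))
}

simulate_image_impl <- function(config) {
  n <- config$n_repeats
  pad <- config$spacing / 2
  width <- ceiling(n * config$spacing + 2 * pad)
  centers <- pad + config$spacing * (seq_len(n) - 0.5)
  if (config$position_sd > 0)
    centers <- sort(centers + stats::rnorm(n, 0, config$position_sd))
  factors <- rep(1, n)
  if (config$intensity_sd > 0)
    factors <- pmax(0.05, stats::rnorm(n, 1, config$intensity_sd))

  profile <- render_profile(config, centers, factors, width)
  amp <- snr_to_amplitude(config$snr, config$background)
  scale <- amp / unit_band_peak(config$psf_sigma)
  lambda <- profile * scale + config$background

  h <- config$image_height
  px <- array(0, dim = c(1, 1, h, width))
  if (is.finite(config$snr)) {
    counts <- stats::rpois(h * width, rep(lambda, each = h))
    px[1, 1, , ] <- matrix(counts, nrow = h)
  } else {
    px[1, 1, , ] <- matrix(rep(lambda, each = h), nrow = h)
  }
  img <- image_data(px, pixel_size = config$pixel_size_nm)
  truth <- ground_truth(config, centers, factors)
  list(image = img, truth = truth)
}

ground_truth <- function(config, centers, factors) {
  positions <- switch(config$pattern_kind,
    bands = sort(as.vector(outer(config$band_offsets, centers, `+`))),
    blocks = centers,
    block_with_middle_band = centers
  )
  edges <- if (config$pattern_kind != "bands") {
    cbind(left = centers - config$block_width / 2,
          right = centers + config$block_width / 2)
  } else NULL
  spacings <- diff(centers)
  structure(
    list(centers = centers, positions = positions, edges = edges,
         intensity_factors = factors, spacings = spacings,
         variation_class = if (length(centers) >= 3)
           100 * (max(spacings) - min(spacings)) / mean(spacings) else NA_real_),
    class = "ground_truth"
  )
}

#' Period-variation class of a simulated image
#'
#' Classifies a ground truth by the percent difference between the two
#' repeats closest together and the two furthest apart:
#' `100 * (max spacing - min spacing) / mean spacing`.
#'
#' @param truth A `ground_truth` from [simulate_image()].
#' @return Percent variation (numeric scalar).
#' @export
classify_period_variation <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(truth$centers) < 3)
    stop_pk("parameter_error", "period-variation class needs >= 3 repeats")
  s <- truth$spacings
  100 * (max(s) - min(s)) / mean(s)
}

#' Simulate a time-lapse movie of a contracting ladder
#'
#' Generates one frame per contraction factor; in frame t the repeat spacing
#' is `config$spacing * contraction[t]`, contracted about the ladder center.
#' The noise model is the same as [simulate_image()].
#'
#' @param config A [simulation_config()].
#' @param contraction Numeric vector of positive per-frame scale factors.
#' @return A list with `image` (multi-frame [image_data()]) and `truth`
#'   (list of per-frame `ground_truth`).
#' @export
simulate_movie <- function(config, contraction) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(contraction <= 0))
    stop_pk("config_error", "contraction factors must be positive")
  with_seed(config$seed, {
    n <- config$n_repeats
    pad <- config$spacing / 2
    width <- ceiling(n * config$spacing + 2 * pad)
    mid <- width / 2
    h <- config$image_height
    px <- array(0, dim = c(length(contraction), 1, h, width))
    truths <- vector("list", length(contraction))
    amp <- snr_to_amplitude(config$snr, config$background)
    scale <- amp / unit_band_peak(config$psf_sigma)
    for (t in seq_along(contraction)) {
      centers0 <- pad + config$spacing * (seq_len(n) - 0.5)
      centers <- mid + (centers0 - mid) * contraction[t]
      factors <- rep(1, n)
      cfg_t <- config
      profile <- render_profile(cfg_t, centers, factors, width)
      lambda <- profile * scale + config$background
      if (is.finite(config$snr)) {
        px[t, 1, , ] <- matrix(stats::rpois(h * width, rep(lambda, each = h)),
                               nrow = h)
      } else {
        px[t, 1, , ] <- matrix(rep(lambda, each = h), nrow = h)
      }
      truths[[t]] <- ground_truth(cfg_t, centers, factors)
    }
    list(image = image_data(px, pixel_size = config$pixel_size_nm),
         truth = truths)
  })
}
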