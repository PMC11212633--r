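# Synthetic image generator: determinism, noise statistics, geometry.

test_that("simulation is deterministic given a seed and exact without noise", {
  cfg <- simulation_config(snr = 3, seed = 123)
  a <- simulate_image(cfg); b <- simulate_image(cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$positions, b$truth$positions)

  noiseless <- simulate_image(simulation_config(snr = Inf, seed = 1))
  prof <- noiseless$image$pixels[1, 1, 8, ]
  maxima <- patternkit:::local_maxima(prof) - 1   # 0-based positions
  for (p in noiseless$truth$positions)
    expect_lte(min(abs(maxima - p)), 0.1 + 0.5)   # integer grid maxima
})

test_that("the realized SNR scales as configured between SNR 2 and 8", {
  seeds <- patternkit:::derive_seeds(701, 100)
  measure <- function(snr, s) {
    cfg <- simulation_config(snr = snr, seed = s)
    sim <- simulate_image(cfg)
    lam_bg <- cfg$background
    m <- sim$image$pixels[1, 1, , ]
    peak_cols <- round(sim$truth$positions) + 1
    amp <- mean(m[, peak_cols]) - lam_bg
    noise <- sd(m[, peak_cols] - mean(m[, peak_cols]))
    amp / noise
  }
  r2 <- sapply(seeds[1:50], function(s) measure(2, s))
  r8 <- sapply(seeds[51:100], function(s) measure(8, s))
  expect_equal(mean(r8) / mean(r2), 4, tolerance = 0.15)
})

test_that("expected photon count is conserved across oversampling factors", {
  sums <- sapply(c(4, 8, 16), function(os) {
    sim <- simulate_image(simulation_config(snr = Inf, oversample = os, seed = 1))
    sum(sim$image$pixels)
  })
  expect_lt(max(abs(sums / sums[1] - 1)), 0.005)
})

test_that("background noise is Poisson: variance approximately equals the mean", {
  seeds <- patternkit:::derive_seeds(801, 100)
  stats <- sapply(seeds, function(s) {
    sim <- simulate_image(simulation_config(snr = 2, seed = s))
    m <- sim$image$pixels[1, 1, , ]
    bg_cols <- which(sapply(seq_len(ncol(m)) - 1, function(p)
      min(abs(p - sim$truth$positions)) > 8))
    v <- as.vector(m[, bg_cols])
    c(mean = mean(v), var = var(v))
  })
  expect_equal(mean(stats["var", ]) / mean(stats["mean", ]), 1, tolerance = 0.1)
})

test_that("period-variation classification follows the closest/furthest rule", {
  cfg <- simulation_config(position_sd = 0, seed = 1)
  sim <- simulate_image(cfg)
  expect_equal(classify_period_variation(sim$truth), 0)
  # direct arithmetic: spacings 22.5 / 25 / 27.5 -> 20%
  truth <- patternkit:::ground_truth(cfg, cumsum(c(10, 22.5, 25, 27.5)), rep(1, 4))
  expect_equal(classify_period_variation(truth), 20)
  truth2 <- patternkit:::ground_truth(cfg, c(10, 35), rep(1, 2))
  expect_error(classify_period_variation(truth2), class = "parameter_error")
})

test_that("movies follow the contraction profile exactly and reproduce by seed", {
  contraction <- 1 + 0.1 * sin(2 * pi * (0:9) / 10)
  cfg <- simulation_config(snr = Inf, seed = 5)
  mv <- simulate_movie(cfg, contraction)
  expect_equal(mv$image$n_frames, 10)
  mean_spacings <- sapply(mv$truth, function(t) mean(t$spacings))
  expect_equal(mean_spacings, 25 * contraction, tolerance = 1e-9)

  mv2 <- simulate_movie(cfg, contraction)
  expect_identical(mv$image$pixels, mv2$image$pixels)
  expect_error(simulate_movie(cfg, c(1, -1)), class = "config_error")
})

test_that("a motif wider than the spacing is rejected at configuration time", {
  expect_error(simulation_config(pattern_kind = "blocks", block_width = 30),
               class = "config_error")
  expect_error(simulation_config(snr = 0), class = "config_error")
  expect_error(simulation_config(oversample = 2), class = "config_error")
})
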