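# Image loading, preprocessing, and profile extraction.

test_that("TIFF round trip preserves structure, inversion flips extrema", {
  px <- array(0, dim = c(1, 1, 64, 64))
  px[1, 1, 30, 40] <- 10
  img <- image_data(px)
  tf <- tempfile(fileext = ".tif")
  write_image(img, tf)

  loaded <- load_image(tf)
  expect_equal(loaded$n_frames, 1)
  expect_equal(loaded$n_channels, 1)
  m <- loaded$pixels[1, 1, , ]
  expect_equal(which(m == max(m), arr.ind = TRUE)[1, ], c(row = 30, col = 40))

  inv <- load_image(tf, invert = TRUE)
  mi <- inv$pixels[1, 1, , ]
  expect_equal(mi[30, 40], min(mi))
  expect_gt(mi[1, 1], mi[30, 40])
})

test_that("Gaussian blur matches a dense direct-convolution oracle and conserves sum", {
  set.seed(11)
  m <- matrix(runif(32 * 32), 32, 32)
  m[16, 16] <- 5
  ours <- patternkit:::gaussian_blur_matrix(m, 2)
  oracle <- blur_oracle(m, 2)
  expect_lt(max(abs(ours - oracle)), 1e-10)

  # sum conservation on a band image (mass away from the borders)
  x <- 0:31
  band <- outer(rep(1, 32), exp(-(x - 16)^2 / (2 * 2^2)))
  band <- band * outer(exp(-(x - 16)^2 / (2 * 6^2)), rep(1, 32))
  blurred <- patternkit:::gaussian_blur_matrix(band, 2)
  expect_lt(abs(sum(blurred) - sum(band)) / sum(band), 0.001)
  expect_lt(max(blurred), max(band))  # peak amplitude strictly decreases
})

test_that("multi-page multi-channel TIFFs load with frames and channels separated", {
  px <- array(runif(2 * 3 * 16 * 20), dim = c(2, 3, 16, 20))
  img <- image_data(px)
  tf <- tempfile(fileext = ".tif")
  write_image(img, tf)
  loaded <- load_image(tf)
  expect_equal(loaded$n_frames, 2)
  expect_equal(loaded$n_channels, 3)
  # relative structure preserved (storage rescales intensities)
  sc <- max(px)
  expect_lt(max(abs(loaded$pixels - px / sc)), 1e-3)
})

test_that("profile along a linear ramp is the identity after normalization", {
  m <- matrix(rep(0:63, each = 32), 32, 64)  # column c has value c
  img <- image_data(m)
  sel <- selection(rbind(c(0, 15), c(30, 15), c(63, 15)), linewidth = 1)
  prof <- extract_profile(img, sel)
  expect_equal(prof$positions, 0:63)
  expect_equal(prof$intensities[["1"]], (0:63) / 63, tolerance = 1e-12)
})

test_that("linewidth averaging along an invariant direction changes nothing", {
  m <- matrix(0, 40, 40)
  m[18:22, ] <- 1  # horizontal stripe: invariant along the averaging direction
  img <- image_data(m)
  sel1 <- selection(rbind(c(10, 5), c(10, 34)), linewidth = 1)
  sel7 <- selection(rbind(c(10, 5), c(10, 34)), linewidth = 7)
  p1 <- extract_profile(img, sel1)
  p7 <- extract_profile(img, sel7)
  expect_equal(p1$intensities[["1"]], p7$intensities[["1"]], tolerance = 1e-12)
})

test_that("normalization sets min 0 / max 1, is idempotent, and rejects flat profiles", {
  v <- c(0.2, 0.9, 0.4, 0.7)
  nm <- patternkit:::normalize_intensities(v)
  expect_equal(min(nm$values), 0)
  expect_equal(max(nm$values), 1)
  again <- patternkit:::normalize_intensities(nm$values)
  expect_equal(again$values, nm$values)
  expect_error(patternkit:::normalize_intensities(rep(2, 5)),
               class = "degenerate_profile")
})

test_that("selection outside the image raises a bounds error", {
  img <- image_data(matrix(runif(100), 10, 10))
  sel <- selection(rbind(c(0, 5), c(30, 5)))
  expect_error(extract_profile(img, sel), class = "bounds_error")
})

test_that("a 5-degree misaligned selection inflates the spacing by 1/cos(5)", {
  sim <- simulate_image(simulation_config(snr = Inf, image_height = 64, seed = 3))
  th <- 5 * pi / 180
  L <- 260 / cos(th)
  y0 <- 31.5 - (L * sin(th)) / 2
  sel <- selection(rbind(c(5, y0), c(5 + L * cos(th), y0 + L * sin(th))),
                   linewidth = 1)
  prof <- extract_profile(sim$image, sel)
  ex <- extract_features(prof, pattern_spec("bands", 1))
  spacing <- mean(ex$lengths)
  expect_equal(spacing, 25 / cos(th), tolerance = 0.002)
  # and the closed form predicts the same +0.38% inflation
  expect_lt(abs((spacing / 25 - 1) - angular_length_error(5)), 2e-4)
})

test_that("angular length error follows 1/cos(theta) - 1", {
  expect_equal(angular_length_error(0), 0)
  expect_equal(angular_length_error(5), 0.0038, tolerance = 1e-2)
  expect_equal(angular_length_error(60), 1.0, tolerance = 1e-12)
  expect_error(angular_length_error(90), class = "domain_error")
})

test_that("background variance of low-SNR profiles decreases with linewidth", {
  seeds <- patternkit:::derive_seeds(501, 25)
  lws <- c(1, 3, 7, 12)
  bg_var <- sapply(lws, function(lw) {
    mean(sapply(seeds, function(s) {
      sim <- simulate_image(simulation_config(snr = 2, seed = s))
      prof <- extract_profile(sim$image, mid_selection(sim$image, linewidth = lw))
      nm <- prof$normalization[["1"]]
      raw <- prof$intensities[["1"]] * (nm[2] - nm[1]) + nm[1]
      # background: samples far from every true band
      bg <- sapply(prof$positions, function(p)
        min(abs(p - sim$truth$positions)) > 6)
      var(raw[bg])
    }))
  })
  expect_true(all(diff(bg_var) < 0))
})

test_that("rolling-ball correction flattens gradients but preserves band contrast", {
  # uniform image -> all-zero output
  flat <- image_data(matrix(7, 40, 40))
  out <- subtract_background_em(flat, radius = 10)
  expect_lt(max(abs(out$pixels)), 1e-8)

  # light background with a dark gradient plus dark bands
  nr <- 60; nc <- 200
  grad <- outer(rep(1, nr), seq(0, 30, length.out = nc))
  m <- 100 + grad
  band_cols <- as.vector(outer(0:3, seq(20, 180, by = 25), `+`))
  m[, band_cols] <- m[, band_cols] - 40
  out <- subtract_background_em(image_data(m), radius = 50)
  o <- out$pixels[1, 1, , ]
  bg_cols <- setdiff(seq_len(nc)[10:(nc - 10)], c(band_cols, band_cols + 1, band_cols - 1))
  band_amp <- mean(o[, band_cols]) - mean(o[, bg_cols])
  expect_lt(abs(band_amp - 40) / 40, 0.05)
  # residual background variation reduced by >= 90%
  expect_lt(max(o[, bg_cols]) - min(o[, bg_cols]), 0.1 * 30)

  expect_error(subtract_background_em(flat, radius = 0), class = "parameter_error")
})

test_that("selection JSON round trip preserves geometry and metadata", {
  s1 <- selection(rbind(c(1.5, 2.25), c(10, 3), c(20, 8)), linewidth = 5,
                  frame = 2, label = "a")
  s2 <- selection(rbind(c(0, 0), c(4, 4)), label = "b")
  tf <- tempfile(fileext = ".json")
  write_selections_json(list(s1, s2), tf)
  back <- read_selections_json(tf)
  expect_length(back, 2)
  expect_equal(back[[1]]$vertices, s1$vertices)
  expect_equal(back[[1]]$linewidth, 5L)
  expect_equal(back[[1]]$frame, 2L)
  expect_equal(back[[2]]$label, "b")
})
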