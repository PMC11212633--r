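# Selection interpolation across frames and feature tracking.

test_that("identical keyframes interpolate to identical 100-point selections", {
  k0 <- selection(rbind(c(0, 5), c(50, 5)), frame = 0, label = "k")
  k1 <- selection(rbind(c(0, 5), c(50, 5)), frame = 10, label = "k")
  sels <- interpolate_selections(list(k0, k1))
  expect_length(sels, 11)
  for (s in sels) {
    expect_equal(nrow(s$vertices), 100)
    expect_equal(s$vertices, sels[["0"]]$vertices)
  }
})

test_that("a translated keyframe pair interpolates linearly (midpoint identity)", {
  k0 <- selection(rbind(c(0, 5), c(50, 5)), frame = 0)
  k1 <- selection(rbind(c(10, 5), c(60, 5)), frame = 10)
  sels <- interpolate_selections(list(k0, k1))
  mid <- sels[["5"]]$vertices
  expect_equal(mid[, "x"], sels[["0"]]$vertices[, "x"] + 5, tolerance = 1e-9)
  expect_equal(mid[, "y"], sels[["0"]]$vertices[, "y"], tolerance = 1e-9)
})

test_that("interpolated path length blends the keyframe lengths", {
  k0 <- selection(rbind(c(0, 0), c(40, 0)), frame = 0)   # length 40
  k1 <- selection(rbind(c(0, 0), c(60, 0)), frame = 4)   # length 60
  sels <- interpolate_selections(list(k0, k1))
  L2 <- patternkit:::polyline_length(sels[["2"]]$vertices)
  expect_equal(L2, 50, tolerance = 0.005)
  expect_error(interpolate_selections(list(k0)), class = "parameter_error")
})

test_that("static detections produce constant tracks with zero variance", {
  centers <- replicate(30, seq(25, 250, by = 25), simplify = FALSE)
  ts <- track_features(centers, rep(270, 30))
  expect_equal(length(unique(ts$tracks$track_id)), 10)
  for (id in unique(ts$tracks$track_id)) {
    pos <- ts$tracks$position_px[ts$tracks$track_id == id]
    expect_length(pos, 30)
    expect_equal(var(pos), 0)
  }
})

test_that("uniform contraction appears as the same normalized ramp in every track", {
  f <- seq(1, 0.9, length.out = 20)
  centers <- lapply(f, function(s) 135 + (seq(25, 250, by = 25) - 135) * s)
  ts <- track_features(centers, rep(270, 20))
  nl <- ts$norm_lengths
  for (id in unique(nl$track_id)) {
    series <- nl$norm_length[nl$track_id == id][order(nl$frame[nl$track_id == id])]
    expect_equal(series, f / mean(f), tolerance = 1e-9)
  }
})

test_that("a missing detection is bridged within the 20-frame gap rule", {
  full <- seq(25, 250, by = 25)
  centers <- replicate(10, full, simplify = FALSE)
  centers[[5]] <- full[-4]   # lose one band in frame 5
  ts <- track_features(centers, rep(270, 10))
  expect_equal(length(unique(ts$tracks$track_id)), 10)
  tr4 <- ts$tracks[abs(ts$tracks$position_px - full[4]) < 1, ]
  expect_equal(sort(tr4$frame), setdiff(0:9, 4))
})

test_that("linking decisions are invariant under per-frame rescaling", {
  set.seed(42)
  base <- seq(25, 250, by = 25)
  centers <- lapply(1:10, function(t) base + rnorm(10, 0, 0.5))
  ts1 <- track_features(centers, rep(270, 10))
  scale <- seq(1, 2, length.out = 10)
  centers2 <- Map(function(c0, s) c0 * s, centers, scale)
  ts2 <- track_features(centers2, 270 * scale)
  expect_equal(ts1$tracks$track_id, ts2$tracks$track_id)
  expect_equal(ts1$tracks$frame, ts2$tracks$frame)
})

test_that("tracking a simulated contracting movie recovers the length time series", {
  contraction <- 1 + 0.1 * sin(2 * pi * (0:14) / 15)
  mv <- simulate_movie(simulation_config(snr = 8, seed = 31), contraction)
  d <- dim(mv$image$pixels)
  ymid <- (d[3] - 1) / 2
  keys <- list(
    selection(rbind(c(0, ymid), c(d[4] - 1, ymid)), linewidth = 7, frame = 0, label = "k"),
    selection(rbind(c(0, ymid), c(d[4] - 1, ymid)), linewidth = 7, frame = 14, label = "k")
  )
  res <- timelapse_extract(mv$image, keys, pattern_spec("bands", 1))
  fl <- res$tracks$frame_lengths
  truth <- 25 * contraction[fl$frame + 1]
  expect_gt(cor(fl$mean_length_px, truth), 0.99)
})
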