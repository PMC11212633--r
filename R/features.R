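# Subpixel feature extraction inside each segmented pattern repeat:
# band centers by Gaussian fit, block edges by sigmoid fit, and the
# sarcomeric-actin "block with middle band" motif by a central Gaussian fit
# plus quantile half-maximum edge crossings.

#' Pattern specification
#'
#' Declarative description of the expected motif in one channel.
#'
#' @param kind `"bands"` (one or more isolated bright bands), `"blocks"`
#'   (plateaus with rising/falling flanks), or `"block_with_middle_band"`
#'   (a plateau with a brighter central band, the typical phalloidin /
#'   sarcomeric-actin motif).
#' @param count Number of bands or blocks per pattern (1 for
#'   block-with-middle-band).
#' @param edge_threshold For blocks: fraction of the plateau height at which
#'   the edge is reported (default 0.5, the sigmoid inflection point).
#' @return Object of class `pattern_spec`.
#' @export
pattern_spec <- function(kind = c("bands", "blocks", "block_with_middle_band"),
                         count = 1, edge_threshold = 0.5) {
  kind <- match.arg(kind)
  if (count < 1) stop_pk("parameter_error", "count must be >= 1")
  if (edge_threshold <= 0 || edge_threshold >= 1)
    stop_pk("parameter_error", "edge_threshold must be in (0, 1)")
  if (kind == "block_with_middle_band") count <- 1
  structure(list(kind = kind, count = as.integer(count),
                 edge_threshold = edge_threshold),
            class = "pattern_spec")
}

# 3-point moving average, used only for local-maximum *detection*;
# fits always run on the raw samples.
smooth3 <- function(y) {
  n <- length(y)
  if (n < 3) return(y)
  c(y[1], (y[-c(1, 2)] + y[-c(1, n)] + y[-c(n - 1, n)]) / 3, y[n])
}

#' Fit band centers in a window
#'
#' Detects the `n_bands` highest local maxima (after a light 3-point
#' moving-average smoothing used for detection only) and least-squares fits
#' a Gaussian plus constant offset around each on a sub-window of half-width
#' `max(3, round(period/4))` px — wide enough to include the flanks that
#' carry most of the localization information. Returns fitted centers
#' sorted by position; a band whose fit fails or drifts outside its
#' sub-window falls back to the integer maximum and is flagged.
#'
#' @param x Positions of the window samples (pixels).
#' @param y Intensities of the window samples.
#' @param n_bands Number of bands expected.
#' @param period Pattern period in pixels (sets the fit sub-window size);
#'   default: window span.
#' @param weights Optional per-sample fit weights (see [fit_gaussian()]).
#' @return data.frame with one row per band: `position`, `amplitude`,
#'   `sigma`, `offset`, `converged`.
#' @export
fit_bands <- function(x, y, n_bands, period = NULL, weights = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(period)) period <- diff(range(x))
  ys <- smooth3(y)
  lm_idx <- local_maxima(ys)
  if (length(lm_idx) < n_bands)
    stop_pk("missing_band", "found %d local maxima, expected %d bands",
            length(lm_idx), n_bands)
  picked <- lm_idx[order(ys[lm_idx], decreasing = TRUE)][seq_len(n_bands)]
  picked <- sort(picked)
  half <- max(3L, as.integer(round(period / 4)))
  out <- lapply(picked, function(i) {
    sel <- which(x >= x[i] - half & x <= x[i] + half)
    if (length(sel) < 4) {
      return(data.frame(position = x[i], amplitude = y[i], sigma = NA_real_,
                        offset = 0, converged = FALSE))
    }
    fit <- fit_gaussian(x[sel], y[sel], center_init = x[i],
                        weights = weights[sel])
    if (fit$converged && abs(fit$center - x[i]) <= half) {
      data.frame(position = fit$center, amplitude = fit$amplitude,
                 sigma = fit$sigma, offset = fit$offset, converged = TRUE)
    } else {
      data.frame(position = x[i], amplitude = y[i], sigma = NA_real_,
                 offset = 0, converged = FALSE)
    }
  })
  res <- do.call(rbind, out)
  res[order(res$position), , drop = FALSE]
}

#' Fit block edges in a window
#'
#' Splits the window at its intensity-weighted center, fits an ascending
#' sigmoid to the left part and a descending one to the right, and reports
#' each edge at the requested threshold of the plateau height (0.5 gives
#' the inflection point, i.e. the sigmoid midpoint parameter itself).
#'
#' @param x,y Window samples.
#' @param edge_threshold Fraction of plateau height defining the edge.
#' @return List with `left_edge`, `right_edge` (pixels), `left_fit`,
#'   `right_fit` (sigmoid parameters), `converged`.
#' @export
fit_block <- function(x, y, edge_threshold = 0.5) {
  stopifnot(length(x) == length(y))
  xc <- sum(x * y) / sum(y)
  left_sel <- x <= xc
  right_sel <- x >= xc
  if (sum(left_sel) < 4 || sum(right_sel) < 4)
    stop_pk("failed_segment", "window too small for block edge fits")
  lf <- fit_sigmoid(x[left_sel], y[left_sel], ascending = TRUE)
  rf <- fit_sigmoid(x[right_sel], y[right_sel], ascending = FALSE)
  if (!lf$converged || !rf$converged)
    stop_pk("failed_segment", "sigmoid edge fit did not converge")
  le <- sigmoid_threshold_position(lf, edge_threshold)
  re <- sigmoid_threshold_position(rf, edge_threshold)
  if (!(le < re))
    stop_pk("failed_segment", "block edges out of order")
  list(left_edge = le, right_edge = re, left_fit = lf, right_fit = rf,
       converged = TRUE)
}

#' Fit the block-with-middle-band (sarcomeric actin) motif
#'
#' The middle band is localized by a Gaussian fit of the central maximum.
#' For the edges, the central 10 pixels of the pattern are excluded; on each
#' remaining side the 90% intensity quantile is computed and the edge is the
#' crossing of half that value — the last upward crossing before the
#' excluded zone on the left, the first downward crossing after it on the
#' right — linearly interpolated between samples.
#'
#' @param x,y Window samples.
#' @return List with `left_edge`, `middle_band`, `right_edge`, `band_fit`.
#' @export
fit_block_with_middle_band <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (max(y) - min(y) <= 0)
    stop_pk("failed_segment", "flat window: no motif to fit")
  i0 <- which.max(smooth3(y))
  half <- max(3L, as.integer(round(diff(range(x)) / 8)))
  sel <- which(x >= x[i0] - half & x <= x[i0] + half)
  if (length(sel) < 4) stop_pk("failed_segment", "window too small for middle-band fit")
  bf <- fit_gaussian(x[sel], y[sel], center_init = x[i0])
  center <- if (bf$converged) bf$center else x[i0]

  excl_lo <- center - 5; excl_hi <- center + 5   # avoid 10 px at the center
  left_idx <- which(x < excl_lo)
  right_idx <- which(x > excl_hi)
  if (length(left_idx) < 2 || length(right_idx) < 2)
    stop_pk("failed_segment", "pattern too narrow around the middle band")

  q_l <- stats::quantile(y[left_idx], 0.9, names = FALSE)
  q_r <- stats::quantile(y[right_idx], 0.9, names = FALSE)
  hv_l <- q_l / 2; hv_r <- q_r / 2

  # left edge: last upward crossing of hv_l before the excluded zone
  li <- left_idx
  up <- which(y[li[-length(li)]] < hv_l & y[li[-1]] >= hv_l)
  if (length(up) == 0) stop_pk("failed_segment", "no left-edge crossing found")
  i <- li[up[length(up)]]
  left_edge <- interp_crossing(x, y, i, hv_l)

  # right edge: first downward crossing of hv_r after the excluded zone
  ri <- right_idx
  dn <- which(y[ri[-length(ri)]] >= hv_r & y[ri[-1]] < hv_r)
  if (length(dn) == 0) stop_pk("failed_segment", "no right-edge crossing found")
  i <- ri[dn[1]]
  right_edge <- interp_crossing(x, y, i, hv_r)

  list(left_edge = left_edge, middle_band = center, right_edge = right_edge,
       band_fit = bf)
}

#' Canonical pattern center and feature grouping
#'
#' Defines the center of a pattern from its features: the mean of band
#' centers (or of block edge midpoints), or the middle-band position for the
#' block-with-middle-band motif. When `positions` holds more features than
#' one pattern's multiplicity, consecutive features are grouped into
#' patterns of `spec$count`, choosing the grouping phase that minimizes the
#' total within-pattern spread; on ties, the phase placing brighter features
#' closer to the pattern centers wins.
#'
#' @param positions Feature positions (band centers, or edge midpoints),
#'   sorted or not.
#' @param spec A [pattern_spec()].
#' @param intensities Optional feature intensities (for the tie-break).
#' @return List with `centers` (one per pattern) and `groups` (list of
#'   index vectors into the sorted positions).
#' @export
canonicalize_pattern <- function(positions, spec, intensities = NULL) {
  ord <- order(positions)
  pos <- positions[ord]
  ints <- if (is.null(intensities)) rep(1, length(pos)) else intensities[ord]
  m <- spec$count
  if (spec$kind == "block_with_middle_band" || m == 1) {
    return(list(centers = pos, groups = as.list(seq_along(pos))))
  }
  n <- length(pos)
  best <- NULL
  for (phase in 0:(m - 1)) {
    if (1 + phase > n - m + 1) next
    starts <- seq(1 + phase, n - m + 1, by = m)
    groups <- lapply(starts, function(s) s:(s + m - 1))
    spread <- sum(vapply(groups, function(g) max(pos[g]) - min(pos[g]), 0))
    centers <- vapply(groups, function(g) mean(pos[g]), 0)
    # intensity score: brighter features nearer their pattern center
    score <- sum(vapply(seq_along(groups), function(k) {
      g <- groups[[k]]
      -sum(ints[g] * abs(pos[g] - centers[k]))
    }, 0))
    cand <- list(spread = spread, score = score, centers = centers, groups = groups)
    if (is.null(best) || spread < best$spread - 1e-9 ||
        (abs(spread - best$spread) <= 1e-9 && score > best$score)) {
      best <- cand
    }
  }
  if (is.null(best))
    stop_pk("parameter_error", "not enough features to form one pattern")
  list(centers = best$centers, groups = best$groups)
}

# Inverse-variance weights for photon-counting profiles: the raw intensity
# is reconstructed from the stored normalization, and the Poisson variance
# scales with it. Floored at 2% of the maximum to keep weights bounded.
poisson_weights <- function(profile, channel) {
  nm <- profile$normalization[[as.character(channel)]]
  if (is.null(nm) || nm["raw_min"] < 0) return(NULL)
  y <- profile_channel(profile, channel)
  raw <- y * (nm["raw_max"] - nm["raw_min"]) + nm["raw_min"]
  1 / pmax(raw, 0.02 * max(raw))
}

segment_feature_rows <- function(profile, channel, seg_row, spec, period, label) {
  x_all <- profile$positions
  y_all <- profile_channel(profile, channel)
  w_all <- poisson_weights(profile, channel)
  sel <- which(x_all >= seg_row$left & x_all <= seg_row$right)
  x <- x_all[sel]; y <- y_all[sel]; w <- w_all[sel]
  base <- data.frame(selection_label = label, channel = channel,
                     segment_index = seg_row$index, stringsAsFactors = FALSE)
  na_fit <- list(amplitude = NA_real_, center = NA_real_, sigma = NA_real_,
                 offset = NA_real_, low = NA_real_, high = NA_real_,
                 midpoint = NA_real_, slope = NA_real_)
  row_of <- function(kind, pos, fit = list()) {
    p <- utils::modifyList(na_fit, fit[names(fit) %in% names(na_fit)])
    cbind(base, data.frame(feature_kind = kind, position_px = pos,
                           as.data.frame(p), stringsAsFactors = FALSE))
  }
  switch(spec$kind,
    bands = {
      bands <- fit_bands(x, y, spec$count, period = period, weights = w)
      do.call(rbind, lapply(seq_len(nrow(bands)), function(i) {
        b <- bands[i, ]
        row_of("band_center", b$position,
               list(amplitude = b$amplitude, center = b$position,
                    sigma = b$sigma, offset = b$offset))
      }))
    },
    blocks = {
      # count > 1: split the window into `count` equal sub-windows
      bounds <- seq(min(x), max(x), length.out = spec$count + 1)
      do.call(rbind, lapply(seq_len(spec$count), function(k) {
        ss <- which(x >= bounds[k] & x <= bounds[k + 1])
        blk <- fit_block(x[ss], y[ss], spec$edge_threshold)
        rbind(
          row_of("block_left_edge", blk$left_edge, blk$left_fit),
          row_of("block_right_edge", blk$right_edge, blk$right_fit)
        )
      }))
    },
    block_with_middle_band = {
      mb <- fit_block_with_middle_band(x, y)
      rbind(
        row_of("block_left_edge", mb$left_edge),
        row_of("middle_band", mb$middle_band,
               list(amplitude = mb$band_fit$amplitude, center = mb$band_fit$center,
                    sigma = mb$band_fit$sigma, offset = mb$band_fit$offset)),
        row_of("block_right_edge", mb$right_edge)
      )
    }
  )
}

pattern_center_from_rows <- function(rows, spec) {
  switch(spec$kind,
    bands = mean(rows$position_px[rows$feature_kind == "band_center"]),
    blocks = {
      le <- rows$position_px[rows$feature_kind == "block_left_edge"]
      re <- rows$position_px[rows$feature_kind == "block_right_edge"]
      mean((le + re) / 2)
    },
    block_with_middle_band = rows$position_px[rows$feature_kind == "middle_band"]
  )
}

#' Run the full extraction pipeline on one profile
#'
#' Period estimation, segmentation (on one driving channel, shared by all
#' channels), and per-segment subpixel fitting according to each channel's
#' pattern spec. Per-pattern lengths are the distances between consecutive
#' pattern centers of the driving channel. Segments whose fits fail are
#' reported with a failure reason and excluded from the lengths.
#'
#' @param profile An [extract_profile()] result.
#' @param spec A [pattern_spec()], or a list of them (one per channel).
#' @param driving_channel Channel used for period estimation and
#'   segmentation; default: the channel whose spec is
#'   `block_with_middle_band` if present, else the first channel.
#' @return Object of class `feature_extraction`: `features` (data.frame),
#'   `centers` (per channel), `lengths` (driving channel), `period`,
#'   `segmentation`, `failed` (data.frame of failed segments).
#' @export
extract_features <- function(profile, spec, driving_channel = NULL) {
  chans <- profile$channels
  specs <- if (inherits(spec, "pattern_spec")) {
    stats::setNames(rep(list(spec), length(chans)), as.character(chans))
  } else {
    stopifnot(length(spec) == length(chans))
    stats::setNames(spec, as.character(chans))
  }
  if (is.null(driving_channel)) {
    kinds <- vapply(specs, function(s) s$kind, "")
    driving_channel <- if (any(kinds == "block_with_middle_band")) {
      chans[which(kinds == "block_with_middle_band")[1]]
    } else chans[1]
  }
  pe <- estimate_period(profile, driving_channel)
  segres <- segment_profile(profile, driving_channel, pe$period)
  segs <- segres$segments

  features <- NULL
  failed <- data.frame(channel = integer(0), segment_index = integer(0),
                       reason = character(0), stringsAsFactors = FALSE)
  label <- profile$source$label
  for (ch in chans) {
    sp <- specs[[as.character(ch)]]
    for (i in seq_len(nrow(segs))) {
      rows <- tryCatch(
        segment_feature_rows(profile, ch, segs[i, ], sp, pe$period, label),
        patternkit_error = function(e) e
      )
      if (inherits(rows, "condition")) {
        failed <- rbind(failed, data.frame(channel = ch,
                                           segment_index = segs$index[i],
                                           reason = conditionMessage(rows),
                                           stringsAsFactors = FALSE))
      } else {
        features <- rbind(features, rows)
      }
    }
  }
  if (is.null(features))
    stop_pk("too_few_patterns", "no segment produced any features")

  centers <- lapply(chans, function(ch) {
    sp <- specs[[as.character(ch)]]
    fch <- features[features$channel == ch, , drop = FALSE]
    segs_ok <- sort(unique(fch$segment_index))
    vapply(segs_ok, function(si) {
      pattern_center_from_rows(fch[fch$segment_index == si, , drop = FALSE], sp)
    }, 0)
  })
  names(centers) <- as.character(chans)
  drv_centers <- sort(centers[[as.character(driving_channel)]])
  lengths <- diff(drv_centers)
  structure(
    list(features = features, centers = centers, lengths = lengths,
         period = pe, segmentation = segres, specs = specs,
         driving_channel = driving_channel, failed = failed,
         profile = profile),
    class = "feature_extraction"
  )
}

#' @export
print.feature_extraction <- function(x, ...) {
  cat(sprintf("<feature_extraction> %d features in %d segments; period %.2f px; %d pattern length(s)\n",
              nrow(x$features), nrow(x$segmentation$segments),
              x$period$period, length(x$lengths)))
  if (nrow(x$failed)) cat(sprintf("  %d failed segment fit(s)\n", nrow(x$failed)))
  invisible(x)
}

#' Write a feature table to CSV, one file per channel
#'
#' @param extraction A [extract_features()] result.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Paths of the files written.
#' @export
write_feature_csvs <- function(extraction, dir, prefix = "features") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in unique(extraction$features$channel)) {
    p <- file.path(dir, sprintf("%s_channel_%d.csv", prefix, ch - 1L))
    utils::write.csv(extraction$features[extraction$features$channel == ch, ],
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  paths
}
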