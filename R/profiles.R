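# Images, selections, and normalized intensity profiles.
#
# Coordinate convention: 0-based, pixel centers at integer coordinates;
# x runs along columns, y along rows. Positions along profiles are subpixel
# floats in pixel units.

#' Image container
#'
#' A multi-frame, multi-channel grayscale image. Pixels are stored in a
#' 4-d array indexed `(frame, channel, row, col)`, 0-based coordinates with
#' pixel centers at integers.
#'
#' @param pixels 4-d numeric array `(frame, channel, row, col)`, or a matrix
#'   (interpreted as a single frame/channel).
#' @param pixel_size Optional physical length per pixel (e.g. nm).
#' @return Object of class `image_data` with fields `pixels`, `pixel_size`,
#'   `n_frames`, `n_channels`.
#' @export
image_data <- function(pixels, pixel_size = NULL) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(1, 1, nrow(pixels), ncol(pixels)))
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 4)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop_pk("format_error", "image intensities must be finite and non-negative")
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         n_frames = dim(pixels)[1], n_channels = dim(pixels)[2]),
    class = "image_data"
  )
}

#' @export
print.image_data <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_data> %d frame(s), %d channel(s), %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

frame_matrix <- function(image, frame = 1, channel = 1) {
  image$pixels[frame, channel, , ]
}

# Separable Gaussian blur of a vector with reflective boundary handling.
gaussian_blur_1d <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  n <- length(v)
  # half-sample reflective padding: conserves total mass exactly for a
  # symmetric kernel
  left <- v[pmin(n, r:1)]
  right <- v[pmax(1, n:(n - r + 1))]
  padded <- c(left, v, right)
  as.numeric(stats::filter(padded, k, sides = 2))[(r + 1):(r + n)]
}

gaussian_blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  m <- apply(m, 2, gaussian_blur_1d, sigma = sigma)
  t(apply(m, 1, gaussian_blur_1d, sigma = sigma))
}

#' Load a TIFF image
#'
#' Reads a single- or multi-page TIFF. Pages become frames; a third array
#' dimension within a page becomes channels. Optional preprocessing for
#' difficult images: gray-value inversion (useful when the features of
#' interest are dark, e.g. electron microscopy) and isotropic Gaussian blur
#' (useful at very low SNR, at a small cost in resolution).
#'
#' @param path Path to a TIFF file.
#' @param invert If `TRUE`, each channel's values `v` become `max(v) - v`.
#' @param blur_sigma Gaussian blur sd in pixels, applied per channel per
#'   frame; 0 disables.
#' @param n_channels Optionally reinterpret a stack of single-channel pages
#'   as interleaved channels of this count.
#' @return An [image_data()].
#' @export
load_image <- function(path, invert = FALSE, blur_sigma = 0, n_channels = NULL) {
  if (!file.exists(path)) stop_pk("io_error", "cannot read image file '%s'", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e) stop_pk("io_error", "failed to read TIFF '%s': %s",
                                                path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  nd <- vapply(dims, length, 1L)
  if (any(nd > 3))
    stop_pk("format_error", "unsupported TIFF axis layout: page with %d axes", max(nd))
  shape <- dims[[1]][1:2]
  if (!all(vapply(dims, function(d) all(d[1:2] == shape), TRUE)))
    stop_pk("format_error", "TIFF pages differ in shape")
  nch <- if (nd[1] == 3) dims[[1]][3] else 1L
  arr <- array(0, dim = c(length(pages), nch, shape[1], shape[2]))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (length(dim(pg)) == 3) {
      for (ch in seq_len(nch)) arr[f, ch, , ] <- pg[, , ch]
    } else {
      arr[f, 1, , ] <- pg
    }
  }
  if (!is.null(n_channels) && nch == 1L && n_channels > 1L) {
    nf <- dim(arr)[1] / n_channels
    if (nf != floor(nf))
      stop_pk("format_error", "page count %d not divisible by %d channels",
              dim(arr)[1], n_channels)
    arr2 <- array(0, dim = c(nf, n_channels, shape[1], shape[2]))
    for (f in seq_len(nf)) for (ch in seq_len(n_channels))
      arr2[f, ch, , ] <- arr[(f - 1) * n_channels + ch, 1, , ]
    arr <- arr2
  }
  for (f in seq_len(dim(arr)[1])) {
    for (ch in seq_len(dim(arr)[2])) {
      m <- arr[f, ch, , ]
      if (invert) m <- max(m) - m
      if (blur_sigma > 0) m <- gaussian_blur_matrix(m, blur_sigma)
      arr[f, ch, , ] <- m
    }
  }
  image_data(arr)
}

#' Write an image to TIFF
#'
#' Intensities are rescaled to the unit interval for storage (the analysis
#' pipeline is invariant to global intensity scale). Each frame becomes one
#' page; up to 4 channels are stored as samples per pixel.
#'
#' @param image An [image_data()].
#' @param path Output path.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "image_data"))
  d <- dim(image$pixels)
  if (d[2] > 4)
    stop_pk("format_error", "TIFF writer supports at most 4 channels, got %d", d[2])
  mx <- max(image$pixels)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(d[1]), function(f) {
    if (d[2] == 1) {
      image$pixels[f, 1, , ] / mx
    } else {
      pg <- array(0, dim = c(d[3], d[4], d[2]))
      for (ch in seq_len(d[2])) pg[, , ch] <- image$pixels[f, ch, , ] / mx
      pg
    }
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

# --- rolling-ball background -------------------------------------------------

# Grayscale opening with a ball-shaped (spherical cap) structuring element,
# the classic rolling-ball background estimate. For large radii the image is
# shrunk (block minima), opened, and the background re-expanded by bilinear
# interpolation, as in the standard implementation of the algorithm.
rolling_ball_background <- function(m, radius) {
  shrink <- if (radius <= 10) 1L else if (radius <= 30) 2L else if (radius <= 100) 4L else 8L
  if (shrink > 1L) {
    nr <- nrow(m); nc <- ncol(m)
    nr2 <- ceiling(nr / shrink); nc2 <- ceiling(nc / shrink)
    small <- matrix(Inf, nr2, nc2)
    for (i in seq_len(nr2)) for (j in seq_len(nc2)) {
      rows <- ((i - 1) * shrink + 1):min(nr, i * shrink)
      cols <- ((j - 1) * shrink + 1):min(nc, j * shrink)
      small[i, j] <- min(m[rows, cols])
    }
    bg_small <- ball_opening(small, radius / shrink)
    # bilinear re-expansion to the original grid
    xi <- (seq_len(nc) - 1) / shrink - (shrink - 1) / (2 * shrink)
    yi <- (seq_len(nr) - 1) / shrink - (shrink - 1) / (2 * shrink)
    bg <- matrix(0, nr, nc)
    for (i in seq_len(nr)) {
      bg[i, ] <- bilinear_row(bg_small, yi[i], xi)
    }
    pmin(bg, m)
  } else {
    ball_opening(m, radius)
  }
}

bilinear_row <- function(m, y, xs) {
  nr <- nrow(m); nc <- ncol(m)
  y <- min(max(y, 0), nr - 1)
  xs <- pmin(pmax(xs, 0), nc - 1)
  r0 <- floor(y); r1 <- min(r0 + 1, nr - 1); fy <- y - r0
  c0 <- floor(xs); c1 <- pmin(c0 + 1, nc - 1); fx <- xs - c0
  v00 <- m[r0 + 1, c0 + 1]; v01 <- m[r0 + 1, c1 + 1]
  v10 <- m[r1 + 1, c0 + 1]; v11 <- m[r1 + 1, c1 + 1]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

ball_opening <- function(m, radius) {
  # non-flat structuring element: ball surface z(dx,dy)
  r <- ceiling(radius)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- offs$dx^2 + offs$dy^2
  keep <- d2 <= radius^2
  offs <- offs[keep, ]
  z <- sqrt(pmax(0, radius^2 - d2[keep]))
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(mat, dy, dx, fill) {
    out <- matrix(fill, nr, nc)
    rs <- max(1, 1 - dy):min(nr, nr - dy)
    cs <- max(1, 1 - dx):min(nc, nc - dx)
    out[rs, cs] <- mat[rs + dy, cs + dx]
    out
  }
  eroded <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(offs)))
    eroded <- pmin(eroded, shift(m, offs$dy[k], offs$dx[k], Inf) - z[k])
  dilated <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(offs)))
    dilated <- pmax(dilated, shift(eroded, -offs$dy[k], -offs$dx[k], -Inf) + z[k])
  dilated
}

#' Rolling-ball background correction for electron microscopy images
#'
#' Electron-dense features appear dark on a light, slowly varying background.
#' This applies a rolling-ball background subtraction in light-background
#' mode, without pre-smoothing, and returns the result gray-inverted so the
#' electron-dense features become bright — analogous to fluorescence images
#' and directly usable by the rest of the pipeline.
#'
#' @param image Single-channel [image_data()].
#' @param radius Ball radius in pixels (default 50).
#' @return An [image_data()] with bright features on a near-zero background.
#' @export
subtract_background_em <- function(image, radius = 50) {
  stopifnot(inherits(image, "image_data"))
  if (radius <= 0) stop_pk("parameter_error", "rolling-ball radius must be positive")
  if (image$n_channels != 1)
    stop_pk("parameter_error", "background correction expects a single-channel image")
  arr <- image$pixels
  for (f in seq_len(dim(arr)[1])) {
    m <- arr[f, 1, , ]
    inv <- max(m) - m               # light background mode: work gray-inverted
    bg <- rolling_ball_background(inv, radius)
    arr[f, 1, , ] <- pmax(0, inv - bg)
  }
  image_data(arr, pixel_size = image$pixel_size)
}

# --- selections --------------------------------------------------------------

#' Polyline selection
#'
#' A user region of interest: an ordered polyline with a stroke linewidth.
#'
#' @param vertices n x 2 matrix (or data.frame) of `(x, y)` subpixel
#'   coordinates, 0-based.
#' @param linewidth Stroke width in pixels (>= 1); intensities are averaged
#'   over this width perpendicular to the path.
#' @param frame 0-based frame index the selection belongs to.
#' @param label Identifier string.
#' @return Object of class `selection`.
#' @export
selection <- function(vertices, linewidth = 1, frame = 0, label = "sel") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  stopifnot(ncol(vertices) == 2)
  if (nrow(vertices) < 2)
    stop_pk("parameter_error", "a selection needs at least 2 vertices")
  if (polyline_length(vertices) <= 0)
    stop_pk("degenerate_selection", "selection has zero path length")
  if (linewidth < 1) stop_pk("parameter_error", "linewidth must be >= 1")
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, linewidth = as.integer(round(linewidth)),
                 frame = as.integer(frame), label = label),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("<selection '%s'> %d vertices, linewidth %d, frame %d, length %.1f px\n",
              x$label, nrow(x$vertices), x$linewidth, x$frame,
              polyline_length(x$vertices)))
  invisible(x)
}

# Sample points and unit tangents along a polyline at arc-length step 1 px.
path_samples <- function(vertices) {
  seg <- diff(vertices)
  len <- sqrt(rowSums(seg^2))
  keep <- len > 0
  starts <- vertices[-nrow(vertices), , drop = FALSE][keep, , drop = FALSE]
  seg <- seg[keep, , drop = FALSE]
  len <- len[keep]
  s_cum <- c(0, cumsum(len))
  total <- s_cum[length(s_cum)]
  s_out <- seq(0, floor(total), by = 1)
  seg_idx <- findInterval(s_out, s_cum, rightmost.closed = TRUE)
  seg_idx[seg_idx > length(len)] <- length(len)
  frac <- (s_out - s_cum[seg_idx]) / len[seg_idx]
  tang <- seg / len
  pts <- starts[seg_idx, , drop = FALSE] + seg[seg_idx, , drop = FALSE] * frac
  list(s = s_out, points = pts, tangents = tang[seg_idx, , drop = FALSE])
}

# Vectorized bilinear interpolation on one channel matrix, 0-based coords.
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  if (any(x < -0.5 | x > nc - 0.5 | y < -0.5 | y > nr - 0.5))
    stop_pk("bounds_error", "selection (with linewidth) extends outside the image")
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  c0 <- floor(x); r0 <- floor(y)
  c1 <- pmin(c0 + 1, nc - 1); r1 <- pmin(r0 + 1, nr - 1)
  fx <- x - c0; fy <- y - r0
  v00 <- m[cbind(r0 + 1, c0 + 1)]; v01 <- m[cbind(r0 + 1, c1 + 1)]
  v10 <- m[cbind(r1 + 1, c0 + 1)]; v11 <- m[cbind(r1 + 1, c1 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Extract a normalized intensity profile along a selection
#'
#' Samples the image every 1.0 px of path length along the polyline. At each
#' sample the intensity is the mean over `linewidth` equally spaced offsets
#' spanning the stroke width, taken perpendicular to the local path
#' direction, with bilinear interpolation of pixel values. Each channel is
#' then normalized so its minimum is 0 and its maximum is 1, which makes
#' multi-channel profiles directly comparable.
#'
#' @param image An [image_data()].
#' @param sel A [selection()].
#' @param channels Channel indices (1-based) to extract; default all.
#' @return Object of class `intensity_profile` with fields `positions`
#'   (pixel units, spacing 1), `intensities` (list, one numeric vector per
#'   channel), `normalization` (per-channel raw min/max), `source`.
#' @export
extract_profile <- function(image, sel, channels = NULL) {
  stopifnot(inherits(image, "image_data"), inherits(sel, "selection"))
  if (is.null(channels)) channels <- seq_len(image$n_channels)
  frame <- sel$frame + 1L
  if (frame < 1 || frame > image$n_frames)
    stop_pk("bounds_error", "selection frame %d outside image", sel$frame)
  ps <- path_samples(sel$vertices)
  lw <- sel$linewidth
  offsets <- if (lw == 1) 0 else seq(-(lw - 1) / 2, (lw - 1) / 2, length.out = lw)
  # normals: rotate tangent by 90 degrees
  nxs <- -ps$tangents[, 2]; nys <- ps$tangents[, 1]
  xs <- outer(ps$points[, 1], rep(1, length(offsets))) + outer(nxs, offsets)
  ys <- outer(ps$points[, 2], rep(1, length(offsets))) + outer(nys, offsets)
  intens <- list()
  normalization <- list()
  for (ch in channels) {
    m <- frame_matrix(image, frame, ch)
    vals <- matrix(bilinear_sample(m, as.vector(xs), as.vector(ys)), nrow = nrow(xs))
    raw <- rowMeans(vals)
    nm <- normalize_intensities(raw)
    intens[[as.character(ch)]] <- nm$values
    normalization[[as.character(ch)]] <- c(raw_min = nm$raw_min, raw_max = nm$raw_max)
  }
  structure(
    list(positions = ps$s, intensities = intens, normalization = normalization,
         channels = channels, source = sel),
    class = "intensity_profile"
  )
}

normalize_intensities <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo)
    stop_pk("degenerate_profile", "constant intensity profile: normalization undefined")
  list(values = (v - lo) / (hi - lo), raw_min = lo, raw_max = hi)
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples, %d channel(s), from '%s'\n",
              length(x$positions), length(x$intensities), x$source$label))
  invisible(x)
}

profile_channel <- function(profile, channel = 1) {
  key <- as.character(channel)
  if (!key %in% names(profile$intensities))
    stop_pk("parameter_error", "channel %s not present in profile", key)
  profile$intensities[[key]]
}

#' Relative length error from a misaligned straight selection
#'
#' A straight selection drawn at angle `theta` to the true pattern axis
#' stretches every measured length by `1/cos(theta)`. Returns the relative
#' error `1/cos(theta) - 1` as a fraction; e.g. a 5-degree misalignment
#' inflates lengths by only 0.38%.
#'
#' @param theta Misalignment angle in degrees, `0 <= theta < 90`.
#' @return Relative error (fraction).
#' @export
angular_length_error <- function(theta) {
  if (any(theta < 0 | theta >= 90))
    stop_pk("domain_error", "theta must satisfy 0 <= theta < 90 degrees")
  1 / cos(theta * pi / 180) - 1
}

# --- profile / selection I/O -------------------------------------------------

#' Write profiles to CSV
#'
#' Columns: `position_px`, then one `channel_<k>` column per channel
#' (0-based channel names).
#'
#' @param profile An [extract_profile()] result.
#' @param path Output CSV path.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(position_px = profile$positions)
  for (i in seq_along(profile$channels)) {
    df[[sprintf("channel_%d", profile$channels[i] - 1L)]] <-
      profile$intensities[[as.character(profile$channels[i])]]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save selections to JSON
#'
#' @param selections A list of [selection()] objects.
#' @param path Output JSON path.
#' @export
write_selections_json <- function(selections, path) {
  if (inherits(selections, "selection")) selections <- list(selections)
  payload <- lapply(selections, function(s) {
    list(label = s$label, frame = s$frame, linewidth = s$linewidth,
         vertices = unname(apply(s$vertices, 1, as.list)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read selections from JSON
#'
#' @param path JSON file written by [write_selections_json()].
#' @return List of [selection()] objects.
#' @export
read_selections_json <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(p) {
    verts <- do.call(rbind, lapply(p$vertices, function(v) c(v[[1]], v[[2]])))
    selection(verts, linewidth = p$linewidth, frame = p$frame, label = p$label)
  })
}
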