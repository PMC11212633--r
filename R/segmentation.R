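# Segmentation of a profile into individual pattern repeats by
# cross-correlation against an automatically chosen reference pattern.

#' Choose the reference pattern window
#'
#' The reference pattern is the window of width `round(period)` centered on
#' the global intensity maximum of the profile, shifted inward if that
#' center is too close to an end to fit the full width.
#'
#' @param profile An [extract_profile()] result.
#' @param channel Channel index (1-based).
#' @param period Estimated spatial period, pixels.
#' @return Integer vector `c(ref_left, ref_right)`, 0-based positions along
#'   the profile (inclusive window bounds).
#' @export
pick_reference <- function(profile, channel = 1, period) {
  x <- profile_channel(profile, channel)
  n <- length(x)
  w <- as.integer(round(period))
  if (n < w) stop_pk("segmentation_error", "profile (%d px) shorter than the period (%d px)", n, w)
  imax <- which.max(x)                       # 1-based sample index
  left <- imax - w %/% 2
  left <- min(max(1L, left), n - w + 1L)     # shift inward to keep full width
  c(ref_left = left - 1L, ref_right = left + w - 2L)
}

# Cross-correlation of the profile with the zero-mean reference pattern,
# evaluated at every integer center position (profile zero-padded beyond its
# ends, consistent with a near-zero normalized background).
cross_correlate_reference <- function(x, ref_left, ref_right) {
  ref <- x[(ref_left + 1):(ref_right + 1)]
  refz <- ref - mean(ref)
  w <- length(refz)
  half_l <- (w - 1L) %/% 2L                  # offsets: -half_l .. w-1-half_l
  n <- length(x)
  xp <- c(numeric(w), x, numeric(w))
  cc <- numeric(n)
  for (j in seq_len(w)) {
    off <- (j - 1L) - half_l
    cc <- cc + refz[j] * xp[(w + 1 + off):(w + n + off)]
  }
  cc
}

#' Segment a profile into pattern repeats
#'
#' Cross-correlates the profile with the reference pattern from
#' [pick_reference()], anchors at the highest cross-correlation peak, and
#' propagates outward in both directions: from each accepted peak the next
#' one is the largest local maximum of the cross-correlation inside the
#' search window starting half a period away and spanning a full period
#' (so repeat sizes between 50% and 150% of the period are tolerated).
#' A candidate peak is accepted only if it reaches `min_peak_fraction` of
#' the anchor peak's cross-correlation, which stops propagation from
#' walking onto noise bumps in the background beyond the pattern.
#' Peak positions are integer-precision at this stage; the subpixel work
#' happens later, inside each segment.
#'
#' @param profile An [extract_profile()] result.
#' @param channel Channel index (1-based) driving the segmentation.
#' @param period Spatial period in pixels (> 4).
#' @param min_peak_fraction Minimum cross-correlation of an accepted peak,
#'   as a fraction of the anchor peak (default 0.2).
#' @return Object of class `segmentation_result`: `segments` (data.frame
#'   with `index`, `center`, `left`, `right`, 0-based pixel positions),
#'   `reference`, `period_used`, `channel_used`.
#' @export
segment_profile <- function(profile, channel = 1, period,
                            min_peak_fraction = 0.2) {
  if (period <= 4) stop_pk("segmentation_error", "period must exceed 4 px")
  x <- profile_channel(profile, channel)
  n <- length(x)
  ref <- pick_reference(profile, channel, period)
  cc <- cross_correlate_reference(x, ref[1], ref[2])
  cc_min <- min_peak_fraction * max(cc)

  find_peak <- function(lo, hi) {
    lo <- max(1L, as.integer(round(lo))); hi <- min(n, as.integer(round(hi)))
    if (hi - lo < 2) return(NA_integer_)
    idx <- lo:hi
    lm <- local_maxima(cc[idx])
    if (length(lm) == 0) return(NA_integer_)   # monotone rise: conservative stop
    cand <- idx[lm]
    cand <- cand[cc[cand] >= cc_min]
    if (length(cand) == 0) return(NA_integer_)
    cand[which.max(cc[cand])]
  }

  anchor <- which.max(cc)
  centers <- anchor
  cur <- anchor
  repeat {                                     # rightward propagation
    nxt <- find_peak(cur + 0.5 * period, cur + 1.5 * period)
    if (is.na(nxt)) break
    centers <- c(centers, nxt); cur <- nxt
  }
  cur <- anchor
  repeat {                                     # leftward propagation
    nxt <- find_peak(cur - 1.5 * period, cur - 0.5 * period)
    if (is.na(nxt)) break
    centers <- c(nxt, centers); cur <- nxt
  }
  centers <- sort(unique(centers))
  if (length(centers) < 2)
    stop_pk("too_few_patterns", "fewer than 2 pattern repeats found")
  half <- period / 2
  segs <- data.frame(
    index = seq_along(centers),
    center = centers - 1,                      # 0-based positions
    left = pmax(0, round(centers - 1 - half)),
    right = pmin(n - 1, round(centers - 1 + half))
  )
  structure(
    list(segments = segs, reference = ref, period_used = period,
         channel_used = channel, cross_correlation = cc),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d segments, period %.2f px (channel %d)\n",
              nrow(x$segments), x$period_used, x$channel_used))
  invisible(x)
}
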