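# Time-lapse support: interpolation of user selections across frames and
# tracking of pattern reference positions over time.

#' Interpolate selections between keyframes
#'
#' Each user-drawn keyframe polyline is resampled to 100 points equally
#' spaced in arc length. For a frame `i + k` between keyframes `i` and `j`,
#' each of the 100 coordinates is the linear blend
#' `((j - i - k) * P_i + k * P_j) / (j - i)`, applied to x and y
#' independently. Frames outside the keyframe range are not generated.
#'
#' @param keyframes List of [selection()] objects with distinct `frame`
#'   fields (at least 2).
#' @return Named list (by frame index) of 100-vertex [selection()]s covering
#'   every frame between the first and last keyframe; keyframe frames
#'   contain their own resampled selection.
#' @export
interpolate_selections <- function(keyframes) {
  if (length(keyframes) < 2)
    stop_pk("parameter_error", "need at least 2 keyframe selections")
  frames <- vapply(keyframes, function(s) s$frame, 0L)
  if (anyDuplicated(frames))
    stop_pk("parameter_error", "duplicate keyframe frames")
  ord <- order(frames)
  keyframes <- keyframes[ord]; frames <- frames[ord]
  resampled <- lapply(keyframes, function(s) resample_polyline(s$vertices, 100))
  out <- list()
  for (k in seq_len(length(keyframes) - 1)) {
    fi <- frames[k]; fj <- frames[k + 1]
    Pi <- resampled[[k]]; Pj <- resampled[[k + 1]]
    for (f in fi:(fj - 1)) {
      w <- (f - fi) / (fj - fi)
      verts <- (1 - w) * Pi + w * Pj
      out[[as.character(f)]] <- selection(
        verts, linewidth = keyframes[[k]]$linewidth, frame = f,
        label = sprintf("%s_f%03d", keyframes[[k]]$label, f)
      )
    }
  }
  f_last <- frames[length(frames)]
  out[[as.character(f_last)]] <- selection(
    resampled[[length(resampled)]],
    linewidth = keyframes[[length(keyframes)]]$linewidth,
    frame = f_last,
    label = sprintf("%s_f%03d", keyframes[[length(keyframes)]]$label, f_last)
  )
  out
}

#' Track pattern reference positions through a time series
#'
#' Greedy nearest-neighbor linking of per-frame pattern centers. Because the
#' pattern size changes over time, all positions are rescaled by the
#' selection length of their frame before distances are computed; the match
#' radius is half the mean rescaled pattern size of the current frame. A
#' track not matched in a frame stays open for up to `max_gap` frames, then
#' closes; unmatched detections open new tracks.
#'
#' @param centers_by_frame List (one element per frame, in frame order) of
#'   numeric vectors of pattern reference positions, pixels.
#' @param selection_lengths Numeric vector of per-frame selection lengths,
#'   pixels (same length as `centers_by_frame`).
#' @param frames Optional frame indices (default `0:(n-1)`).
#' @param max_gap Maximum number of frames a track survives unmatched.
#' @return Object of class `track_set`: `tracks` (data.frame `track_id`,
#'   `frame`, `position_px`), `frame_lengths` (data.frame `frame`,
#'   `mean_length_px`), `norm_lengths` (data.frame `track_id`, `frame`,
#'   `length_px`, `norm_length` — per-sarcomere length normalized by its own
#'   track mean).
#' @export
track_features <- function(centers_by_frame, selection_lengths,
                           frames = NULL, max_gap = 20) {
  n_frames <- length(centers_by_frame)
  if (n_frames == 0) stop_pk("parameter_error", "no frames to track")
  stopifnot(length(selection_lengths) == n_frames)
  if (is.null(frames)) frames <- seq_len(n_frames) - 1L

  tracks <- list()   # each: list(id, frames, positions, last_u, last_frame)
  next_id <- 1L
  for (t in seq_len(n_frames)) {
    pos <- sort(centers_by_frame[[t]])
    if (length(pos) == 0) next
    u <- pos / selection_lengths[t]              # rescaled coordinates
    mean_size <- if (length(u) > 1) mean(diff(u)) else 0.1
    radius <- mean_size / 2

    open_idx <- which(vapply(tracks, function(tr) frames[t] - tr$last_frame <= max_gap, TRUE))
    assigned_det <- rep(FALSE, length(u))
    assigned_trk <- rep(FALSE, length(open_idx))
    if (length(open_idx)) {
      d <- abs(outer(vapply(tracks[open_idx], function(tr) tr$last_u, 0), u, `-`))
      ord <- order(d)
      for (k in ord) {
        if (d[k] > radius) break
        i <- (k - 1) %% length(open_idx) + 1     # track row
        j <- (k - 1) %/% length(open_idx) + 1    # detection col
        if (assigned_trk[i] || assigned_det[j]) next
        ti <- open_idx[i]
        tracks[[ti]]$frames <- c(tracks[[ti]]$frames, frames[t])
        tracks[[ti]]$positions <- c(tracks[[ti]]$positions, pos[j])
        tracks[[ti]]$last_u <- u[j]
        tracks[[ti]]$last_frame <- frames[t]
        assigned_trk[i] <- TRUE; assigned_det[j] <- TRUE
      }
    }
    for (j in which(!assigned_det)) {
      tracks[[length(tracks) + 1]] <- list(id = next_id, frames = frames[t],
                                           positions = pos[j], last_u = u[j],
                                           last_frame = frames[t])
      next_id <- next_id + 1L
    }
  }
  if (length(tracks) == 0) stop_pk("parameter_error", "no detections to track")

  tracks_df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track_id = tr$id, frame = tr$frames, position_px = tr$positions)
  }))
  tracks_df <- tracks_df[order(tracks_df$track_id, tracks_df$frame), ]

  frame_lengths <- do.call(rbind, lapply(seq_len(n_frames), function(t) {
    pos <- sort(centers_by_frame[[t]])
    data.frame(frame = frames[t],
               mean_length_px = if (length(pos) > 1) mean(diff(pos)) else NA_real_)
  }))

  # per-sarcomere lengths: distance to the next track (by mean position)
  mean_pos <- vapply(tracks, function(tr) mean(tr$positions), 0)
  ord <- order(mean_pos)
  norm_rows <- NULL
  for (k in seq_len(length(ord) - 1)) {
    a <- tracks[[ord[k]]]; b <- tracks[[ord[k + 1]]]
    common <- intersect(a$frames, b$frames)
    if (length(common) == 0) next
    la <- a$positions[match(common, a$frames)]
    lb <- b$positions[match(common, b$frames)]
    len <- lb - la
    norm_rows <- rbind(norm_rows, data.frame(
      track_id = a$id, frame = common, length_px = len,
      norm_length = len / mean(len)
    ))
  }
  structure(list(tracks = tracks_df, frame_lengths = frame_lengths,
                 norm_lengths = norm_rows),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks over %d frames\n",
              length(unique(x$tracks$track_id)),
              length(unique(x$tracks$frame))))
  invisible(x)
}

#' Run extraction on every frame of a movie and track the patterns
#'
#' Interpolates the keyframe selections, extracts features frame by frame
#' (frames whose extraction fails are skipped), and links the pattern
#' centers over time with [track_features()].
#'
#' @param image Multi-frame [image_data()].
#' @param keyframes List of keyframe [selection()]s (>= 2).
#' @param spec A [pattern_spec()] (or list per channel).
#' @return List with `tracks` (a `track_set`), `extractions` (per frame),
#'   `selections` (per frame).
#' @export
timelapse_extract <- function(image, keyframes, spec) {
  sels <- interpolate_selections(keyframes)
  frames <- as.integer(names(sels))
  centers <- list(); lens <- numeric(0); used <- integer(0)
  extractions <- list()
  for (i in seq_along(frames)) {
    ex <- tryCatch({
      prof <- extract_profile(image, sels[[i]])
      extract_features(prof, spec)
    }, patternkit_error = function(e) NULL)
    if (is.null(ex)) next
    ch <- as.character(ex$driving_channel)
    centers[[length(centers) + 1]] <- sort(ex$centers[[ch]])
    lens <- c(lens, polyline_length(sels[[i]]$vertices))
    used <- c(used, frames[i])
    extractions[[as.character(frames[i])]] <- ex
  }
  if (length(centers) < 2)
    stop_pk("too_few_patterns", "fewer than 2 frames produced extractions")
  list(tracks = track_features(centers, lens, frames = used),
       extractions = extractions, selections = sels)
}
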