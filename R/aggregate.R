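# Pooling of feature tables across selections and images: length
# distributions, the average aligned pattern profile, and its 2-d rendering.

#' Pool extractions and summarize pattern lengths
#'
#' Pools the per-pattern lengths of several extractions, computes their
#' mean/sd/n, and builds the average pattern profile: each pattern window is
#' aligned on its canonical center, linearly resampled onto a common grid of
#' `round(mean length) + 1` samples spanning one mean length, and averaged
#' per channel with equal weights.
#'
#' @param extractions A list of [extract_features()] results (a single one
#'   is accepted).
#' @return Object of class `analysis_summary`: `lengths` (data.frame with
#'   `source`, `pattern_index`, `length_px`), `length_stats`
#'   (`mean`, `sd`, `n`), `grid` (positions relative to the pattern center),
#'   `average_profile` (matrix, samples x channels).
#' @export
pool_and_summarize <- function(extractions) {
  if (inherits(extractions, "feature_extraction")) extractions <- list(extractions)
  stopifnot(length(extractions) >= 1)
  lens <- do.call(rbind, lapply(extractions, function(e) {
    if (length(e$lengths) == 0) return(NULL)
    data.frame(source = e$profile$source$label,
               pattern_index = seq_along(e$lengths),
               length_px = e$lengths, stringsAsFactors = FALSE)
  }))
  if (is.null(lens) || nrow(lens) == 0)
    stop_pk("empty_analysis", "no valid patterns to pool")
  mean_len <- mean(lens$length_px)
  l2 <- round(mean_len)
  grid <- seq(-l2 / 2, l2 / 2, by = 1)

  chans <- extractions[[1]]$profile$channels
  acc <- matrix(0, nrow = length(grid), ncol = length(chans))
  cnt <- matrix(0, nrow = length(grid), ncol = length(chans))
  for (e in extractions) {
    for (ci in seq_along(chans)) {
      ch <- chans[ci]
      centers <- e$centers[[as.character(ch)]]
      x <- e$profile$positions
      y <- profile_channel(e$profile, ch)
      for (c0 in centers) {
        v <- stats::approx(x, y, xout = c0 + grid)$y
        ok <- !is.na(v)
        acc[ok, ci] <- acc[ok, ci] + v[ok]
        cnt[ok, ci] <- cnt[ok, ci] + 1
      }
    }
  }
  avg <- acc / pmax(cnt, 1)
  avg[cnt == 0] <- NA_real_
  colnames(avg) <- sprintf("channel_%d", chans - 1L)
  structure(
    list(lengths = lens,
         length_stats = list(mean = mean_len,
                             sd = stats::sd(lens$length_px),
                             n = nrow(lens)),
         grid = grid, average_profile = avg, channels = chans),
    class = "analysis_summary"
  )
}

#' @export
print.analysis_summary <- function(x, ...) {
  cat(sprintf("<analysis_summary> n = %d patterns; length %.3f +/- %.3f px\n",
              x$length_stats$n, x$length_stats$mean,
              ifelse(is.na(x$length_stats$sd), 0, x$length_stats$sd)))
  invisible(x)
}

#' Render the average pattern as an image
#'
#' Replicates the average per-channel profile over `height` rows, producing
#' a multi-channel image of the average pattern (width = number of profile
#' samples). Useful for visualizing low-SNR patterns, since averaging
#' suppresses noise.
#'
#' @param summary An [pool_and_summarize()] result.
#' @param height Image height in pixels.
#' @param path Optional TIFF output path.
#' @return An [image_data()] (invisibly if `path` is given).
#' @export
render_average_image <- function(summary, height = 20, path = NULL) {
  stopifnot(inherits(summary, "analysis_summary"))
  prof <- summary$average_profile
  prof[is.na(prof)] <- 0
  nch <- ncol(prof)
  px <- array(0, dim = c(1, nch, height, nrow(prof)))
  for (ch in seq_len(nch)) {
    px[1, ch, , ] <- matrix(rep(prof[, ch], each = height), nrow = height)
  }
  img <- image_data(pmax(px, 0))
  if (!is.null(path)) {
    write_image(img, path)
    return(invisible(img))
  }
  img
}

#' Write analysis outputs
#'
#' Writes the pooled lengths CSV, a JSON summary (mean, sd, n pooled and per
#' selection), and the average-profile CSV.
#'
#' @param summary An [pool_and_summarize()] result.
#' @param dir Output directory.
#' @export
write_analysis <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(summary$lengths, file.path(dir, "lengths.csv"), row.names = FALSE)
  per_sel <- lapply(split(summary$lengths$length_px, summary$lengths$source),
                    function(v) list(mean = mean(v), sd = stats::sd(v), n = length(v)))
  jsonlite::write_json(
    list(pooled = summary$length_stats, per_selection = per_sel),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA, na = "null"
  )
  df <- data.frame(position_px = summary$grid, summary$average_profile)
  utils::write.csv(df, file.path(dir, "average_profile.csv"), row.names = FALSE)
  invisible(dir)
}
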