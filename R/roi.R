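# ImageJ ROI interop: read line-type ROIs (.roi files and .zip archives of
# them) into selections. The binary layout follows ImageJ's RoiDecoder:
# big-endian, "Iout" magic, fixed 64-byte header, then integer vertex
# coordinates relative to the bounding box (plus optional subpixel floats).

ROI_TYPES <- c(polygon = 0L, rect = 1L, oval = 2L, line = 3L, freeline = 4L,
               polyline = 5L, noRoi = 6L, freehand = 7L, traced = 8L,
               angle = 9L, point = 10L)
ROI_OPT_SUBPIXEL <- 128L

read_short <- function(raw, offset) {   # 0-based offset, big-endian signed
  readBin(raw[(offset + 1):(offset + 2)], "integer", size = 2,
          signed = TRUE, endian = "big")
}
read_float <- function(raw, offset, n = 1) {
  readBin(raw[(offset + 1):(offset + 4 * n)], "numeric", size = 4,
          n = n, endian = "big")
}

# Parse one .roi blob; returns a selection or NULL (non-line ROI).
parse_roi <- function(raw, label) {
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop_pk("format_error", "'%s' is not an ImageJ ROI", label)
  type <- as.integer(raw[7])
  top <- read_short(raw, 8); left <- read_short(raw, 10)
  n <- read_short(raw, 16)
  stroke <- read_short(raw, 34)
  options <- read_short(raw, 50)
  lw <- if (stroke >= 1) stroke else 1L

  if (type == ROI_TYPES[["line"]]) {
    xy <- read_float(raw, 18, 4)            # x1 y1 x2 y2
    verts <- rbind(c(xy[1], xy[2]), c(xy[3], xy[4]))
    return(selection(verts, linewidth = lw, label = label))
  }
  if (type %in% c(ROI_TYPES[["polyline"]], ROI_TYPES[["freeline"]])) {
    if (n < 2) return(NULL)
    subpixel <- bitwAnd(options, ROI_OPT_SUBPIXEL) != 0 &&
      length(raw) >= 64 + 4 * n + 8 * n
    if (subpixel) {
      xs <- read_float(raw, 64 + 4 * n, n)
      ys <- read_float(raw, 64 + 4 * n + 4 * n, n)
    } else {
      xs <- vapply(seq_len(n) - 1L, function(i) read_short(raw, 64 + 2 * i), 0L) + left
      ys <- vapply(seq_len(n) - 1L, function(i) read_short(raw, 64 + 2 * n + 2 * i), 0L) + top
    }
    return(selection(cbind(xs, ys), linewidth = lw, label = label))
  }
  NULL
}

#' Import ImageJ ROIs as selections
#'
#' Reads a single ImageJ `.roi` file or a `.zip` archive of ROIs and
#' converts every line-type ROI (straight line, segmented line, freehand
#' line) into a [selection()], keeping the stroke width (default 1 if
#' absent). Non-line ROI types are skipped with a warning.
#'
#' @param path Path to a `.roi` file or `.zip` of ROIs.
#' @return List of [selection()] objects, in file order.
#' @export
import_imagej_rois <- function(path) {
  if (!file.exists(path)) stop_pk("io_error", "cannot read ROI file '%s'", path)
  blobs <- if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    tmp <- tempfile("rois")
    dir.create(tmp)
    files <- utils::unzip(path, exdir = tmp)
    files <- files[grepl("\\.roi$", files, ignore.case = TRUE)]
    stats::setNames(
      lapply(files, function(f) readBin(f, "raw", file.info(f)$size)),
      sub("\\.roi$", "", basename(files), ignore.case = TRUE)
    )
  } else {
    stats::setNames(list(readBin(path, "raw", file.info(path)$size)),
                    sub("\\.roi$", "", basename(path), ignore.case = TRUE))
  }
  sels <- list()
  for (nm in names(blobs)) {
    s <- parse_roi(blobs[[nm]], nm)
    if (is.null(s)) {
      warning(sprintf("skipping non-line ROI '%s'", nm))
    } else {
      sels[[length(sels) + 1]] <- s
    }
  }
  if (length(sels) == 0)
    stop_pk("empty_result", "no line-type ROI found in '%s'", path)
  sels
}

# Minimal ImageJ ROI writer (straight line or subpixel polyline), used for
# round-trip tests and to let users hand selections back to ImageJ.
write_short <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "big")
write_float <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "big")

write_imagej_roi <- function(sel, path) {
  v <- sel$vertices
  n <- nrow(v)
  straight <- n == 2
  type <- if (straight) ROI_TYPES[["line"]] else ROI_TYPES[["polyline"]]
  top <- floor(min(v[, 2])); left <- floor(min(v[, 1]))
  bottom <- ceiling(max(v[, 2])); right <- ceiling(max(v[, 1]))
  header <- c(
    charToRaw("Iout"),
    write_short(228),                       # version
    as.raw(c(type, 0)),
    write_short(top), write_short(left),
    write_short(bottom), write_short(right),
    write_short(if (straight) 2 else n),
    if (straight) c(write_float(v[1, 1]), write_float(v[1, 2]),
                    write_float(v[2, 1]), write_float(v[2, 2]))
    else raw(16),
    write_short(sel$linewidth),
    raw(12),                                # shape size, stroke/fill color
    write_short(0),                         # subtype
    write_short(if (straight) 0 else ROI_OPT_SUBPIXEL),
    raw(4),                                 # arrow style/size, arc size
    writeBin(0L, raw(), size = 4, endian = "big"),  # position
    writeBin(0L, raw(), size = 4, endian = "big")   # header2 offset
  )
  body <- if (straight) raw(0) else c(
    unlist(lapply(round(v[, 1]) - left, write_short)),
    unlist(lapply(round(v[, 2]) - top, write_short)),
    write_float(v[, 1]), write_float(v[, 2])
  )
  writeBin(c(header, body), path)
  invisible(path)
}
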