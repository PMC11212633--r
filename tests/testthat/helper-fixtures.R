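# Shared fixtures and independent oracles, all built in code at test time.

# Straight horizontal selection across the middle row of an image.
mid_selection <- function(image, linewidth = 7, label = "mid") {
  d <- dim(image$pixels)
  ymid <- (d[3] - 1) / 2
  selection(rbind(c(0, ymid), c(d[4] - 1, ymid)), linewidth = linewidth,
            label = label)
}

# Wrap a bare intensity vector as an intensity_profile (positions 0,1,2,...),
# for unit tests that don't need an image.
make_profile <- function(v, label = "synthetic") {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  vn <- if (hi > lo) (v - lo) / (hi - lo) else v
  structure(
    list(positions = seq_along(v) - 1,
         intensities = list("1" = vn),
         normalization = list("1" = c(raw_min = lo, raw_max = hi)),
         channels = 1L,
         source = structure(list(vertices = rbind(c(0, 0), c(length(v) - 1, 0)),
                                 linewidth = 1L, frame = 0L, label = label),
                            class = "selection")),
    class = "intensity_profile"
  )
}

# Noiseless Gaussian band ladder as a plain vector (independent of the
# package's simulator): bands of sd `sigma` at the given centers.
ladder_vector <- function(n = 270, centers = seq(25, 250, by = 25),
                          sigma = 1.8, amplitudes = 1) {
  x <- seq_len(n) - 1
  amplitudes <- rep_len(amplitudes, length(centers))
  v <- numeric(n)
  for (i in seq_along(centers))
    v <- v + amplitudes[i] * exp(-(x - centers[i])^2 / (2 * sigma^2))
  v
}

# Dense direct 2-d Gaussian convolution with reflective padding: the oracle
# for the package's separable blur.
blur_oracle <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k1 <- dnorm(-r:r, 0, sigma); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  nr <- nrow(m); nc <- ncol(m)
  reflect <- function(i, n) {       # half-sample reflection
    i[i < 1] <- 1 - i[i < 1]
    i[i > n] <- 2 * n + 1 - i[i > n]
    pmin(pmax(i, 1), n)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      acc <- acc + k2[di + r + 1, dj + r + 1] *
        m[reflect(i + di, nr), reflect(j + dj, nc)]
    }
    out[i, j] <- acc
  }
  out
}

# Brute-force matcher oracle: maximum number of truth positions matchable
# one-to-one within `tol`, by exhaustive recursion (feasible for <= 6).
match_oracle <- function(truth, extracted, tol) {
  best <- 0L
  recurse <- function(ti, used) {
    if (ti > length(truth)) {
      best <<- max(best, sum(used >= 0))
      return(invisible())
    }
    # skip this truth position
    recurse(ti + 1L, used)
    for (j in seq_along(extracted)) {
      if (j %in% used) next
      if (abs(extracted[j] - truth[ti]) <= tol) {
        recurse(ti + 1L, c(used, j))
      }
    }
  }
  recurse(1L, integer(0))
  best
}

# --- minimal stored (uncompressed) zip writer, for .zip ROI fixtures -------

crc32_table <- local({
  tab <- numeric(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (c %% 2 == 1) {
        v <- floor(c / 2)
        # xor with 0xEDB88320 on 16-bit halves
        lo <- bitwXor(as.integer(v %% 65536), as.integer(0xEDB88320 %% 65536))
        hi <- bitwXor(as.integer(v %/% 65536), as.integer(0xEDB88320 %/% 65536))
        lo + 65536 * hi
      } else floor(c / 2)
    }
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- 4294967295
  for (b in as.integer(bytes)) {
    idx <- bitwXor(as.integer(crc %% 256), b)
    v <- floor(crc / 256)
    t <- crc32_table[idx + 1]
    lo <- bitwXor(as.integer(v %% 65536), as.integer(t %% 65536))
    hi <- bitwXor(as.integer(v %/% 65536), as.integer(t %/% 65536))
    crc <- lo + 65536 * hi
  }
  4294967295 - crc  # equals crc xor 0xFFFFFFFF for crc in [0, 2^32)
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) {
  c(u16(x %% 65536), u16(x %/% 65536))
}

write_stored_zip <- function(files, path) {
  # files: named list of raw vectors
  body <- raw(0); central <- raw(0); offsets <- integer(0)
  for (nm in names(files)) {
    data <- files[[nm]]
    crc <- crc32(data)
    offsets <- c(offsets, length(body))
    local_hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), u16(20), u16(0), u16(0),
                   u16(0), u16(0), u32(crc), u32(length(data)),
                   u32(length(data)), u16(nchar(nm)), u16(0), charToRaw(nm))
    body <- c(body, local_hdr, data)
  }
  for (i in seq_along(files)) {
    nm <- names(files)[i]
    data <- files[[nm]]
    central <- c(central,
                 as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16(20), u16(20), u16(0),
                 u16(0), u16(0), u16(0), u32(crc32(data)), u32(length(data)),
                 u32(length(data)), u16(nchar(nm)), u16(0), u16(0), u16(0),
                 u16(0), u32(0), u32(offsets[i]), charToRaw(nm))
  }
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16(0), u16(0),
            u16(length(files)), u16(length(files)), u32(length(central)),
            u32(length(body)), u16(0))
  writeBin(c(body, central, eocd), path)
  invisible(path)
}

roi_raw <- function(sel) {
  tf <- tempfile(fileext = ".roi")
  patternkit:::write_imagej_roi(sel, tf)
  on.exit(unlink(tf))
  readBin(tf, "raw", file.info(tf)$size)
}
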