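# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic entry points funnel through this
# so that a config seed fully determines the output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of per-item seeds (< 2^31) from one master seed.
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

stop_pk <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "patternkit_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Linear interpolation of the crossing of `level` between samples i and i+1.
# x: positions, y: values; returns position of crossing inside [x[i], x[i+1]].
interp_crossing <- function(x, y, i, level) {
  x[i] + (level - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
}

# Indices of strict interior local maxima of y (plateaus take the first index).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# Resample a polyline (n x 2 matrix of x,y) to `n_out` points equally spaced
# in arc length.
resample_polyline <- function(vertices, n_out) {
  d <- sqrt(rowSums(diff(vertices)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  if (total <= 0) stop_pk("degenerate_selection", "selection has zero path length")
  t_out <- seq(0, total, length.out = n_out)
  cbind(
    x = stats::approx(s, vertices[, 1], xout = t_out)$y,
    y = stats::approx(s, vertices[, 2], xout = t_out)$y
  )
}

polyline_length <- function(vertices) {
  sum(sqrt(rowSums(diff(vertices)^2)))
}
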