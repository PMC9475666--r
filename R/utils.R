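# Internal helpers: local RNG scoping, smoothing, run detection.

#' Evaluate an expression with a locally-set RNG seed
#'
#' Saves and restores `.Random.seed` so package functions that take a `seed`
#' argument never disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Centered moving average with edge shrinkage
#'
#' Window width is given in samples (odd; forced odd by adding 1 if even).
#' Near the edges the window shrinks symmetrically, so the output has the
#' same length as the input and no NA padding.
#' @noRd
moving_average <- function(x, width) {
  n <- length(x)
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || n < 3L) return(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  # symmetric shrink: window half-width limited by the nearer edge
  h <- pmin(i - lo, hi - i)
  lo <- i - h
  hi <- i + h
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Centered slope estimate of a series over a fixed time span
#'
#' Returns (x[i+k] - x[i-k]) / (2*k*dt) with edge values extended from the
#' nearest interior estimate. `span` is the full baseline in seconds.
#' @noRd
centered_slope <- function(x, dt, span) {
  n <- length(x)
  k <- max(1L, round(span / (2 * dt)))
  if (n < 2L * k + 1L) k <- max(1L, (n - 1L) %/% 2L)
  i <- seq_len(n)
  lo <- pmax(i - k, 1L)
  hi <- pmin(i + k, n)
  (x[hi] - x[lo]) / ((hi - lo) * dt)
}

#' Runs of TRUE in a logical vector
#'
#' Returns a data.frame with start/end indices of each maximal run of TRUE.
#' @noRd
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Two-segment piecewise-linear breakpoint fit
#'
#' Fits y ~ continuous piecewise-linear function of t with a single
#' breakpoint, scanning candidate breakpoints over the interior grid points
#' and minimising SSE. Returns the breakpoint time, the two slopes, the
#' fitted value at the breakpoint, and the SSE improvement over a single
#' straight line. Used to localise kinematic corner events (the intersection
#' of the two fitted lines is unbiased for a corner in piecewise-linear data
#' even after moving-average smoothing).
#' @noRd
breakpoint_fit <- function(t, y, min_side = 3L) {
  n <- length(t)
  if (n < 2L * min_side + 1L) return(NULL)
  base <- stats::lm.fit(cbind(1, t), y)
  sse0 <- sum(base$residuals^2)
  best <- NULL
  idx <- seq.int(min_side + 1L, n - min_side)
  for (j in idx) {
    tb <- t[j]
    # basis: intercept, t, hinge (t - tb)_+
    X <- cbind(1, t, pmax(t - tb, 0))
    f <- stats::lm.fit(X, y)
    sse <- sum(f$residuals^2)
    if (is.null(best) || sse < best$sse) {
      cf <- f$coefficients
      best <- list(t_break = tb, sse = sse,
                   slope1 = cf[2], slope2 = cf[2] + cf[3],
                   y_break = cf[1] + cf[2] * tb)
    }
  }
  best$sse_line <- sse0
  best$improvement <- 1 - best$sse / max(sse0, .Machine$double.eps)
  best
}

#' Degrees to radians
#' @noRd
deg2rad <- function(deg) deg * pi / 180

stop_domain <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
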