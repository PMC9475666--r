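# Kinematics: segment 10 Hz tag traces into lunges, extract the six event
# times/speeds, phase durations, tailbeat periods, and the final long-period
# gyroscope oscillation; sample "middle" lunges.
#
# Detection strategy (a reproducible proxy for the analyst-assisted event
# picks the field method relies on):
#   1. coarse: maximal runs where the 0.5 s-smoothed speed slope falls below
#      -a_thresh mark candidate engulfment decelerations;
#   2. the run's steepest point anchors half-steepness crossings that give
#      coarse mouth-opening/closure times, robust to a gently-decelerating
#      adjustment phase bleeding into the run;
#   3. each corner event (T_accel, T_max, T_MO, T_MC, T_min) is refined by
#      an iterated two-line intersection fit, which is unbiased for a corner
#      in piecewise-linear kinematics even after smoothing;
#   4. fluking onset (T_fluke) comes from the gyroscope amplitude envelope
#      with linear back-extrapolation of the first tailbeat's rise;
#   5. the final long-period oscillation is the last zero-crossing-bounded
#      gyro cycle of significant amplitude intersecting [T_MO, T_MC].

#' Detection threshold set
#'
#' All tunables of the lunge detector. `a_thresh` is the smoothed-slope
#' threshold (m s^-2) marking a steep engulfment deceleration; `g_thresh`
#' the gyro envelope amplitude (rad s^-1) separating fluking from gliding;
#' `smooth_s` the moving-average width (s) used for speed smoothing;
#' `min_run`/`min_drop` the minimum duration (s) and speed drop (m s^-1) a
#' candidate deceleration must show; `min_rise`/`rise_lookback` require an
#' accelerative approach (speed rise, m s^-1, within the lookback, s) so a
#' candidate matches the standard accelerate-then-decelerate lunge profile.
#'
#' @param a_thresh deceleration threshold (m s^-2), default 0.35.
#' @param g_thresh gyro fluking-envelope threshold (rad s^-1), default 0.1.
#' @param smooth_s smoothing window (s), default 0.5.
#' @param slope_span slope-estimate baseline (s), default 0.5.
#' @param min_run minimum deceleration-run duration (s).
#' @param min_drop minimum speed drop over the deceleration (m s^-1).
#' @param merge_gap merge candidate runs separated by less than this (s).
#' @param min_rise minimum speed rise before mouth opening (m s^-1).
#' @param rise_lookback lookback for the rise test (s).
#' @param t_min_window search window for the speed minimum after mouth
#'   closure (s), default 5 (fixed by the field protocol).
#' @param glide_quiet minimum quiet-gyro span that qualifies as the
#'   pre-lunge glide (s).
#' @param min_osc_amp minimum half-cycle gyro amplitude for the final
#'   oscillation (rad s^-1).
#' @return A list of class `detection_thresholds`.
#' @export
detection_thresholds <- function(a_thresh = 0.35, g_thresh = 0.1,
                                 smooth_s = 0.5, slope_span = 0.5,
                                 min_run = 0.3, min_drop = 0.6,
                                 merge_gap = 2.0, min_rise = 0.6,
                                 rise_lookback = 15, t_min_window = 5,
                                 glide_quiet = 1.5, min_osc_amp = 0.1) {
  structure(as.list(environment()), class = "detection_thresholds")
}

# joint two-breakpoint continuous piecewise-linear fit: scans (b1, b2) on
# the sample grid minimising SSE of y ~ 1 + t + (t-b1)_+ + (t-b2)_+.
# Used for the mouth-closure / speed-minimum pair, whose two corners sit
# close together and are estimated far better jointly than one at a time.
two_break_fit <- function(t, y, b1_lo, b1_hi, b2_lo, b2_hi,
                          min_gap = 0.4, step = 1L) {
  n <- length(t)
  if (n < 10L) return(NULL)
  i1 <- which(t >= b1_lo & t <= b1_hi)
  if (length(i1) < 2L) return(NULL)
  i1 <- i1[seq(1L, length(i1), by = step)]
  best <- NULL
  for (a in i1) {
    b1 <- t[a]
    i2 <- which(t >= max(b2_lo, b1 + min_gap) & t <= b2_hi)
    if (length(i2) < 2L) next
    i2 <- i2[seq(1L, length(i2), by = step)]
    for (b in i2) {
      b2 <- t[b]
      if (b2 >= t[n] - 0.2) next
      X <- cbind(1, t, pmax(t - b1, 0), pmax(t - b2, 0))
      f <- stats::lm.fit(X, y)
      cf <- f$coefficients
      if (anyNA(cf)) next
      sse <- sum(f$residuals^2)
      if (is.null(best) || sse < best$sse) {
        best <- list(b1 = b1, b2 = b2, sse = sse,
                     slope1 = cf[2], slope2 = cf[2] + cf[3],
                     slope3 = cf[2] + cf[3] + cf[4])
      }
    }
  }
  best
}

# iterated two-line intersection fit around a kinematic corner; an optional
# known-period sine/cosine pair in each arm's regression absorbs tailbeat
# speed ripple so it cannot tilt the lines (the intersection uses the
# linear part only)
corner_locate <- function(t, y, guess, arm_left, arm_right, exclude,
                          iters = 3L, min_pts = 3L, ripple_period = NA) {
  est <- guess
  res <- NULL
  # ripple columns only make sense on an arm spanning > 1 period; on a
  # shorter arm they are near-collinear with the line and wreck the fit.
  # They are applied to the right (ramp-side) arm only - the glide side
  # carries no tailbeat ripple.
  use_rip <- is.finite(ripple_period) && arm_right > 1.05 * ripple_period
  rip <- function(tt) {
    if (!use_rip) return(NULL)
    cbind(sin(2 * pi * tt / ripple_period),
          cos(2 * pi * tt / ripple_period))
  }
  for (it in seq_len(iters)) {
    li <- which(t >= est - exclude - arm_left & t <= est - exclude)
    ri <- which(t >= est + exclude & t <= est + exclude + arm_right)
    if (length(li) < min_pts || length(ri) < min_pts) return(res)
    fl <- stats::lm.fit(cbind(1, t[li]), y[li])$coefficients
    fr <- stats::lm.fit(cbind(1, t[ri], rip(t[ri])), y[ri])$coefficients
    denom <- fl[2] - fr[2]
    if (!is.finite(denom) || abs(denom) < 1e-8) return(res)
    tb <- (fr[1] - fl[1]) / denom
    tb <- min(max(tb, est - exclude - arm_left), est + exclude + arm_right)
    res <- list(t = unname(tb), slope1 = unname(fl[2]),
                slope2 = unname(fr[2]),
                y = unname(fl[1] + fl[2] * tb))
    if (abs(tb - est) < 0.02) break
    est <- tb
  }
  res
}

# interpolated channel value at arbitrary times
at_time <- function(t, y, times) stats::approx(t, y, xout = times, rule = 2)$y

# refine an approximate zero-crossing time by a local line fit through the
# signal; `side` restricts the fit window to samples inside the oscillation
# (noise makes the raw sign-change crossings wander into the quiet spans
# bordering the cycle)
refine_crossing <- function(t, g, tc, period, side = c("center", "after",
                                                       "before")) {
  side <- match.arg(side)
  w <- switch(side,
              after = c(0, 0.2 * period),
              before = c(-0.2 * period, 0),
              center = c(-0.15 * period, 0.15 * period))
  for (k in 1:2) {
    i <- which(t >= tc + w[1] & t <= tc + w[2])
    if (length(i) < 3L) return(tc)
    cf <- stats::lm.fit(cbind(1, t[i]), g[i])$coefficients
    if (!is.finite(cf[2]) || abs(cf[2]) < 1e-4) return(tc)
    tc_new <- -cf[1] / cf[2]
    if (!is.finite(tc_new) || abs(tc_new - tc) > 0.5 * period) return(tc)
    tc <- tc_new
  }
  tc
}

# single-cycle sine fit for the final oscillation: g ~ A sin(2 pi (t-T1)/P)
# on [T1, T1+P] and 0 outside, minimised over (T1, P, A) from the raw
# zero-crossing initialisation
finos_sine_fit <- function(t, g, t1, t3) {
  P0 <- t3 - t1
  w <- which(t >= t1 - 0.4 * P0 & t <= t3 + 0.4 * P0)
  if (length(w) < 10L) return(NULL)
  tt <- t[w]; yy <- g[w]
  obj <- function(par) {
    T1 <- par[1]; P <- par[2]; A <- par[3]
    if (P < 0.4 * P0 || P > 1.8 * P0) return(1e9)
    m <- ifelse(tt >= T1 & tt <= T1 + P,
                A * sin(2 * pi * (tt - T1) / P), 0)
    sum((yy - m)^2)
  }
  A0 <- max(abs(yy))
  fit <- try(stats::optim(c(t1, P0, A0), obj,
                          control = list(maxit = 400)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  T1 <- fit$par[1]; P <- fit$par[2]
  if (P < 0.45 * P0 || P > 1.7 * P0 || abs(T1 - t1) > 0.6 * P0) return(NULL)
  list(T1 = T1, P = P, A = fit$par[3])
}

# zero crossings of a series, linearly interpolated, with the peak absolute
# value of the half-cycle between consecutive crossings
gyro_half_cycles <- function(t, g) {
  s <- sign(g)
  s[s == 0] <- 1
  flips <- which(diff(s) != 0)
  if (length(flips) < 2L) return(NULL)
  # crossing times by linear interpolation
  tc <- t[flips] - g[flips] * (t[flips + 1L] - t[flips]) /
    (g[flips + 1L] - g[flips])
  n <- length(tc)
  peak <- numeric(n - 1L)
  sgn <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    idx <- (flips[i] + 1L):flips[i + 1L]
    k <- idx[which.max(abs(g[idx]))]
    peak[i] <- abs(g[k])
    sgn[i] <- sign(g[k])
  }
  data.frame(t_start = tc[-n], t_end = tc[-1L], peak = peak, sgn = sgn)
}

# median full-cycle period of significant gyro oscillations in a window
estimate_period <- function(t, g, lo, hi, min_amp = 0.08) {
  w <- which(t >= lo & t <= hi)
  if (length(w) < 8L) return(NA_real_)
  hc <- gyro_half_cycles(t[w], g[w])
  if (is.null(hc)) return(NA_real_)
  sig <- hc[hc$peak >= min_amp, , drop = FALSE]
  if (nrow(sig) < 2L) return(NA_real_)
  per <- numeric(0)
  for (i in seq_len(nrow(sig) - 1L)) {
    if (sig$sgn[i] != sig$sgn[i + 1L]) {
      per <- c(per, sig$t_end[i + 1L] - sig$t_start[i])
    }
  }
  if (!length(per)) return(NA_real_)
  stats::median(per)
}

# hinge scan for the ramp/adjustment corner with a second hinge fixed at
# the (already estimated) mouth-opening time; returns the best corner and
# an F-like statistic for its significance against the no-adjustment model
tmax_scan <- function(t, y, b_lo, b_hi, t_mo, win_lo, win_hi,
                      ripple_period = NA) {
  w <- which(t >= win_lo & t <= win_hi)
  if (length(w) < 12L) return(NULL)
  tt <- t[w]; yy <- y[w]
  cand <- which(tt >= b_lo & tt <= b_hi)
  if (length(cand) < 2L) return(NULL)
  h2 <- pmax(tt - t_mo, 0)
  # known-period sine/cosine columns absorb the tailbeat speed ripple so a
  # ripple fragment cannot masquerade as an adjustment corner
  R <- if (is.finite(ripple_period)) {
    cbind(sin(2 * pi * tt / ripple_period),
          cos(2 * pi * tt / ripple_period))
  } else NULL
  X0 <- cbind(1, tt, h2, R)
  sse0 <- sum(stats::lm.fit(X0, yy)$residuals^2)
  best <- NULL
  for (a in cand) {
    b1 <- tt[a]
    f <- stats::lm.fit(cbind(1, tt, pmax(tt - b1, 0), h2, R), yy)
    sse <- sum(f$residuals^2)
    if (is.null(best) || sse < best$sse) {
      cf <- f$coefficients
      best <- list(b1 = b1, sse = sse, slope_ramp = unname(cf[2]),
                   slope_adj = unname(cf[2] + cf[3]))
    }
  }
  best$f_stat <- (sse0 - best$sse) /
    (best$sse / max(length(w) - ncol(X0) - 1L, 1L))
  best
}

empty_lunge_table <- function() {
  cols <- c("lunge_id", "dive_id", "position_in_dive",
            "T_fluke", "T_accel", "T_max", "T_MO", "T_MC", "T_min",
            "U_fluke", "U_accel", "U_max", "U_MO", "U_MC", "U_min",
            "dT_accel", "dT_adjust", "dT_decel",
            "T_gyr1", "T_gyr2", "T_gyr3", "dT_finOs",
            "depth_at_MO", "distance_decel")
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  df$position_in_dive <- character(0)
  class(df) <- c("lunge_table", "data.frame")
  df
}

#' Segment one candidate lunge window into phases
#'
#' Populates the six event times and speeds, the three phase durations, and
#' the deceleration-phase travel distance for one candidate deceleration
#' window found by [detect_lunges()] (which is the usual caller). Returns
#' `NULL` when the window fails the event-ordering or inclusion rules.
#'
#' @param trace a [tag_trace()].
#' @param window numeric length-2: coarse start/end times (s) of the steep
#'   deceleration run.
#' @param thresholds a [detection_thresholds()].
#' @return One-row data.frame (no gyro fields; see [final_oscillation()]),
#'   or `NULL`.
#' @export
segment_phases <- function(trace, window, thresholds = detection_thresholds()) {
  th <- thresholds
  dt <- trace_dt(trace)
  t <- trace$t
  v_s <- moving_average(trace$speed, th$smooth_s / dt)
  acc <- centered_slope(v_s, dt, th$slope_span)
  seg_t0 <- t[1]; seg_t1 <- t[length(t)]

  ir <- which(t >= window[1] & t <= window[2])
  if (length(ir) < 2L) return(NULL)
  i_steep <- ir[which.min(acc[ir])]
  s_d <- acc[i_steep]
  if (!is.finite(s_d) || s_d >= -th$a_thresh) return(NULL)

  # coarse T_MO / T_MC: fractional-steepness crossings walking out from the
  # steepest deceleration (robust when a gentle adjustment-phase or
  # post-closure decline extends the run). A long (1.2 s) slope baseline
  # resists noise on weak-contrast decelerations but smears short sharp
  # ones, so the mouth-closure side falls back to the short baseline when
  # the deceleration is steep (the sharp case never has a weak-contrast
  # post-closure decline, so the short baseline is safe there).
  n <- length(t)
  walk_out <- function(slope_series, frac) {
    half <- frac * min(slope_series[ir])
    i <- i_steep
    while (i > 1L && slope_series[i] <= half &&
           t[i_steep] - t[i] < 15) i <- i - 1L
    lo <- t[i]
    i <- i_steep
    while (i < n && slope_series[i] <= half &&
           t[i] - t[i_steep] < 15) i <- i + 1L
    c(lo, t[i])
  }
  w_long <- walk_out(centered_slope(v_s, dt, 1.2), 0.6)
  g_mo <- w_long[1]
  g_mc <- if (s_d < -1.1) walk_out(acc, 0.5)[2] else w_long[2]
  if (g_mc - g_mo < th$min_run) return(NULL)

  # refine T_MO by a corner fit
  dTd0 <- g_mc - g_mo
  f_mo <- corner_locate(t, v_s, g_mo, arm_left = 0.9,
                        arm_right = min(1.2, 0.45 * dTd0), exclude = 0.3)
  T_MO <- if (!is.null(f_mo)) f_mo$t else g_mo

  # T_min first: the post-closure decline meeting the recovery stroke forms
  # a strong V whose location then caps the right arm of the T_MC fit
  wmin <- which(t > g_mc + 0.1 & t <= min(g_mc + th$t_min_window, seg_t1))
  if (!length(wmin)) return(NULL)
  g_min <- t[wmin[which.min(v_s[wmin])]]
  f_min <- corner_locate(t, v_s, g_min,
                         arm_left = max(0.5, min(1.6, g_min - g_mc - 0.3)),
                         arm_right = 1.1, exclude = 0.25)
  T_min <- if (!is.null(f_min) && f_min$slope2 > f_min$slope1) {
    f_min$t
  } else g_min

  # T_MC: corner between the steep deceleration and the post-closure
  # decline, with the left arm inside the deceleration and the right arm
  # kept clear of the T_min corner
  f_mc <- corner_locate(t, v_s, g_mc,
                        arm_left = max(0.3, min(3.0, g_mc - T_MO - 0.3)),
                        arm_right = max(0.3, min(1.8, T_min - 0.3 - g_mc)),
                        exclude = 0.3)
  T_MC <- if (!is.null(f_mc)) f_mc$t else g_mc

  # joint 3-segment refinement of (T_MC, T_min): deceleration, post-closure
  # decline, and recovery rise are all near-linear, and the continuity
  # constraints at both corners sharpen each one. The window must stop
  # before the recovery levels off (~1.5 s after the minimum).
  dTd_est <- T_MC - T_MO
  wj <- which(t >= T_MO + max(0.2, 0.15 * dTd_est) & t <= T_min + 1.2)
  if (dTd_est >= 0.45 && length(wj) >= 12L) {
    fj <- two_break_fit(t[wj], trace$speed[wj],
                        b1_lo = T_MC - min(1.0, 0.3 + 0.5 * dTd_est),
                        b1_hi = T_MC + min(1.0, 0.3 + 0.5 * dTd_est),
                        b2_lo = T_min - 0.8, b2_hi = T_min + 0.8)
    if (!is.null(fj) && fj$slope1 < fj$slope2 && fj$slope2 < fj$slope3) {
      T_MC <- fj$b1
      T_min <- fj$b2
    }
  }
  T_min <- min(max(T_min, T_MC + 0.1), T_MC + th$t_min_window)
  if (T_MC <= T_MO + th$min_run) return(NULL)
  U_MO <- at_time(t, v_s, T_MO)
  U_MC <- at_time(t, v_s, T_MC)
  U_min <- at_time(t, v_s, T_min)
  if (U_MO - U_MC < th$min_drop) return(NULL)  # inclusion rule U_MO > U_MC

  # standard profile: accelerative approach before mouth opening
  pre <- which(t >= T_MO - th$rise_lookback & t <= T_MO)
  if (!length(pre) || U_MO - min(v_s[pre]) < th$min_rise) return(NULL)

  # rough ramp extent first: earliest speed maximum before mouth opening
  # (tie-break to the earliest sample) and a speed-level estimate of the
  # ramp onset; both anchor the refined T_max and T_accel fits below
  wmax <- which(t >= max(T_MO - 8, seg_t0) & t <= T_MO - 0.05)
  if (!length(wmax)) return(NULL)
  vm <- v_s[wmax]
  g_max <- t[wmax[which(vm >= max(vm) - 1e-9)[1]]]   # earliest attaining max
  U_max_rough <- max(vm)
  wpre <- which(t >= g_max - 25 & t <= g_max - 0.5)
  if (length(wpre) < 5L) return(NULL)
  vmin_pre <- min(v_s[wpre])
  v_target <- vmin_pre + 0.12 * (U_max_rough - vmin_pre)
  below <- wpre[v_s[wpre] <= v_target]
  if (!length(below)) return(NULL)
  g_acc <- t[below[length(below)]]   # last crossing: lower part of ramp

  # tailbeat period from the gyro over the ramp, for ripple-aware smoothing
  g_s <- moving_average(trace$gyro_y, 0.3 / dt)
  P_tb <- estimate_period(t, g_s, g_acc, g_max)
  if (!is.finite(P_tb)) P_tb <- 2
  P_tb <- min(max(P_tb, 1.2), 4.2)

  # T_max: corner between the fluking ramp and the (optional) adjustment
  # phase. A hinge scan with a second hinge fixed at the known T_MO lets
  # the deceleration-side data pin the adjustment line through continuity,
  # which roughly halves the corner uncertainty for gentle adjustments;
  # when no significant corner exists T_max snaps to T_MO.
  arm_l <- min(6, max(1.5 * P_tb, 0.6 * (g_max - g_acc)))
  win_lo <- g_max - arm_l
  win_hi <- T_MO + min(2, 0.6 * (T_MC - T_MO))
  f_max <- tmax_scan(t, v_s, b_lo = max(win_lo + 1, T_MO - 3.6),
                     b_hi = T_MO - 0.35, t_mo = T_MO,
                     win_lo = win_lo, win_hi = win_hi)
  # an adjustment phase must itself decelerate (slope < 0): that gate keeps
  # ripple fragments on the rising ramp from faking a corner, so the scan
  # can be broad without the false-positive risk
  if (!is.null(f_max) && f_max$b1 < T_MO - 0.35 &&
      f_max$slope_ramp > 0.04 && f_max$slope_adj < -0.005 &&
      f_max$slope_ramp - f_max$slope_adj > 0.06 && f_max$f_stat > 6) {
    T_max <- f_max$b1
  } else {
    T_max <- T_MO
  }
  U_max <- if (T_max < T_MO) at_time(t, v_s, T_max) else U_MO

  # second pass on T_MO: with T_max known, the adjustment segment length is
  # known too, so the left arm can span most of it
  if (T_max < T_MO - 1.0) {
    f_mo2 <- corner_locate(t, v_s, T_MO,
                           arm_left = max(0.6, min(2.2, T_MO - T_max - 0.3)),
                           arm_right = min(1.6, 0.45 * (T_MC - T_MO)),
                           exclude = 0.3)
    if (!is.null(f_mo2) && abs(f_mo2$t - T_MO) < 0.6 &&
        f_mo2$t > T_max + 0.3 && f_mo2$t < T_MC - th$min_run) {
      T_MO <- f_mo2$t
      U_MO <- at_time(t, v_s, T_MO)
    }
  }

  # T_accel: ramp onset, refined with ripple-absorbing arm fits. The level
  # crossing can start the search a couple of seconds up a long shallow
  # ramp, from where the iteration may diverge rightwards, so several
  # starts are tried and the fit with the flattest glide-side arm (the
  # glide is near-level by definition) wins.
  f_acc <- NULL
  for (st in c(g_acc, g_acc - 1.5, g_acc - 3, g_acc - 4.5)) {
    f_try <- corner_locate(t, v_s, st,
                           arm_left = min(2.5, max(1.0, st - seg_t0)),
                           arm_right = min(6, max(0.8, T_max - st - 0.5)),
                           exclude = 0.35, iters = 6L, ripple_period = P_tb)
    if (!is.null(f_try) && f_try$slope2 - f_try$slope1 > 0.04 &&
        f_try$slope1 < 0.08 && f_try$t >= g_acc - 6 &&
        (is.null(f_acc) ||
           f_try$slope2 - f_try$slope1 > f_acc$slope2 - f_acc$slope1)) {
      f_acc <- f_try
    }
  }
  T_accel <- if (!is.null(f_acc) && f_acc$slope2 - f_acc$slope1 > 0.04 &&
                 f_acc$t < T_max - 1 &&
                 at_time(t, v_s, f_acc$t) < U_MO - th$min_rise / 2) {
    f_acc$t
  } else g_acc
  T_accel <- min(T_accel, T_max - 0.5)
  U_accel <- at_time(t, v_s, T_accel)

  # T_fluke: gyro envelope onset after a quiet glide
  env <- moving_average(abs(g_s), 2 / dt)
  wq <- which(t >= max(T_accel - 40, seg_t0) & t <= T_max - 1)
  T_fluke <- NA_real_
  if (length(wq) > 4L) {
    quiet <- true_runs(env[wq] < th$g_thresh)
    if (nrow(quiet)) {
      dur <- (quiet$end - quiet$start) * dt
      # the pre-lunge glide must end near the acceleration onset (a quiet
      # span can also appear where the last tailbeats die away before
      # maximum speed; that one must not be mistaken for the glide)
      q_end <- t[wq[quiet$end]]
      ok <- which(dur >= th$glide_quiet & q_end <= T_accel + 1)
      if (length(ok)) {
        q <- ok[length(ok)]
        onset0 <- t[wq[quiet$end[q]]]
        wsearch <- which(t >= onset0 - 0.5 & t <= onset0 + 3)
        j <- wsearch[abs(g_s[wsearch]) >= 0.06]
        if (length(j)) {
          # phase back-extrapolation: the first stroke is sinusoidal, so
          # the crossing level and the stroke amplitude give the elapsed
          # phase since the true onset
          j0 <- j[1]
          wamp <- which(t >= t[j0] & t <= t[j0] + 0.6 * P_tb)
          A1 <- max(abs(g_s[wamp]))
          phi <- asin(min(abs(g_s[j0]) / max(A1, 1e-6), 1))
          T_fluke <- t[j0] - phi * P_tb / (2 * pi)
          T_fluke <- min(max(T_fluke, onset0 - 1), t[j0])
        }
      }
    }
  }
  if (!is.finite(T_fluke)) T_fluke <- T_accel
  T_fluke <- min(T_fluke, T_accel)
  U_fluke <- at_time(t, v_s, T_fluke)

  # ordering and inclusion invariants
  if (!(T_fluke <= T_accel && T_accel < T_max && T_max <= T_MO &&
        T_MO < T_MC && T_MC <= T_min && U_MO > U_MC)) {
    return(NULL)
  }

  # deceleration travel distance: trapezoid of the raw speed over
  # [T_MO, T_MC] with interpolated endpoints
  wd <- which(t > T_MO & t < T_MC)
  td <- c(T_MO, t[wd], T_MC)
  ud <- c(at_time(t, trace$speed, T_MO), trace$speed[wd],
          at_time(t, trace$speed, T_MC))
  dist <- sum(diff(td) * (utils::head(ud, -1) + utils::tail(ud, -1)) / 2)

  d_s <- moving_average(trace$depth, th$smooth_s / dt)
  data.frame(
    T_fluke = T_fluke, T_accel = T_accel, T_max = T_max,
    T_MO = T_MO, T_MC = T_MC, T_min = T_min,
    U_fluke = U_fluke, U_accel = U_accel, U_max = U_max,
    U_MO = U_MO, U_MC = U_MC, U_min = U_min,
    dT_accel = T_max - T_accel, dT_adjust = T_MO - T_max,
    dT_decel = T_MC - T_MO,
    depth_at_MO = at_time(t, d_s, T_MO),
    distance_decel = dist
  )
}

#' Final long-period gyroscope oscillation of a lunge
#'
#' Finds the last zero-crossing-bounded gyro cycle (two consecutive
#' half-cycles of opposite sign, each with peak amplitude above
#' `min_osc_amp`) whose span intersects the deceleration window
#' `[T_MO, T_MC]`. Returns `NA` fields (lunge flagged) when no such
#' oscillation exists.
#'
#' @param trace a [tag_trace()].
#' @param lunge one-row data.frame/list with `T_MO` and `T_MC`.
#' @param thresholds a [detection_thresholds()].
#' @return List with `T_gyr1`, `T_gyr2`, `T_gyr3`, `dT_finOs`.
#' @export
final_oscillation <- function(trace, lunge,
                              thresholds = detection_thresholds()) {
  lunge <- as.list(lunge)
  dt <- trace_dt(trace)
  w <- which(trace$t >= lunge$T_MO - 15 & trace$t <= lunge$T_MC + 15)
  miss <- list(T_gyr1 = NA_real_, T_gyr2 = NA_real_, T_gyr3 = NA_real_,
               dT_finOs = NA_real_)
  if (length(w) < 8L) return(miss)
  g_s <- moving_average(trace$gyro_y[w], 0.3 / dt)
  hc <- gyro_half_cycles(trace$t[w], g_s)
  if (is.null(hc)) return(miss)
  amp <- thresholds$min_osc_amp
  best <- NULL
  for (i in seq_len(nrow(hc) - 1L)) {
    if (hc$peak[i] >= amp && hc$peak[i + 1L] >= amp &&
        hc$sgn[i] != hc$sgn[i + 1L] &&
        abs(hc$t_end[i] - hc$t_start[i + 1L]) < 1e-9) {
      t1 <- hc$t_start[i]; t3 <- hc$t_end[i + 1L]
      if (t1 <= lunge$T_MC && t3 >= lunge$T_MO) {
        P0 <- t3 - t1
        tt <- trace$t[w]
        best <- list(T_gyr1 = t1, T_gyr2 = hc$t_end[i], T_gyr3 = t3,
                     dT_finOs = P0)
        sf <- finos_sine_fit(tt, g_s, t1, t3)
        if (!is.null(sf)) {
          best <- list(T_gyr1 = sf$T1, T_gyr2 = sf$T1 + sf$P / 2,
                       T_gyr3 = sf$T1 + sf$P, dT_finOs = sf$P)
        } else {
          t1r <- refine_crossing(tt, g_s, t1, P0, "after")
          t2r <- refine_crossing(tt, g_s, hc$t_end[i], P0, "center")
          t3r <- refine_crossing(tt, g_s, t3, P0, "before")
          if (t1r < t2r && t2r < t3r) {
            best <- list(T_gyr1 = t1r, T_gyr2 = t2r, T_gyr3 = t3r,
                         dT_finOs = t3r - t1r)
          }
        }
      }
    }
  }
  best %||% miss
}

#' Per-beat tailbeat periods between fluking onset and the final oscillation
#'
#' Measures the period of each full gyro cycle between `T_fluke` and
#' `T_gyr1`, appending the final-oscillation period as the last entry.
#'
#' @param trace a [tag_trace()].
#' @param lunge one-row lunge record with `T_fluke`, `T_gyr1`, `dT_finOs`
#'   (gyro fields may be `NA`).
#' @param thresholds a [detection_thresholds()].
#' @return List with `periods` (s; final oscillation last) and
#'   `final_period` (s, `NA` if absent).
#' @export
tailbeat_periods <- function(trace, lunge,
                             thresholds = detection_thresholds()) {
  lunge <- as.list(lunge)
  dt <- trace_dt(trace)
  t_end <- if (is.finite(lunge$T_gyr1 %||% NA_real_)) lunge$T_gyr1 else lunge$T_MO
  w <- which(trace$t >= lunge$T_fluke - 0.5 & trace$t <= t_end + 0.5)
  periods <- numeric(0)
  if (length(w) > 8L) {
    g_s <- moving_average(trace$gyro_y[w], 0.3 / dt)
    hc <- gyro_half_cycles(trace$t[w], g_s)
    if (!is.null(hc)) {
      sig <- hc[hc$peak >= thresholds$min_osc_amp / 2, , drop = FALSE]
      if (nrow(sig) >= 2L) {
        # full cycle = two consecutive opposite-sign half-cycles
        i <- 1L
        while (i < nrow(sig)) {
          if (sig$sgn[i] != sig$sgn[i + 1L]) {
            periods <- c(periods, sig$t_end[i + 1L] - sig$t_start[i])
            i <- i + 2L
          } else i <- i + 1L
        }
      }
    }
  }
  fp <- lunge$dT_finOs %||% NA_real_
  if (is.finite(fp)) periods <- c(periods, fp)
  list(periods = periods, final_period = fp)
}

#' Detect lunges in a tag trace
#'
#' Scans the trace for steep-deceleration candidates, refines each into a
#' fully populated lunge event via [segment_phases()] and
#' [final_oscillation()], rejects candidates that do not match the standard
#' accelerate-then-decelerate profile, and classifies each lunge's position
#' within its dive (`first`/`middle`/`last`/`solitary`).
#'
#' Masked (gap) spans longer than 1 s split the trace; shorter gaps are
#' bridged by linear interpolation and never contribute event times.
#'
#' @param trace a [tag_trace()].
#' @param thresholds a [detection_thresholds()].
#' @return A `lunge_table` data.frame, one row per accepted lunge, ordered
#'   by `T_MO`, with a `lunge_id` column.
#' @export
detect_lunges <- function(trace, thresholds = detection_thresholds()) {
  th <- thresholds
  dt <- trace_dt(trace)
  n <- nrow(trace)
  out <- empty_lunge_table()
  if (n < round(5 / dt)) return(out)

  # split at masked runs >= 1 s; interpolate shorter gaps
  gapruns <- true_runs(trace$masked)
  long_gap <- gapruns[(gapruns$end - gapruns$start + 1L) * dt >= 1, ,
                      drop = FALSE]
  bounds <- c(0L, as.vector(t(as.matrix(long_gap))), n + 1L)
  seg_start <- bounds[seq(1, length(bounds), by = 2)] + 1L
  seg_end <- bounds[seq(2, length(bounds), by = 2)] - 1L

  rows <- list()
  for (s in seq_along(seg_start)) {
    i0 <- seg_start[s]; i1 <- seg_end[s]
    if (i1 - i0 + 1L < round(5 / dt)) next
    seg <- trace[i0:i1, , drop = FALSE]
    for (ch in c("depth", "pitch", "speed", "gyro_y")) {
      if (anyNA(seg[[ch]])) {
        seg[[ch]] <- stats::approx(seg$t[!is.na(seg[[ch]])],
                                   seg[[ch]][!is.na(seg[[ch]])],
                                   xout = seg$t, rule = 2)$y
      }
    }
    seg <- tag_trace(seg$t, seg$depth, seg$pitch, seg$speed, seg$gyro_y,
                     attr(trace, "sample_rate"))

    v_s <- moving_average(seg$speed, th$smooth_s / dt)
    acc <- centered_slope(v_s, dt, th$slope_span)
    runs <- true_runs(acc < -th$a_thresh)
    if (!nrow(runs)) next
    # merge runs separated by short gaps
    if (nrow(runs) > 1L) {
      merged <- runs[1, , drop = FALSE]
      for (r in 2:nrow(runs)) {
        if ((runs$start[r] - merged$end[nrow(merged)]) * dt < th$merge_gap) {
          merged$end[nrow(merged)] <- runs$end[r]
        } else merged <- rbind(merged, runs[r, ])
      }
      runs <- merged
    }
    keep <- (runs$end - runs$start + 1L) * dt >= th$min_run
    runs <- runs[keep, , drop = FALSE]
    for (r in seq_len(nrow(runs))) {
      win <- c(seg$t[runs$start[r]], seg$t[runs$end[r]])
      ev <- segment_phases(seg, win, th)
      if (is.null(ev)) next
      fo <- final_oscillation(seg, ev, th)
      ev$T_gyr1 <- fo$T_gyr1; ev$T_gyr2 <- fo$T_gyr2
      ev$T_gyr3 <- fo$T_gyr3; ev$dT_finOs <- fo$dT_finOs
      rows[[length(rows) + 1L]] <- ev
    }
  }
  if (!length(rows)) return(out)
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$T_MO), , drop = FALSE]
  # collapse duplicate detections of the same deceleration, keeping the
  # candidate with the larger speed drop
  if (nrow(ev) > 1L) {
    grp <- cumsum(c(TRUE, diff(ev$T_MO) > 2))
    pick <- vapply(split(seq_len(nrow(ev)), grp), function(ix) {
      ix[which.max(ev$U_MO[ix] - ev$U_MC[ix])]
    }, integer(1))
    ev <- ev[sort(pick), , drop = FALSE]
  }
  ev$lunge_id <- seq_len(nrow(ev))

  # dive context
  dives <- find_dives(trace)
  ev$dive_id <- NA_integer_
  for (d in seq_len(nrow(dives))) {
    inside <- ev$T_MO >= dives$t_start[d] & ev$T_MO <= dives$t_end[d]
    ev$dive_id[inside] <- dives$dive_id[d]
  }
  ev$position_in_dive <- "solitary"
  for (d in unique(ev$dive_id[!is.na(ev$dive_id)])) {
    idx <- which(ev$dive_id == d)
    if (length(idx) == 1L) next
    ord <- idx[order(ev$T_MO[idx])]
    ev$position_in_dive[ord] <- "middle"
    ev$position_in_dive[ord[1]] <- "first"
    ev$position_in_dive[ord[length(ord)]] <- "last"
  }
  ev <- ev[, names(empty_lunge_table())]
  class(ev) <- c("lunge_table", "data.frame")
  rownames(ev) <- NULL
  ev
}

#' Randomly sample "middle" lunges
#'
#' Draws a uniform random sample without replacement of up to `n` middle
#' lunges (not the first, last, or solitary lunge of a dive), reproducibly
#' under a fixed seed. Returns all middle lunges when fewer than `n` exist,
#' and an empty subset (with a warning) when there are none.
#'
#' @param events a `lunge_table`.
#' @param n sample size, default 30.
#' @param seed integer seed (optional).
#' @return Subset of `events`, ordered by `T_MO`.
#' @export
sample_middle_lunges <- function(events, n = 30, seed = NULL) {
  mid <- which(events$position_in_dive == "middle")
  if (!length(mid)) {
    warning("no middle lunges available to sample")
    return(events[integer(0), , drop = FALSE])
  }
  take <- min(n, length(mid))
  pick <- with_seed(seed, sample(mid, take))
  out <- events[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kinematic-parameter stability versus sample size
#'
#' Bootstrap check that per-individual mean kinematics stabilise with the
#' number of randomly sampled middle lunges: for each candidate size, draws
#' `replicates` random subsets, computes the subset mean of each parameter,
#' and reports the mean and between-replicate SD of those means.
#'
#' @param events a `lunge_table`.
#' @param sizes integer vector of sample sizes.
#' @param replicates bootstrap replicates per size (SD reported as `NA`
#'   when `replicates = 1`).
#' @param seed integer seed.
#' @param params parameter columns to track.
#' @return data.frame with one row per (size, parameter): `size`, `param`,
#'   `mean`, `sd`, `capped`.
#' @export
sample_size_stability <- function(events, sizes, replicates = 20,
                                  seed = NULL,
                                  params = c("U_MO", "U_MC", "dT_accel",
                                             "dT_decel")) {
  mid <- events[events$position_in_dive == "middle", , drop = FALSE]
  pool <- nrow(mid)
  if (!pool) stop("no middle lunges in the event table", call. = FALSE)
  capped <- sizes > pool
  if (any(capped)) {
    warning(sprintf("sizes exceeding the middle-lunge pool (%d) were capped",
                    pool))
  }
  sizes_eff <- pmin(sizes, pool)
  with_seed(seed, {
    rows <- list()
    for (k in seq_along(sizes)) {
      s <- sizes_eff[k]
      means <- matrix(NA_real_, nrow = replicates, ncol = length(params),
                      dimnames = list(NULL, params))
      for (r in seq_len(replicates)) {
        pick <- sample(pool, s)
        for (p in params) means[r, p] <- mean(mid[[p]][pick], na.rm = TRUE)
      }
      for (p in params) {
        rows[[length(rows) + 1L]] <- data.frame(
          size = sizes[k], param = p, mean = mean(means[, p]),
          sd = if (replicates > 1L) stats::sd(means[, p]) else NA_real_,
          capped = capped[k]
        )
      }
    }
    do.call(rbind, rows)
  })
}
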