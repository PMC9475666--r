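# Engulfment: prescribed gape schedule, projected mouth area, engulfed
# volume (posterior integral + anterior ellipsoid wedge), engulfment drag,
# and the shape-drag-minus-thrust force residual.

#' Gape schedule for the deceleration phase
#'
#' The mouth opens linearly from closed to `max_gape` over the first third of
#' the deceleration, holds maximum gape over the middle third, and closes
#' linearly over the final third.
#'
#' @param dT_decel deceleration-phase duration (s), > 0.
#' @param max_gape maximum gape angle in degrees (default 75).
#' @return Object of class `gape_schedule` with fields `dT_decel`,
#'   `max_gape_deg`, `max_gape_rad`, `t_open` and `t_close` (phase
#'   boundaries, s), and `rate_deg_s` (angular rate on the opening/closing
#'   thirds).
#' @examples
#' sched <- gape_schedule(3)
#' gape_angle(1.5, sched)  # plateau: 75 degrees in radians
#' @export
gape_schedule <- function(dT_decel, max_gape = 75) {
  if (!is.numeric(dT_decel) || !is.finite(dT_decel) || dT_decel <= 0) {
    stop_domain("dT_decel", "deceleration duration must be finite and > 0")
  }
  if (!is.numeric(max_gape) || !is.finite(max_gape) || max_gape <= 0 ||
      max_gape > 90) {
    stop_domain("max_gape", "maximum gape must be in (0, 90] degrees")
  }
  structure(list(
    dT_decel = dT_decel,
    max_gape_deg = max_gape,
    max_gape_rad = deg2rad(max_gape),
    t_open = dT_decel / 3,
    t_close = 2 * dT_decel / 3,
    rate_deg_s = max_gape / (dT_decel / 3)
  ), class = "gape_schedule")
}

#' Instantaneous gape angle
#'
#' Piecewise-linear rise/plateau/fall per [gape_schedule()]. Vectorised over
#' `t_rel`.
#'
#' @param t_rel time since the start of the deceleration phase (s), in
#'   `[0, dT_decel]`.
#' @param schedule a [gape_schedule()].
#' @return Gape angle in radians.
#' @export
gape_angle <- function(t_rel, schedule) {
  stopifnot(inherits(schedule, "gape_schedule"))
  if (any(!is.finite(t_rel)) || any(t_rel < -1e-9) ||
      any(t_rel > schedule$dT_decel + 1e-9)) {
    stop_domain("t_rel", "must lie within [0, dT_decel]")
  }
  t_rel <- pmin(pmax(t_rel, 0), schedule$dT_decel)
  g <- ifelse(
    t_rel <= schedule$t_open,
    t_rel / schedule$t_open,
    ifelse(t_rel >= schedule$t_close,
           (schedule$dT_decel - t_rel) / schedule$t_open,
           1)
  )
  g * schedule$max_gape_rad
}

#' Projected mouth area
#'
#' `A_proj = A_jaw * sin(G_instant)`.
#'
#' @param A_jaw jaw area (m^2), > 0.
#' @param G_instant instantaneous gape angle (rad), in `[0, pi/2]`.
#' @return Projected area (m^2). Vectorised over `G_instant`.
#' @export
projected_area <- function(A_jaw, G_instant) {
  if (!is.numeric(A_jaw) || any(!is.finite(A_jaw)) || any(A_jaw <= 0)) {
    stop_domain("A_jaw", "jaw area must be finite and > 0")
  }
  if (any(!is.finite(G_instant)) || any(G_instant < -1e-12) ||
      any(G_instant > pi / 2 + 1e-12)) {
    stop_domain("G_instant", "gape angle must lie in [0, pi/2] rad")
  }
  A_jaw * sin(pmin(pmax(G_instant, 0), pi / 2))
}

#' Posterior engulfed volume
#'
#' Trapezoid integral of `U_instant * A_proj(t)` from mouth opening to
#' maximum gape: `V_pos = int_{T_MO}^{T_MG} U A_jaw sin(G) dt`. The
#' integration endpoint `T_MG` is `T_MO + dT_decel/2` by default (maximum
#' gape halfway through engulfment), or `T_MO + 2 dT_decel/3` (the end of
#' the plateau) with `vpos_end = "two_thirds"`.
#'
#' @param t sample times (s), strictly increasing; `t[1]` is taken as
#'   `T_MO`.
#' @param speed forward speed at `t` (m s^-1), non-negative.
#' @param A_jaw jaw area (m^2).
#' @param schedule a [gape_schedule()]; its `dT_decel` defines the phase
#'   boundaries relative to `t[1]`.
#' @param vpos_end `"half"` (default) or `"two_thirds"`.
#' @return Posterior volume (m^3), >= 0.
#' @export
posterior_volume <- function(t, speed, A_jaw, schedule,
                             vpos_end = c("half", "two_thirds")) {
  stopifnot(inherits(schedule, "gape_schedule"))
  vpos_end <- match.arg(vpos_end)
  if (length(t) != length(speed)) stop("t and speed must have equal length", call. = FALSE)
  t_end <- schedule$dT_decel * if (vpos_end == "half") 0.5 else 2 / 3
  t_rel <- t - t[1]
  keep <- t_rel <= t_end + 1e-9
  t_rel <- t_rel[keep]
  u <- pmax(speed[keep], 0)
  if (length(t_rel) < 2L) {
    stop("fewer than 2 samples in the [T_MO, T_MG] window", call. = FALSE)
  }
  # the integrand is only piecewise smooth: insert nodes exactly at the
  # window end and at the gape-schedule phase boundaries so the trapezoid
  # rule never straddles a kink
  full <- t - t[1]
  u_of <- function(x) stats::approx(full, pmax(speed, 0), xout = x,
                                    rule = 2)$y
  knots <- c(schedule$t_open, schedule$t_close, t_end)
  knots <- knots[knots > 1e-9 & knots < t_end + 1e-9]
  for (k in knots) {
    if (all(abs(t_rel - k) > 1e-9)) {
      t_rel <- c(t_rel, k)
      u <- c(u, u_of(k))
    }
  }
  o <- order(t_rel)
  t_rel <- t_rel[o]
  u <- u[o]
  integrand <- u * projected_area(A_jaw, gape_angle(t_rel, schedule))
  sum(diff(t_rel) * (utils::head(integrand, -1) + utils::tail(integrand, -1)) / 2)
}

#' Anterior engulfed volume
#'
#' Ellipsoid-wedge model of the buccal volume anterior to the
#' temporomandibular joint at a 75-degree gape:
#' `V_ant = 2 pi W_bz L_rbh^2 / 3 * 75/360`.
#'
#' @param W_bz bizygomatic width (m), > 0.
#' @param L_rbh rostrum-to-blowhole length (m), > 0.
#' @param wedge_deg wedge angle in degrees (default 75, matching the gape).
#' @return Anterior volume (m^3).
#' @export
anterior_volume <- function(W_bz, L_rbh, wedge_deg = 75) {
  if (!is.numeric(W_bz) || any(!is.finite(W_bz)) || any(W_bz <= 0)) {
    stop_domain("W_bz", "bizygomatic width must be finite and > 0")
  }
  if (!is.numeric(L_rbh) || any(!is.finite(L_rbh)) || any(L_rbh <= 0)) {
    stop_domain("L_rbh", "rostrum-to-blowhole length must be finite and > 0")
  }
  2 * pi * W_bz * L_rbh^2 / 3 * wedge_deg / 360
}

#' Engulfment drag
#'
#' Time-averaged reaction force from accelerating the engulfed mass up to the
#' whale's speed: `D_engulf = M_W * U_MC / dT_decel`.
#'
#' @param M_W engulfed water mass (kg), >= 0.
#' @param U_MC speed at mouth closure (m s^-1), >= 0.
#' @param dT_decel deceleration duration (s), > 0.
#' @return Drag (N).
#' @export
engulfment_drag <- function(M_W, U_MC, dT_decel) {
  if (!is.numeric(dT_decel) || any(!is.finite(dT_decel)) || any(dT_decel <= 0)) {
    stop_domain("dT_decel", "deceleration duration must be finite and > 0")
  }
  if (any(M_W < 0) || any(U_MC < 0)) {
    stop_domain("M_W/U_MC", "mass and speed must be non-negative")
  }
  M_W * U_MC / dT_decel
}

#' Shape-drag-minus-thrust force residual
#'
#' `D_shape - Th = M_kg (U_MO - U_MC) / dT_decel - D_engulf`. Positive means
#' shape drag exceeds tail thrust (deceleration faster than engulfment drag
#' alone predicts); negative means thrust exceeds shape drag. The normalised
#' residual divides by `D_engulf` and is `NA` when `D_engulf` is 0.
#'
#' @param M_kg unladen body mass (kg), > 0.
#' @param U_MO,U_MC speeds at mouth opening/closure (m s^-1); `U_MO > U_MC`
#'   is the inclusion rule.
#' @param dT_decel deceleration duration (s), > 0.
#' @param D_engulf engulfment drag (N), >= 0.
#' @return List with `residual` (N) and `normalized` (dimensionless).
#' @export
force_residual <- function(M_kg, U_MO, U_MC, dT_decel, D_engulf) {
  if (any(U_MO <= U_MC)) {
    stop("inclusion rule violated: U_MO must exceed U_MC", call. = FALSE)
  }
  if (any(D_engulf < 0)) stop_domain("D_engulf", "must be >= 0")
  if (any(dT_decel <= 0)) stop_domain("dT_decel", "must be > 0")
  residual <- M_kg * (U_MO - U_MC) / dT_decel - D_engulf
  normalized <- ifelse(D_engulf > 0, residual / D_engulf, NA_real_)
  list(residual = residual, normalized = normalized)
}

#' Full engulfment computation for one lunge
#'
#' Runs the gape schedule, posterior and anterior volume models, engulfed
#' mass, engulfment drag, and force residual for a single lunge, given the
#' deceleration-phase speed trace and the individual's morphometrics.
#'
#' @param trace a [tag_trace()] (or any data.frame with `t` and `speed`).
#' @param lunge one-row data.frame (or list) with at least `T_MO`, `T_MC`,
#'   `U_MO`, `U_MC`, `dT_decel`.
#' @param morph a [complete_morphometrics()] record.
#' @param rho seawater density (kg m^-3), default 1025.
#' @param max_gape maximum gape (degrees), default 75.
#' @param vpos_end posterior-volume endpoint convention, see
#'   [posterior_volume()].
#' @return Object of class `engulfment_result`: list with `V_pos`, `V_ant`,
#'   `V_total`, `M_W`, `D_engulf`, `force_residual`, `normalized_residual`,
#'   `rho`, `T_MG`, and the `A_proj` / `G_instant` time series over the
#'   deceleration window.
#' @export
engulf_lunge <- function(trace, lunge, morph, rho = 1025, max_gape = 75,
                         vpos_end = c("half", "two_thirds")) {
  vpos_end <- match.arg(vpos_end)
  lunge <- as.list(lunge)
  sched <- gape_schedule(lunge$dT_decel, max_gape)
  win <- trace$t >= lunge$T_MO - 1e-9 & trace$t <= lunge$T_MC + 1e-9
  if (sum(win) < 2L) stop("deceleration window contains fewer than 2 samples", call. = FALSE)
  t_w <- trace$t[win]
  u_w <- trace$speed[win]
  V_pos <- posterior_volume(t_w, u_w, morph$A_jaw, sched, vpos_end)
  if (is.na(morph$W_bz) || is.na(morph$L_rbh)) {
    stop("anterior volume requires W_bz and L_rbh in the morphometric record",
         call. = FALSE)
  }
  V_ant <- anterior_volume(morph$W_bz, morph$L_rbh, max_gape)
  V_total <- V_pos + V_ant
  M_W <- rho * V_total
  D_engulf <- engulfment_drag(M_W, lunge$U_MC, lunge$dT_decel)
  fr <- force_residual(morph$M_kg, lunge$U_MO, lunge$U_MC, lunge$dT_decel,
                       D_engulf)
  G <- gape_angle(t_w - t_w[1], sched)
  structure(list(
    V_pos = V_pos, V_ant = V_ant, V_total = V_total, M_W = M_W,
    D_engulf = D_engulf, force_residual = fr$residual,
    normalized_residual = fr$normalized, rho = rho,
    T_MG = lunge$T_MO + sched$dT_decel / 2,
    t = t_w, G_instant = G, A_proj = projected_area(morph$A_jaw, G)
  ), class = "engulfment_result")
}

#' @export
print.engulfment_result <- function(x, ...) {
  cat(sprintf("<engulfment_result> V_pos %.2f + V_ant %.2f = %.2f m^3 | M_W %.0f kg\n",
              x$V_pos, x$V_ant, x$V_total, x$M_W))
  cat(sprintf("  D_engulf %.0f N | residual %.0f N (normalized %.3f)\n",
              x$D_engulf, x$force_residual, x$normalized_residual))
  invisible(x)
}
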