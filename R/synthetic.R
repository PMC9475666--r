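# Synthetic deployment generator: seeded multi-dive tag traces with known
# ground-truth lunge annotations, statistically calibrated to the published
# species means, so the whole pipeline is testable without field data.

#' Species profile for the synthetic generator
#'
#' Means and spreads for the morphometric and kinematic quantities the
#' generator draws from, calibrated to published species-level means where
#' those are printed (body length, jaw areas, U_MO, phase durations,
#' final-oscillation period). Quantities the source tables do not pin down
#' (glide durations, adjustment-phase slopes, dive structure, channel noise)
#' are one-time realistic choices documented in the methods vignette; in
#' particular, mouth-closure speed U_MC is set from momentum/force-residual
#' consistency (the printed post-lunge minimum speeds are internally
#' inconsistent with the printed force residuals for the three large
#' species).
#'
#' @param species `"minke"`, `"humpback"`, `"fin"`, or `"blue"`.
#' @param ... named overrides for any profile field.
#' @return Object of class `species_profile` (a list).
#' @export
species_profile <- function(species = c("minke", "humpback", "fin", "blue"),
                            ...) {
  species <- match.arg(species)
  base <- list(
    minke = list(
      L_body_mean = 7.6,  L_body_sd = 0.8,
      w_max_mean = 1.00, W_bz_mean = 1.10, L_rbh_mean = 2.09,
      A_jaw_mean = 1.12,
      U_MO_mean = 4.57, U_MO_sd = 0.20,
      U_MC_mean = 3.28, U_MC_sd = 0.15,
      dT_accel_mean = 7.47, dT_accel_sd = 0.70,
      dT_decel_mean = 0.67, dT_decel_sd = 0.05,
      dT_adjust_mean = 2.0, dT_adjust_sd = 0.40, p_adjust = 0.7,
      adj_slope = 0.35, U_fluke_mean = 2.0,
      dT_post_mean = 2.0, U_min_drop = 0.75,
      finos_mult = 3.42, lunges_per_dive = 5, lunge_depth = 70
    ),
    humpback = list(
      L_body_mean = 11.4, L_body_sd = 0.8,
      w_max_mean = 1.65, W_bz_mean = 1.63, L_rbh_mean = 3.93,
      A_jaw_mean = 4.02,
      U_MO_mean = 3.33, U_MO_sd = 0.20,
      U_MC_mean = 1.52, U_MC_sd = 0.12,
      dT_accel_mean = 7.63, dT_accel_sd = 0.80,
      dT_decel_mean = 2.93, dT_decel_sd = 0.20,
      dT_adjust_mean = 1.8, dT_adjust_sd = 0.40, p_adjust = 0.6,
      adj_slope = 0.05, U_fluke_mean = 1.25,
      dT_post_mean = 1.8, U_min_drop = 0.45,
      finos_mult = 1.43, lunges_per_dive = 3, lunge_depth = 100
    ),
    fin = list(
      L_body_mean = 18.9, L_body_sd = 1.0,
      w_max_mean = 2.30, W_bz_mean = 2.20, L_rbh_mean = 4.33,
      A_jaw_mean = 5.25,
      U_MO_mean = 3.95, U_MO_sd = 0.20,
      U_MC_mean = 1.97, U_MC_sd = 0.15,
      dT_accel_mean = 8.97, dT_accel_sd = 0.90,
      dT_decel_mean = 3.53, dT_decel_sd = 0.25,
      dT_adjust_mean = 1.8, dT_adjust_sd = 0.40, p_adjust = 0.6,
      adj_slope = 0.12, U_fluke_mean = 1.6,
      dT_post_mean = 1.8, U_min_drop = 0.45,
      finos_mult = 1.36, lunges_per_dive = 3, lunge_depth = 150
    ),
    blue = list(
      L_body_mean = 22.3, L_body_sd = 1.4,
      w_max_mean = 2.90, W_bz_mean = 2.90, L_rbh_mean = 5.14,
      A_jaw_mean = 9.10,
      U_MO_mean = 4.01, U_MO_sd = 0.20,
      U_MC_mean = 1.65, U_MC_sd = 0.12,
      dT_accel_mean = 17.54, dT_accel_sd = 1.50,
      dT_decel_mean = 4.17, dT_decel_sd = 0.30,
      dT_adjust_mean = 1.8, dT_adjust_sd = 0.40, p_adjust = 0.6,
      adj_slope = 0.08, U_fluke_mean = 1.3,
      dT_post_mean = 2.0, U_min_drop = 0.50,
      finos_mult = 1.79, lunges_per_dive = 3, lunge_depth = 160
    )
  )[[species]]
  shared <- list(
    species = species,
    # tailbeat frequency scales as 1/L against a 0.25 Hz blue-whale anchor
    tailbeat_hz_anchor = 0.25, tailbeat_anchor_L = 22.3,
    ripple_amp = 0.15,      # m/s, speed ripple at tailbeat frequency
    gyro_tb_amp = 0.30,     # rad/s, tailbeat gyro amplitude
    gyro_finos_amp = 0.25,  # rad/s, final long-period oscillation amplitude
    noise_depth = 0.05, noise_speed = 0.05, noise_gyro = 0.02,
    noise_pitch = 0.02,
    glide_min = 4.0, glide_max = 6.0,  # pre-lunge glide (s)
    recovery_dur = 3.0,                # post-minimum speed recovery (s)
    surface_dur = 60, descent_speed = 2.0, descent_pitch = 1.05,
    sample_rate = 10
  )
  prof <- utils::modifyList(c(base, shared), list(...))
  stopifnot(prof$U_MO_mean > prof$U_MC_mean,
            prof$dT_decel_mean > 0, prof$finos_mult > 1)
  structure(prof, class = "species_profile")
}

# truncated-normal draw: +/- 3 sd and a positive floor
rtrunc <- function(n, mean, sd, lo = -Inf) {
  if (sd <= 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, pmax(mean - 3 * sd, lo)), mean + 3 * sd)
}

#' Simulate one tagged deployment
#'
#' Builds a multi-dive 10 Hz deployment for one synthetic individual:
#' surface interval, steep descent, a bottom phase containing lunges (glide,
#' fluking acceleration ramp with tailbeat ripple, optional adjustment
#' phase, steep linear deceleration spanned by a single long-period
#' gyroscope oscillation, post-closure decline to the speed minimum, slow
#' recovery), then ascent. Gaussian sensor noise is added per channel and
#' every injected event time and pre-noise speed is stored as ground truth.
#'
#' @param profile a [species_profile()].
#' @param n_dives number of foraging dives (>= 1).
#' @param seed integer seed; the trace is bit-reproducible given
#'   (profile, n_dives, seed).
#' @param lunges set `FALSE` for a lunge-free control deployment (cruising
#'   dives with gentle speed variation only).
#' @return Object of class `synthetic_deployment`: list with `trace`
#'   ([tag_trace()]), `morph` ([complete_morphometrics()]), `truth`
#'   (data.frame of injected lunge events), `seed`, `profile`.
#' @examples
#' dep <- simulate_deployment(species_profile("minke"), n_dives = 2, seed = 1)
#' nrow(dep$truth)
#' @export
simulate_deployment <- function(profile, n_dives = 4, seed = 1,
                                lunges = TRUE) {
  stopifnot(inherits(profile, "species_profile"), n_dives >= 1)
  with_seed(seed, {
    p <- profile
    fs <- p$sample_rate
    dt <- 1 / fs

    # --- individual morphometrics, allometrically structured around L ----
    L <- rtrunc(1, p$L_body_mean, p$L_body_sd, lo = 0.5 * p$L_body_mean)
    scl <- L / p$L_body_mean
    jit <- function(sd) exp(stats::rnorm(1, 0, sd))
    morph <- complete_morphometrics(
      individual_id = sprintf("%s_sim%04d", p$species, seed %% 10000L),
      species = p$species,
      L_body = L,
      w_max = p$w_max_mean * scl * jit(0.03),
      W_bz = p$W_bz_mean * scl * jit(0.03),
      L_rbh = p$L_rbh_mean * scl * jit(0.03),
      A_jaw_direct = p$A_jaw_mean * scl^2 * jit(0.08)
    )
    f_tb <- p$tailbeat_hz_anchor * p$tailbeat_anchor_L / L
    P_tb <- 1 / f_tb

    # --- assemble per-dive speed/depth anchors and truth events ----------
    t_anchor <- 0; v_anchor <- 1.5
    d_anchor_t <- 0; d_anchor_z <- 0.3
    seg_flukes <- list()   # (start, end) spans with tailbeat activity
    seg_finos <- list()    # (T_gyr1, period) final oscillations
    truth <- list()
    t_cur <- 0
    add_v <- function(t, v) {
      t_anchor <<- c(t_anchor, t); v_anchor <<- c(v_anchor, v)
    }
    add_z <- function(t, z) {
      d_anchor_t <<- c(d_anchor_t, t); d_anchor_z <<- c(d_anchor_z, z)
    }

    for (dv in seq_len(n_dives)) {
      # surface interval
      surf <- p$surface_dur * stats::runif(1, 0.8, 1.2)
      t_cur <- t_cur + surf
      add_v(t_cur, 1.6); add_z(t_cur, 0.3)
      # descent
      depth <- p$lunge_depth * stats::runif(1, 0.85, 1.15)
      rate <- p$descent_speed * sin(p$descent_pitch)
      desc <- (depth - 0.3) / rate
      t_cur <- t_cur + desc
      add_v(t_cur, p$descent_speed); add_z(t_cur, depth)
      # bottom phase
      n_lg <- if (!lunges) 0L else {
        if (stats::runif(1) < 0.08) 1L else max(1L, stats::rpois(1, p$lunges_per_dive))
      }
      dive_t0 <- t_cur
      if (n_lg == 0L) {
        # cruising bottom: gentle speed variation only
        dur <- stats::runif(1, 120, 200)
        steps <- seq(0, dur, by = 20)[-1]
        for (s in steps) add_v(t_cur + s, stats::runif(1, 1.5, 2.1))
        t_cur <- t_cur + dur
        add_z(t_cur, depth)
      } else {
        for (lg in seq_len(n_lg)) {
          U_fl <- rtrunc(1, p$U_fluke_mean, 0.1, lo = 0.5)
          U_MO <- rtrunc(1, p$U_MO_mean, p$U_MO_sd, lo = U_fl + 0.8)
          U_MC <- rtrunc(1, p$U_MC_mean, p$U_MC_sd, lo = 0.3)
          if (U_MC >= U_MO - 0.5) U_MC <- U_MO - 0.5
          dTa <- rtrunc(1, p$dT_accel_mean, p$dT_accel_sd, lo = 3)
          dTd <- rtrunc(1, p$dT_decel_mean, p$dT_decel_sd,
                        lo = 0.5 * p$dT_decel_mean)
          dTj <- if (stats::runif(1) < p$p_adjust) {
            rtrunc(1, p$dT_adjust_mean, p$dT_adjust_sd, lo = 1.2)
          } else 0
          U_max <- U_MO + p$adj_slope * dTj
          glide <- stats::runif(1, p$glide_min, p$glide_max)
          # glide at U_fl, then fluking ramp
          add_v(t_cur + 0.5, v_anchor[length(v_anchor)])
          T_fluke <- t_cur + 0.5 + glide
          add_v(T_fluke, U_fl)
          T_accel <- T_fluke
          T_max <- T_accel + dTa
          add_v(T_max, U_max)
          T_MO <- T_max + dTj
          if (dTj > 0) add_v(T_MO, U_MO)
          T_MC <- T_MO + dTd
          add_v(T_MC, U_MC)
          dTp <- rtrunc(1, p$dT_post_mean, 0.25, lo = 0.8)
          dTp <- min(dTp, 4.5)
          U_min <- max(U_MC - p$U_min_drop * stats::runif(1, 0.85, 1.15), 0.2)
          T_min <- T_MC + dTp
          add_v(T_min, U_min)
          # a recovery stroke lifts speed briefly after the minimum, then
          # the whale holds and blends into the next glide; the speed
          # minimum must be a genuine local minimum for its within-5-s
          # field definition to be meaningful
          T_rec <- T_min + 1.5
          add_v(T_rec, U_min + 0.3)
          # fluking span (speed ripple + gyro tailbeats) covers the ramp;
          # the final tailbeat completes just before maximum speed / mouth
          # opening, so the span ends half a tailbeat period early
          P_fin <- p$finos_mult * dTd
          T_g1 <- T_MO - max(0, P_fin - dTd) / 2
          fl_end <- min(T_max, T_g1) - 0.5 * P_tb
          if (fl_end < T_fluke + P_tb) {
            fl_end <- T_fluke + 0.6 * (T_max - T_fluke)
          }
          seg_flukes[[length(seg_flukes) + 1L]] <- c(T_fluke, fl_end)
          seg_finos[[length(seg_finos) + 1L]] <- c(T_g1, P_fin)
          truth[[length(truth) + 1L]] <- data.frame(
            dive_id = dv, lunge_in_dive = lg,
            T_fluke = T_fluke, T_accel = T_accel, T_max = T_max,
            T_MO = T_MO, T_MC = T_MC, T_min = T_min,
            U_fluke = U_fl, U_accel = U_fl, U_max = U_max,
            U_MO = U_MO, U_MC = U_MC, U_min = U_min,
            dT_accel = dTa, dT_adjust = dTj, dT_decel = dTd,
            T_gyr1 = T_g1, T_gyr2 = T_g1 + P_fin / 2, T_gyr3 = T_g1 + P_fin,
            dT_finOs = P_fin, depth_at_MO = NA_real_
          )
          t_cur <- T_rec + stats::runif(1, 1, 3)
        }
        add_z(t_cur, depth)
      }
      # ascent
      t_cur <- t_cur + desc
      add_v(t_cur, p$descent_speed); add_z(t_cur, 0.3)
    }
    t_cur <- t_cur + 20
    add_v(t_cur, 1.5); add_z(t_cur, 0.3)

    # --- rasterise to the sample grid ------------------------------------
    tt <- seq(0, t_cur, by = dt)
    speed <- stats::approx(t_anchor, v_anchor, xout = tt, rule = 2)$y
    depth_m <- stats::approx(d_anchor_t, d_anchor_z, xout = tt, rule = 2)$y
    gyro <- numeric(length(tt))
    # tailbeat ripple + gyro during fluking spans. Both start at full stroke
    # amplitude (the sine starts at zero, so the channels stay continuous)
    # and taper out over the final beat as fluking ceases.
    for (sg in seg_flukes) {
      i <- tt >= sg[1] & tt <= sg[2]
      ph <- 2 * pi * f_tb * (tt[i] - sg[1])
      tap_out <- pmin(1, pmax(0, (sg[2] - tt[i]) / P_tb))
      speed[i] <- speed[i] + p$ripple_amp * sin(ph) * tap_out
      gyro[i] <- gyro[i] + p$gyro_tb_amp * sin(ph) * tap_out
    }
    for (sg in seg_finos) {
      i <- tt >= sg[1] & tt <= sg[1] + sg[2]
      gyro[i] <- gyro[i] +
        p$gyro_finos_amp * sin(2 * pi * (tt[i] - sg[1]) / sg[2])
    }
    # smooth the depth wiggle slightly and derive a consistent pitch
    dz <- c(diff(depth_m), 0) / dt
    ratio <- pmax(pmin(dz / pmax(speed, 0.3), 0.95), -0.95)
    pitch <- asin(ratio)

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(dive_id = integer(), T_MO = numeric())
    if (nrow(truth)) {
      truth$depth_at_MO <- stats::approx(tt, depth_m, xout = truth$T_MO,
                                         rule = 2)$y
      npd <- stats::ave(truth$lunge_in_dive, truth$dive_id,
                        FUN = length)
      truth$position_in_dive <- ifelse(
        npd == 1L, "solitary",
        ifelse(truth$lunge_in_dive == 1L, "first",
               ifelse(truth$lunge_in_dive == npd, "last", "middle")))
    }

    trace <- tag_trace(
      t = tt,
      depth = depth_m + stats::rnorm(length(tt), 0, p$noise_depth),
      pitch = pitch + stats::rnorm(length(tt), 0, p$noise_pitch),
      speed = pmax(speed + stats::rnorm(length(tt), 0, p$noise_speed), 0),
      gyro_y = gyro + stats::rnorm(length(tt), 0, p$noise_gyro),
      sample_rate = fs
    )
    structure(list(trace = trace, morph = morph, truth = truth,
                   seed = seed, profile = p),
              class = "synthetic_deployment")
  })
}

#' @export
print.synthetic_deployment <- function(x, ...) {
  cat(sprintf("<synthetic_deployment> %s seed %d: %d lunges over %.0f s\n",
              x$morph$individual_id, x$seed, nrow(x$truth),
              x$trace$t[nrow(x$trace)]))
  invisible(x)
}

#' Simulate a cohort of deployments
#'
#' Independent deployments per species with per-individual morphometrics;
#' per-deployment seeds are derived deterministically from the master seed.
#'
#' @param species character vector of species names (repeats allowed) or a
#'   named integer vector of counts, e.g. `c(minke = 5, blue = 5)`.
#' @param n_dives dives per deployment.
#' @param seed master seed.
#' @param profiles optional named list of [species_profile()] overrides.
#' @return List of `synthetic_deployment` objects.
#' @export
simulate_cohort <- function(species, n_dives = 3, seed = 1, profiles = NULL) {
  if (!is.null(names(species)) && is.numeric(species)) {
    species <- rep(names(species), times = species)
  }
  n <- length(species)
  stopifnot(n >= 1)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i) {
    prof <- profiles[[species[i]]] %||% species_profile(species[i])
    simulate_deployment(prof, n_dives = n_dives, seed = sub_seeds[i])
  })
}
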