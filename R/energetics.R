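# Energetics: per-lunge metabolic cost (fluke, parasitic, VGB, ceteral),
# energetic gain from prey, foraging efficiency at lunge/dive/day scales,
# and the minimum momentum speed.

#' Energetic parameter set
#'
#' Bundles the efficiencies, coefficients, and environment constants used by
#' the cost/gain model. Defaults: metabolic efficiency `mu_met` 0.25,
#' propulsive (Froude) efficiency `mu_prop` 0.80, digestive efficiency
#' `mu_prey` 0.84, added-mass coefficient `k` 0.05 for humpbacks and 0.03
#' for other species, metabolic correction `f_Met` 2, ceteral basal-rate
#' coefficient 4.1 (W kg^-0.75) with Kleiber exponent 0.75, seawater density
#' 1025 kg m^-3 and kinematic viscosity 1.05e-6 m^2 s^-1, and a prey energy
#' content per kg of engulfed water `E_prey` of 3.01118 kJ kg^-1 (calibrated
#' so that the minke species-mean engulfed volume reproduces the minke
#' species-mean energetic gain; see [calibrate_prey_density()]).
#'
#' `cost_mode` selects between the full ceteral cost model
#' (`E_cost = E_accel + E_decel + cet`) and the averaged approximation
#' (`E_cost = 1.5 (E_accel + E_decel)`).
#'
#' @param mu_met,mu_prop,mu_prey efficiencies in (0, 1].
#' @param k_added named numeric vector of added-mass coefficients by species.
#' @param f_Met dimensionless metabolic correction factor.
#' @param cet_basal_coeff,cet_exponent ceteral basal-rate coefficients.
#' @param E_prey prey energy per kg of engulfed water (kJ kg^-1).
#' @param rho seawater density (kg m^-3).
#' @param nu seawater kinematic viscosity (m^2 s^-1).
#' @param cost_mode `"ceteral"` or `"averaged"`.
#' @param accel_speed_pair `"mo_mc"` (printed-equation speeds U_MO/U_MC in
#'   the fluke-work term) or `"max_accel"` (substitute U_max/U_accel).
#' @param ln_day named numeric vector: lunges per day by species.
#' @return Object of class `energetic_params` (a list).
#' @export
energetic_params <- function(mu_met = 0.25, mu_prop = 0.80, mu_prey = 0.84,
                             k_added = c(minke = 0.03, humpback = 0.05,
                                         fin = 0.03, blue = 0.03),
                             f_Met = 2.0,
                             cet_basal_coeff = 4.1, cet_exponent = 0.75,
                             E_prey = 3.01118,
                             rho = 1025, nu = 1.05e-6,
                             cost_mode = c("ceteral", "averaged"),
                             accel_speed_pair = c("mo_mc", "max_accel"),
                             ln_day = c(minke = 1000, humpback = 300,
                                        fin = 250, blue = 200)) {
  for (e in c(mu_met, mu_prop, mu_prey)) {
    if (!is.finite(e) || e <= 0 || e > 1) {
      stop_domain("efficiency", "mu_met, mu_prop, mu_prey must lie in (0, 1]")
    }
  }
  if (any(k_added < 0)) stop_domain("k_added", "added-mass coefficients must be >= 0")
  if (E_prey < 0) stop_domain("E_prey", "prey energy density must be >= 0")
  structure(list(
    mu_met = mu_met, mu_prop = mu_prop, mu_prey = mu_prey,
    k_added = k_added, f_Met = f_Met,
    cet_basal_coeff = cet_basal_coeff, cet_exponent = cet_exponent,
    E_prey = E_prey, rho = rho, nu = nu,
    cost_mode = match.arg(cost_mode),
    accel_speed_pair = match.arg(accel_speed_pair),
    ln_day = ln_day
  ), class = "energetic_params")
}

#' Parasitic drag work over the acceleration phase
#'
#' Evaluates the flat-plate-with-form-factor parasitic work expression
#' verbatim:
#' `rho * S_wet * 0.072 / Re_MO^0.2 * [1 + 1.5 (w/L)^1.5 + 7 (w/L)^3]
#'  * dT_accel / (3.8 (U_MO - U_MC)) * U_MO^0.2 * (U_MO^3.8 - U_MC^3.8)`
#' with `Re_MO = U_MO * L_body / nu`, then converts J to kJ. At exact
#' `U_MO == U_MC` the continuous limit (proportional to `dT_accel * U_MO^3`)
#' is returned.
#'
#' @param rho seawater density (kg m^-3).
#' @param S_wet wetted surface area (m^2).
#' @param w_max maximum body width (m).
#' @param L_body body length (m).
#' @param U_MO,U_MC mouth-opening and mouth-closure speeds (m s^-1),
#'   `U_MO >= U_MC >= 0`.
#' @param dT_accel acceleration-phase duration (s).
#' @param nu kinematic viscosity (m^2 s^-1).
#' @return Parasitic work in kJ.
#' @export
parasitic_work <- function(rho, S_wet, w_max, L_body, U_MO, U_MC, dT_accel,
                           nu = 1.05e-6) {
  if (any(c(rho, S_wet, w_max, L_body, dT_accel, nu) <= 0)) {
    stop_domain("geometry", "rho, S_wet, w_max, L_body, dT_accel, nu must be > 0")
  }
  if (any(U_MO < U_MC) || any(U_MC < 0) || any(U_MO <= 0)) {
    stop_domain("speeds", "require U_MO >= U_MC >= 0 and U_MO > 0")
  }
  Re <- U_MO * L_body / nu
  form <- 1 + 1.5 * (w_max / L_body)^1.5 + 7.0 * (w_max / L_body)^3
  common <- rho * S_wet * 0.072 / Re^0.2 * form * U_MO^0.2
  du <- U_MO - U_MC
  joules <- ifelse(
    du > 0,
    common * dT_accel / (3.8 * du) * (U_MO^3.8 - U_MC^3.8),
    # limit of (U^3.8 - Uc^3.8)/(3.8 (U - Uc)) as Uc -> U is U^2.8
    common * dT_accel * U_MO^2.8
  )
  joules / 1000
}

#' Mechanical fluke work during the acceleration phase
#'
#' `W_flukes = 1/2 M (U1^2 - U2^2) + W_parasite + 1/2 k M (U1^2 - U2^2)`,
#' where the speed pair (U1, U2) is (U_MO, U_MC) as printed (the default) or
#' (U_max, U_accel) under the alternative reading selected by
#' `accel_speed_pair = "max_accel"` in [energetic_params()].
#'
#' @param M_kg body mass (kg).
#' @param k added-mass coefficient (dimensionless, >= 0).
#' @param U1,U2 speed pair (m s^-1), `U1 >= U2`.
#' @param W_parasite parasitic work (kJ).
#' @return Fluke work in kJ.
#' @export
fluke_work <- function(M_kg, k, U1, U2, W_parasite = 0) {
  if (any(U1 < U2)) stop_domain("speeds", "require U1 >= U2")
  if (any(k < 0)) stop_domain("k", "added-mass coefficient must be >= 0")
  kinetic_kj <- 0.5 * M_kg * (U1^2 - U2^2) / 1000
  kinetic_kj * (1 + k) + W_parasite
}

#' Mechanical work by the ventral groove blubber musculature
#'
#' `W_VGB = 1/2 M_kg U_MO^2 (U_MC/U_MO)(M_W/M_kg)(1 + U_MC/U_MO)`,
#' algebraically `1/2 M_W U_MO U_MC (1 + U_MC/U_MO)` - independent of body
#' mass at fixed engulfed mass.
#'
#' @param M_kg body mass (kg), > 0 (cancels algebraically).
#' @param M_W engulfed water mass (kg), >= 0.
#' @param U_MO,U_MC mouth-opening/closure speeds (m s^-1), `U_MO > 0`.
#' @return VGB work in kJ.
#' @export
vgb_work <- function(M_kg, M_W, U_MO, U_MC) {
  if (any(U_MO <= 0)) stop_domain("U_MO", "must be > 0")
  if (any(M_W < 0) || any(U_MC < 0)) stop_domain("M_W/U_MC", "must be >= 0")
  r <- U_MC / U_MO
  0.5 * M_kg * U_MO^2 * r * (M_W / M_kg) * (1 + r) / 1000
}

#' Ceteral (non-locomotor) basal expenditure rate
#'
#' The Kleiber-form basal rate `f_Met * 4.1 * M_kg^0.75`, interpreted in
#' watts. (Reading this as a total per-lunge cost in kJ gives ceteral costs
#' several times the published total lunge cost for every species, so the
#' rate interpretation is used; see the methods vignette.)
#'
#' @param M_kg body mass (kg), > 0.
#' @param f_Met metabolic correction factor.
#' @param params optional [energetic_params()] supplying the coefficient and
#'   exponent.
#' @return Rate in W.
#' @export
ceteral_rate <- function(M_kg, f_Met = 2.0, params = NULL) {
  if (any(M_kg <= 0)) stop_domain("M_kg", "body mass must be > 0")
  coeff <- if (is.null(params)) 4.1 else params$cet_basal_coeff
  expo <- if (is.null(params)) 0.75 else params$cet_exponent
  f_Met * coeff * M_kg^expo
}

#' Ceteral cost over one lunge
#'
#' Ceteral rate times the lunge duration `dT_accel + dT_decel`, in kJ.
#'
#' @inheritParams ceteral_rate
#' @param dT_accel,dT_decel phase durations (s), >= 0.
#' @return Ceteral cost in kJ.
#' @export
ceteral_cost <- function(M_kg, f_Met = 2.0, dT_accel, dT_decel,
                         params = NULL) {
  if (any(dT_accel < 0) || any(dT_decel < 0)) {
    stop_domain("durations", "phase durations must be >= 0")
  }
  ceteral_rate(M_kg, f_Met, params) * (dT_accel + dT_decel) / 1000
}

#' Total metabolic cost of a lunge
#'
#' Combines the acceleration-phase cost `E_accel = W_flukes/(mu_prop mu_met)`
#' and deceleration-phase cost `E_decel = W_VGB/mu_met` (the deceleration
#' fluke-work term is omitted) either with the ceteral term
#' (`cost_mode = "ceteral"`: `E_accel + E_decel + cet`) or via the averaged
#' approximation (`cost_mode = "averaged"`: `1.5 (E_accel + E_decel)`).
#'
#' @param E_accel,E_decel phase metabolic costs (kJ), >= 0.
#' @param cet ceteral cost (kJ); required for `"ceteral"` mode.
#' @param cost_mode `"ceteral"` or `"averaged"`.
#' @return Total cost in kJ.
#' @examples
#' lunge_cost(100, 50, cost_mode = "averaged")       # 225
#' lunge_cost(100, 50, cet = 30, cost_mode = "ceteral") # 180
#' @export
lunge_cost <- function(E_accel, E_decel, cet = NULL,
                       cost_mode = c("ceteral", "averaged")) {
  cost_mode <- match.arg(cost_mode)
  if (any(E_accel < 0) || any(E_decel < 0)) {
    stop_domain("E_accel/E_decel", "phase costs must be >= 0")
  }
  if (cost_mode == "averaged") {
    1.5 * (E_accel + E_decel)
  } else {
    if (is.null(cet)) stop("cost_mode = 'ceteral' requires `cet`", call. = FALSE)
    E_accel + E_decel + cet
  }
}

#' Energetic gain of a lunge
#'
#' `E_gain = M_W * E_prey * mu_prey`.
#'
#' @param M_W engulfed water mass (kg).
#' @param E_prey prey energy per kg of engulfed water (kJ kg^-1).
#' @param mu_prey digestive efficiency.
#' @return Gain in kJ.
#' @export
lunge_gain <- function(M_W, E_prey, mu_prey = 0.84) {
  if (any(M_W < 0) || any(E_prey < 0) || any(mu_prey < 0)) {
    stop_domain("inputs", "must be non-negative")
  }
  M_W * E_prey * mu_prey
}

#' Back-solve the per-volume energetic yield from a (gain, volume) pair
#'
#' Returns `E_prey` such that `lunge_gain(rho * V_total, E_prey, mu_prey)`
#' equals `E_gain`: `E_prey = E_gain / (rho * V_total * mu_prey)`. Used to
#' calibrate the default prey energy density from the minke species-mean row
#' of [species_reference()].
#'
#' @param E_gain energetic gain (kJ).
#' @param V_total engulfed volume (m^3).
#' @param rho seawater density (kg m^-3).
#' @param mu_prey digestive efficiency.
#' @return `E_prey` in kJ per kg of engulfed water.
#' @export
calibrate_prey_density <- function(E_gain, V_total, rho = 1025,
                                   mu_prey = 0.84) {
  if (any(V_total <= 0) || any(rho <= 0) || any(mu_prey <= 0)) {
    stop_domain("inputs", "V_total, rho, mu_prey must be > 0")
  }
  E_gain / (rho * V_total * mu_prey)
}

#' Foraging efficiency
#'
#' `FE = E_gain / E_cost`.
#'
#' @param E_gain energetic gain (kJ), >= 0.
#' @param E_cost energetic cost (kJ), > 0.
#' @return Dimensionless ratio.
#' @export
foraging_efficiency <- function(E_gain, E_cost) {
  if (any(E_cost <= 0)) stop_domain("E_cost", "must be > 0")
  E_gain / E_cost
}

#' Foraging efficiency at lunge, dive, and day timescales
#'
#' Scales a lunge's cost and gain to the encompassing dive and to a 24-hour
#' day. The dive-scale cost is `ln_dive * E_cost` plus the ceteral basal
#' rate applied to the non-lunging seconds of the dive; the day-scale cost
#' is built the same way over 86,400 s with `ln_day` lunges. Gains scale by
#' the lunge counts alone, so `FE_dive <= FE` whenever the excess term is
#' positive.
#'
#' @param E_gain,E_cost per-lunge gain and cost (kJ).
#' @param M_kg body mass (kg), for the basal excess rate.
#' @param dT_lunge duration of one lunge, `dT_accel + dT_decel` (s).
#' @param ln_dive lunges in the encompassing dive (>= 1).
#' @param dT_dive dive duration (s), must be >= `ln_dive * dT_lunge`.
#' @param ln_day lunges per day.
#' @param f_Met metabolic correction factor for the excess rate.
#' @param params optional [energetic_params()].
#' @return Object of class `timescale_efficiency`: list with `FE_lunge`,
#'   `FE_dive`, `FE_day`, `ln_dive`, `ln_day`, `dT_dive`.
#' @export
timescale_efficiency <- function(E_gain, E_cost, M_kg, dT_lunge,
                                 ln_dive, dT_dive, ln_day,
                                 f_Met = 2.0, params = NULL) {
  if (ln_dive < 1) stop_domain("ln_dive", "must be >= 1")
  if (dT_dive < ln_dive * dT_lunge) {
    stop("dT_dive shorter than the total lunging time ln_dive * dT_lunge",
         call. = FALSE)
  }
  day_s <- 86400
  if (day_s < ln_day * dT_lunge) {
    stop("ln_day * dT_lunge exceeds one day", call. = FALSE)
  }
  rate_kw <- ceteral_rate(M_kg, f_Met, params) / 1000  # kJ s^-1
  excess_dive <- rate_kw * (dT_dive - ln_dive * dT_lunge)
  excess_day <- rate_kw * (day_s - ln_day * dT_lunge)
  FE <- foraging_efficiency(E_gain, E_cost)
  structure(list(
    FE_lunge = FE,
    FE_dive = (ln_dive * E_gain) / (ln_dive * E_cost + excess_dive),
    FE_day = (ln_day * E_gain) / (ln_day * E_cost + excess_day),
    ln_dive = ln_dive, ln_day = ln_day, dT_dive = dT_dive
  ), class = "timescale_efficiency")
}

#' Minimum momentum lunging speed
#'
#' The minimum mouth-opening speed that lets the buccal cavity fill purely
#' on momentum over one VGB length under the observed deceleration:
#' `U_mom = sqrt(2 L_VGB (U_MO - U_MC) / dT_decel)`.
#'
#' @param L_VGB ventral groove blubber length (m), > 0.
#' @param U_MO,U_MC speeds (m s^-1), `U_MO >= U_MC`.
#' @param dT_decel deceleration duration (s), > 0.
#' @return Speed in m s^-1.
#' @export
min_momentum_speed <- function(L_VGB, U_MO, U_MC, dT_decel) {
  if (any(L_VGB <= 0)) stop_domain("L_VGB", "must be > 0")
  if (any(dT_decel <= 0)) stop_domain("dT_decel", "must be > 0")
  if (any(U_MO < U_MC)) stop_domain("speeds", "require U_MO >= U_MC")
  sqrt(2 * L_VGB * (U_MO - U_MC) / dT_decel)
}

#' Full energetic accounting for one lunge
#'
#' Computes every work and cost term, the gain, the three-timescale
#' efficiencies, the Reynolds number at mouth opening, and the minimum
#' momentum speed for a single lunge, from its kinematic event record, the
#' engulfment result, and the individual's morphometrics.
#'
#' @param lunge one-row data.frame/list with `U_MO`, `U_MC`, `dT_accel`,
#'   `dT_decel`, and (for the `"max_accel"` speed pair) `U_max`, `U_accel`;
#'   optionally `ln_dive` and `dT_dive` for the dive-scale efficiency.
#' @param engulf an [engulf_lunge()] result (or list with `M_W`).
#' @param morph a [complete_morphometrics()] record.
#' @param params an [energetic_params()].
#' @return One-row data.frame with columns `W_parasite`, `W_flukes`,
#'   `W_VGB`, `E_accel`, `E_decel`, `cet_cost`, `E_cost`, `E_gain`, `FE`,
#'   `FE_dive`, `FE_day`, `Re_MO`, `U_mom`.
#' @export
lunge_energetics <- function(lunge, engulf, morph,
                             params = energetic_params()) {
  lunge <- as.list(lunge)
  k <- params$k_added[[morph$species]] %||% 0.03
  W_par <- parasitic_work(params$rho, morph$S_wet, morph$w_max, morph$L_body,
                          lunge$U_MO, lunge$U_MC, lunge$dT_accel, params$nu)
  if (params$accel_speed_pair == "max_accel") {
    U1 <- lunge$U_max; U2 <- lunge$U_accel
  } else {
    U1 <- lunge$U_MO; U2 <- lunge$U_MC
  }
  W_fl <- fluke_work(morph$M_kg, k, U1, U2, W_par)
  W_vgb <- vgb_work(morph$M_kg, engulf$M_W, lunge$U_MO, lunge$U_MC)
  E_accel <- W_fl / (params$mu_prop * params$mu_met)
  E_decel <- W_vgb / params$mu_met
  cet <- ceteral_cost(morph$M_kg, params$f_Met, lunge$dT_accel,
                      lunge$dT_decel, params)
  E_cost <- lunge_cost(E_accel, E_decel, cet, params$cost_mode)
  E_gain <- lunge_gain(engulf$M_W, params$E_prey, params$mu_prey)
  FE <- foraging_efficiency(E_gain, E_cost)

  FE_dive <- FE_day <- NA_real_
  ln_dive <- lunge$ln_dive %||% NA
  if (!is.na(ln_dive) && !is.na(lunge$dT_dive %||% NA)) {
    ts <- timescale_efficiency(
      E_gain, E_cost, morph$M_kg, lunge$dT_accel + lunge$dT_decel,
      ln_dive, lunge$dT_dive, params$ln_day[[morph$species]] %||% 300,
      params$f_Met, params
    )
    FE_dive <- ts$FE_dive
    FE_day <- ts$FE_day
  }
  data.frame(
    W_parasite = W_par, W_flukes = W_fl, W_VGB = W_vgb,
    E_accel = E_accel, E_decel = E_decel, cet_cost = cet,
    E_cost = E_cost, E_gain = E_gain, FE = FE,
    FE_dive = FE_dive, FE_day = FE_day,
    Re_MO = lunge$U_MO * morph$L_body / params$nu,
    U_mom = min_momentum_speed(morph$L_VGB, lunge$U_MO, lunge$U_MC,
                               lunge$dT_decel)
  )
}
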