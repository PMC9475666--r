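test_that("parasitic work matches an independent symbolic evaluation", {
  # dual-implementation oracle, frozen: 32.69637627 kJ for the reference
  # inputs below (flat-plate friction with form factor, verbatim)
  got <- parasitic_work(rho = 1025, S_wet = 50, w_max = 2.5, L_body = 12,
                        U_MO = 4, U_MC = 2, dT_accel = 8, nu = 1.05e-6)
  expect_equal(got, 32.69637627, tolerance = 1e-8)
  # strictly increasing in U_MO, all else fixed
  sweep <- vapply(seq(3, 6, by = 0.25), function(u) {
    parasitic_work(1025, 50, 2.5, 12, u, 2, 8)
  }, numeric(1))
  expect_true(all(diff(sweep) > 0))
  # continuous limit at U_MO == U_MC is finite and positive, and the
  # formula approaches it smoothly from in-domain
  lim <- parasitic_work(1025, 50, 2.5, 12, 4, 4, 8)
  near <- parasitic_work(1025, 50, 2.5, 12, 4, 4 - 1e-7, 8)
  expect_gt(lim, 0)
  expect_equal(near, lim, tolerance = 1e-5)
  # U_MC = 0 evaluated without error (U_MC^3.8 -> 0)
  expect_gt(parasitic_work(1025, 50, 2.5, 12, 4, 0, 8), 0)
  expect_error(parasitic_work(1025, -50, 2.5, 12, 4, 2, 8), "geometry")
})

test_that("fluke work combines kinetic, added-mass, and parasitic terms", {
  expect_equal(fluke_work(10000, 0, 4, 2, 0), 60)      # 1/2 M dU^2 in kJ
  expect_equal(fluke_work(10000, 0.03, 4, 2, 0), 61.8) # (1+k) scaling
  expect_equal(fluke_work(10000, 0.03, 3, 3, 0), 0)
  expect_equal(fluke_work(10000, 0, 4, 2, 5), 65)
  expect_error(fluke_work(10000, 0, 2, 4), "speeds")
})

test_that("VGB work cancels body mass at fixed engulfed mass", {
  expect_equal(vgb_work(10000, 5000, 4, 2), 30)
  expect_equal(vgb_work(20000, 5000, 4, 2), 30)  # algebraic cancellation
  expect_equal(vgb_work(10000, 5000, 4, 0), 0)
  expect_error(vgb_work(10000, 5000, 0, 1), "U_MO")
})

test_that("ceteral rate follows the Kleiber form and cost scales with time", {
  expect_equal(ceteral_rate(10000, f_Met = 1), 4100)   # 10000^0.75 = 1000
  expect_equal(ceteral_rate(10000, f_Met = 2), 8200)   # linear in f_Met
  expect_equal(ceteral_rate(16 * 10000, 1) / ceteral_rate(10000, 1), 8)
  expect_equal(ceteral_cost(10000, 1, dT_accel = 6, dT_decel = 4), 41)
  expect_equal(ceteral_cost(10000, 1, 0, 0), 0)
  expect_error(ceteral_rate(-1), "M_kg")
})

test_that("lunge cost honours both cost modes", {
  expect_equal(lunge_cost(100, 50, cost_mode = "averaged"), 225)
  expect_equal(lunge_cost(100, 50, cet = 30, cost_mode = "ceteral"), 180)
  expect_error(lunge_cost(100, 50, cost_mode = "ceteral"), "cet")
  expect_error(lunge_cost(100, 50, cost_mode = "nonsense"))
  # averaged identity holds to machine precision for arbitrary inputs
  set.seed(9)
  for (k in 1:20) {
    ea <- runif(1, 0, 5000); ed <- runif(1, 0, 5000)
    expect_equal(lunge_cost(ea, ed, cost_mode = "averaged"),
                 1.5 * (ea + ed), tolerance = 1e-15)
  }
  # efficiency chain: with defaults, E_accel = 5 x W_flukes
  p <- energetic_params()
  expect_equal(1 / (p$mu_prop * p$mu_met), 5)
})

test_that("energetic gain and prey-density calibration are inverse operations", {
  expect_equal(lunge_gain(1000, 3, 0.84), 2520)
  expect_equal(lunge_gain(1000, 0), 0)
  # calibrate from the minke reference row, then reproduce the other
  # species' printed mean gains within 0.5% from their volumes alone
  ref <- species_reference()
  E_prey <- calibrate_prey_density(ref$E_gain[ref$species == "minke"],
                                   ref$V_total[ref$species == "minke"])
  expect_equal(E_prey, 3.01118, tolerance = 1e-5)
  for (sp in c("humpback", "fin", "blue")) {
    r <- ref[ref$species == sp, ]
    pred <- lunge_gain(1025 * r$V_total, E_prey, 0.84)
    expect_lt(abs(pred - r$E_gain) / r$E_gain, 0.005)
  }
})

test_that("foraging efficiency and its timescale extrapolation are consistent", {
  expect_equal(foraging_efficiency(100, 100), 1)
  expect_equal(foraging_efficiency(2520, 225), 11.2)
  expect_equal(foraging_efficiency(0, 10), 0)
  expect_error(foraging_efficiency(1, 0), "E_cost")

  # zero excess (massless basal term) leaves FE unchanged under scaling
  ts0 <- timescale_efficiency(1000, 100, M_kg = 1e-9, dT_lunge = 20,
                              ln_dive = 5, dT_dive = 400, ln_day = 300)
  expect_equal(ts0$FE_dive, ts0$FE_lunge, tolerance = 1e-6)
  # positive excess strictly lowers the dive- and day-scale ratios
  ts <- timescale_efficiency(1000, 100, M_kg = 30000, dT_lunge = 20,
                             ln_dive = 5, dT_dive = 400, ln_day = 300)
  expect_lt(ts$FE_dive, ts$FE_lunge)
  expect_lt(ts$FE_day, ts$FE_dive)
  expect_error(timescale_efficiency(1, 1, 1000, 100, ln_dive = 5,
                                    dT_dive = 400, ln_day = 300),
               "shorter")
})

test_that("minimum momentum speed satisfies the stopping-distance identity", {
  expect_equal(min_momentum_speed(5, 4, 2, 2), sqrt(10))
  expect_equal(min_momentum_speed(5, 2, 2, 2), 0)
  # a body starting at U_mom under constant deceleration a stops after
  # exactly L_VGB metres: d = U^2 / (2a)
  set.seed(11)
  for (k in 1:25) {
    L <- runif(1, 1, 12)
    a <- runif(1, 0.1, 3)     # (U_MO - U_MC)/dT_decel
    U <- min_momentum_speed(L, 3 + a, 3, 1)
    expect_equal(U^2 / (2 * a), L, tolerance = 1e-12)
  }
  expect_error(min_momentum_speed(-1, 4, 2, 2), "L_VGB")
})

test_that("lunge_energetics assembles all terms with consistent units", {
  morph <- ref_morph("blue")
  lunge <- data.frame(U_MO = 4, U_MC = 1.7, U_max = 4.1, U_accel = 1.6,
                      dT_accel = 17, dT_decel = 4.2, ln_dive = 3,
                      dT_dive = 600)
  eng <- list(M_W = 80000)
  en <- lunge_energetics(lunge, eng, morph)
  expect_true(all(en[, c("W_parasite", "W_flukes", "W_VGB", "E_accel",
                         "E_decel", "cet_cost", "E_cost", "E_gain")] >= 0))
  expect_equal(en$FE, en$E_gain / en$E_cost)
  expect_equal(en$E_cost, en$E_accel + en$E_decel + en$cet_cost)
  expect_lt(en$FE_day, en$FE_dive)
  expect_lt(en$FE_dive, en$FE)
  # averaged mode applies the 1.5 factor row-wise
  en2 <- lunge_energetics(lunge, eng, morph,
                          energetic_params(cost_mode = "averaged"))
  expect_equal(en2$E_cost, 1.5 * (en2$E_accel + en2$E_decel))
  # alternative speed pair uses U_max / U_accel in the fluke term
  en3 <- lunge_energetics(lunge, eng, morph,
                          energetic_params(accel_speed_pair = "max_accel"))
  expect_false(isTRUE(all.equal(en3$W_flukes, en$W_flukes)))
})

test_that("cost rises and efficiency falls with lunging speed", {
  morph <- ref_morph("blue")
  speeds <- seq(3, 5.5, by = 0.25)
  out <- t(vapply(speeds, function(u) {
    lg <- data.frame(U_MO = u, U_MC = 1.7, dT_accel = 17, dT_decel = 4.2)
    en <- lunge_energetics(lg, list(M_W = 80000), morph)
    c(cost = en$E_cost, fe = en$FE)
  }, numeric(2)))
  expect_true(all(diff(out[, "cost"]) > 0))
  expect_true(all(diff(out[, "fe"]) < 0))
})
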