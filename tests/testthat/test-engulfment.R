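test_that("gape schedule opens, holds, and closes over thirds", {
  sched <- gape_schedule(3)
  expect_equal(gape_angle(0, sched), 0)
  expect_equal(gape_angle(3, sched), 0)                   # closes what it opens
  expect_equal(gape_angle(1.5, sched), 75 * pi / 180)     # 1.3090 rad plateau
  expect_equal(gape_angle(0.5, sched), 37.5 * pi / 180)   # half the opening third
  expect_equal(sched$rate_deg_s, 75)
  # symmetric: opening mirrors closing
  expect_equal(gape_angle(0.4, sched), gape_angle(2.6, sched))
  expect_error(gape_angle(3.5, sched), "t_rel")
  expect_error(gape_schedule(-1), "dT_decel")
})

test_that("projected area is A_jaw sin(G)", {
  expect_equal(projected_area(4, 0), 0)
  expect_equal(projected_area(4, pi / 2), 4)
  expect_equal(projected_area(4, 75 * pi / 180), 4 * sin(75 * pi / 180))
  expect_error(projected_area(-1, 0.3), "A_jaw")
  expect_error(projected_area(4, 2), "G_instant")
})

test_that("posterior volume matches an independent quadrature oracle", {
  # constant-speed case: U = 3, A_jaw = 4, dT_decel = 3, T_MG at half.
  # Oracle: 3*4*(int_0^1 sin(1.309 u) du + 0.5 sin 75deg), evaluated with
  # adaptive quadrature, frozen at 12.59020145 m^3.
  sched <- gape_schedule(3)
  oracle <- 12 * (integrate(function(u) sin(sched$max_gape_rad * u), 0, 1,
                            rel.tol = 1e-10)$value +
                    0.5 * sin(sched$max_gape_rad))
  expect_equal(oracle, 12.59020145, tolerance = 1e-8)
  t10 <- seq(0, 1.5, by = 1 / 1000)  # fine grid: trapezoid ~ exact
  v_fine <- posterior_volume(t10, rep(3, length(t10)), 4, sched)
  expect_equal(v_fine, oracle, tolerance = 1e-5)
  # 10 Hz grid within 0.5% of the oracle
  t1 <- seq(0, 1.5, by = 0.1)
  v10 <- posterior_volume(t1, rep(3, length(t1)), 4, sched)
  expect_lt(abs(v10 - oracle) / oracle, 0.005)
  # zero speed gives zero volume; <2 samples errors
  expect_equal(posterior_volume(t1, rep(0, length(t1)), 4, sched), 0)
  expect_error(posterior_volume(0, 3, 4, sched), "2 samples")
  # alternative endpoint integrates further, so is strictly larger
  v23 <- posterior_volume(seq(0, 2, by = 0.1), rep(3, 21), 4, sched,
                          vpos_end = "two_thirds")
  expect_gt(v23, v10)
})

test_that("grid refinement converges for smooth decelerating lunges", {
  set.seed(42)
  for (k in 1:10) {
    d <- runif(1, 2, 5)
    U0 <- runif(1, 3, 5); U1 <- runif(1, 1, U0 - 0.5)
    sched <- gape_schedule(d)
    sp <- function(t) U0 - (U0 - U1) * t / d
    t10 <- seq(0, d / 2, by = 0.1)
    t1k <- seq(0, d / 2, by = 0.001)
    v10 <- posterior_volume(t10, sp(t10), 5, sched)
    v1k <- posterior_volume(t1k, sp(t1k), 5, sched)
    expect_lt(abs(v10 - v1k) / v1k, 0.005)
  }
})

test_that("anterior volume follows the ellipsoid wedge formula", {
  expect_equal(anterior_volume(2, 3), 2 * pi * 2 * 9 / 3 * 75 / 360)
  expect_equal(anterior_volume(2, 3), 7.85398, tolerance = 1e-5)
  expect_equal(anterior_volume(2, 6), 4 * anterior_volume(2, 3)) # L_rbh^2 law
  expect_error(anterior_volume(0, 3), "W_bz")
})

test_that("engulfment drag and force residual follow the momentum balance", {
  expect_equal(engulfment_drag(1000, 2, 2), 1000)
  expect_equal(engulfment_drag(1000, 0, 2), 0)
  expect_equal(engulfment_drag(10000, 2, 2), 10 * engulfment_drag(1000, 2, 2))
  expect_error(engulfment_drag(1000, 2, 0), "dT_decel")

  fr <- force_residual(10000, 4, 2, 2, 10000)
  expect_equal(fr$residual, 0)
  expect_equal(fr$normalized, 0)
  fr2 <- force_residual(10000, 4, 2, 2, 8000)
  expect_equal(fr2$residual, 2000)
  expect_equal(fr2$normalized, 0.25)
  expect_true(is.na(force_residual(10000, 4, 2, 2, 0)$normalized))
  expect_error(force_residual(10000, 2, 2, 2, 100), "inclusion")
})

test_that("per-lunge engulfment preserves additivity and mass identities", {
  morph <- ref_morph("blue")
  d <- 4
  t <- seq(0, d, by = 0.1)
  sp <- 4 - 0.55 * t
  tr <- make_trace(sp)
  lunge <- data.frame(T_MO = 0, T_MC = d, U_MO = 4, U_MC = sp[length(sp)],
                      dT_decel = d)
  eng <- engulf_lunge(tr, lunge, morph)
  expect_equal(eng$V_total, eng$V_pos + eng$V_ant)          # exact additivity
  expect_equal(eng$M_W, 1025 * eng$V_total)                 # exact density
  expect_gte(eng$D_engulf, 0)
  expect_equal(eng$T_MG, d / 2)
  expect_equal(length(eng$A_proj), length(eng$G_instant))
  # rho is configurable and scales the mass exactly
  eng2 <- engulf_lunge(tr, lunge, morph, rho = 1000)
  expect_equal(eng2$M_W / eng$M_W, 1000 / 1025)
  expect_equal(eng2$V_total, eng$V_total)
})
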