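test_that("deployments are bit-reproducible under a fixed seed", {
  prof <- species_profile("minke")
  d1 <- simulate_deployment(prof, n_dives = 2, seed = 42)
  d2 <- simulate_deployment(prof, n_dives = 2, seed = 42)
  expect_identical(d1$trace$speed, d2$trace$speed)
  expect_identical(d1$trace$gyro_y, d2$trace$gyro_y)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_deployment(prof, n_dives = 2, seed = 43)
  expect_false(identical(d1$trace$speed, d3$trace$speed))
  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_deployment(prof, 1, seed = 9))
  expect_identical(runif(1), before)
})

test_that("injected ground truth satisfies every lunge-event invariant", {
  for (sp in c("minke", "blue")) {
    tr <- simulate_deployment(species_profile(sp), n_dives = 3,
                              seed = 17)$truth
    expect_gt(nrow(tr), 0)
    expect_true(all(tr$T_fluke <= tr$T_accel))
    expect_true(all(tr$T_accel < tr$T_max))
    expect_true(all(tr$T_max <= tr$T_MO))
    expect_true(all(tr$T_MO < tr$T_MC))
    expect_true(all(tr$T_MC <= tr$T_min))
    expect_true(all(tr$T_min - tr$T_MC <= 5))
    expect_true(all(tr$U_MO > tr$U_MC))
    expect_true(all(tr$dT_decel > 0))
    expect_true(all(tr$dT_adjust >= 0))
    expect_true(all(tr$dT_finOs > tr$dT_decel))  # oscillation spans decel
    expect_equal(tr$dT_accel, tr$T_max - tr$T_accel)
    expect_equal(tr$dT_decel, tr$T_MC - tr$T_MO)
    solitary <- tr$position_in_dive == "solitary"
    expect_true(all(table(tr$dive_id[!solitary]) >= 2))
  }
})

test_that("injected kinematics are calibrated to the species means", {
  # minke mouth-opening speed: mean of >= 100 injected draws within
  # 2 se of 4.57 m/s (sampling check on the generator itself)
  us <- unlist(lapply(1:5, function(s) {
    simulate_deployment(species_profile("minke"), n_dives = 6,
                        seed = 100 + s)$truth$U_MO
  }))
  expect_gte(length(us), 100)
  se <- 0.20 / sqrt(length(us))
  expect_lt(abs(mean(us) - 4.57), 2 * se + 1e-9)
})

test_that("zero-noise deployments are recovered within one sample interval", {
  prof <- species_profile("minke", noise_speed = 1e-6, noise_gyro = 1e-6,
                          noise_depth = 1e-6, noise_pitch = 1e-6)
  dep <- simulate_deployment(prof, n_dives = 2, seed = 5)
  ev <- detect_lunges(dep$trace)
  tr <- dep$truth
  expect_equal(nrow(ev), nrow(tr))
  for (i in seq_len(nrow(tr))) {
    j <- which.min(abs(ev$T_MO - tr$T_MO[i]))
    for (f in c("T_fluke", "T_accel", "T_max", "T_MO", "T_MC", "T_min")) {
      expect_lt(abs(ev[[f]][j] - tr[[f]][i]), 0.1)
    }
  }
})

test_that("cohorts derive distinct seeds and reproduce bit-exactly", {
  co <- simulate_cohort(c(minke = 2, blue = 2), n_dives = 1, seed = 8)
  expect_length(co, 4)
  seeds <- vapply(co, `[[`, numeric(1), "seed")
  expect_equal(anyDuplicated(seeds), 0L)
  expect_setequal(vapply(co, function(d) d$morph$species, character(1)),
                  c("minke", "blue"))
  co2 <- simulate_cohort(c(minke = 2, blue = 2), n_dives = 1, seed = 8)
  expect_identical(co[[1]]$trace$speed, co2[[1]]$trace$speed)
})

test_that("an injected adjustment plateau is recovered", {
  # fixed 1.6 s adjustment phase (sd = 0): recovered within 0.2 s
  prof <- species_profile("minke", dT_adjust_mean = 1.6, dT_adjust_sd = 0,
                          p_adjust = 1)
  dep <- simulate_deployment(prof, n_dives = 2, seed = 21)
  ev <- detect_lunges(dep$trace)
  tr <- dep$truth
  hits <- 0
  for (i in seq_len(nrow(tr))) {
    j <- which.min(abs(ev$T_MO - tr$T_MO[i]))
    if (length(j) && abs(ev$dT_adjust[j] - 1.6) <= 0.2) hits <- hits + 1
  }
  expect_gte(hits / nrow(tr), 0.8)
})
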