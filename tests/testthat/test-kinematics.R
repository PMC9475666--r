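test_that("detector recovers injected lunges and rejects degenerate traces", {
  dep <- simulate_deployment(species_profile("humpback"), n_dives = 3,
                             seed = 12)
  ev <- detect_lunges(dep$trace)
  tr <- dep$truth
  # every injected lunge detected with T_MO within 0.2 s; no extras
  expect_equal(nrow(ev), nrow(tr))
  for (i in seq_len(nrow(tr))) {
    expect_lt(min(abs(ev$T_MO - tr$T_MO[i])), 0.2)
  }
  # emitted events satisfy the ordering invariants
  expect_true(all(ev$T_fluke <= ev$T_accel & ev$T_accel < ev$T_max &
                    ev$T_max <= ev$T_MO & ev$T_MO < ev$T_MC &
                    ev$T_MC <= ev$T_min))
  expect_true(all(ev$U_MO > ev$U_MC))
  expect_true(all(ev$T_min - ev$T_MC <= 5 + 1e-9))
  # constant-speed trace yields an empty table
  flat <- make_trace(rep(2, 2000), depth = rep(40, 2000))
  expect_equal(nrow(detect_lunges(flat)), 0)
})

test_that("a speed rise during the engulfment window is not a lunge", {
  # accelerate, then keep accelerating (U_MO < U_MC pattern): no candidate
  # deceleration run exists, so the non-standard profile is rejected
  t <- seq(0, 120, by = 0.1)
  sp <- 1.5 + 2.5 * pmin(pmax((t - 60) / 10, 0), 1) +
    1.0 * pmin(pmax((t - 70) / 3, 0), 1)
  tr <- make_trace(sp + rnorm(length(t), 0, 0.05), depth = rep(40, length(t)))
  expect_equal(nrow(detect_lunges(tr)), 0)
})

test_that("phase segmentation matches injected durations", {
  dep <- simulate_deployment(species_profile("blue"), n_dives = 3, seed = 4)
  ev <- detect_lunges(dep$trace)
  tr <- dep$truth
  ok_d <- ok_f <- 0
  for (i in seq_len(nrow(tr))) {
    j <- which.min(abs(ev$T_MO - tr$T_MO[i]))
    if (!length(j)) next
    if (abs(ev$dT_decel[j] - tr$dT_decel[i]) <= 0.2) ok_d <- ok_d + 1
    if (is.finite(ev$dT_finOs[j]) &&
        abs(ev$dT_finOs[j] - tr$dT_finOs[i]) <= 0.2) ok_f <- ok_f + 1
  }
  expect_gte(ok_d / nrow(tr), 0.8)
  expect_gte(ok_f / nrow(tr), 0.8)
  # final oscillation spans intersect the deceleration and are longer
  fin_ok <- is.finite(ev$dT_finOs)
  expect_true(all(ev$T_gyr1[fin_ok] <= ev$T_MC[fin_ok]))
  expect_true(all(ev$T_gyr3[fin_ok] >= ev$T_MO[fin_ok]))
  expect_true(mean(ev$dT_finOs[fin_ok] > ev$dT_decel[fin_ok]) > 0.9)
})

test_that("deceleration distance integrates a linear ramp exactly", {
  # speed linear 4 -> 2 over [T_MO, T_MC] = 3 s: distance = 9 m
  t <- seq(0, 3, by = 0.1)
  td <- c(0, t, 3)
  sp <- 4 - (2 / 3) * t
  d <- sum(diff(t) * (head(sp, -1) + tail(sp, -1)) / 2)
  expect_equal(d, 9, tolerance = 1e-12)
  # and the detector's own column agrees with the trapezoid of the raw
  # speed on a synthetic lunge
  dep <- simulate_deployment(species_profile("fin"), n_dives = 1, seed = 2)
  ev <- detect_lunges(dep$trace)
  expect_gt(nrow(ev), 0)
  for (j in seq_len(nrow(ev))) {
    w <- dep$trace$t > ev$T_MO[j] & dep$trace$t < ev$T_MC[j]
    approx_d <- mean(dep$trace$speed[w]) * ev$dT_decel[j]
    expect_equal(ev$distance_decel[j], approx_d,
                 tolerance = 0.05)
  }
})

test_that("pure-noise gyro flags the final oscillation absent", {
  set.seed(30)
  n <- 600
  sp <- c(rep(2, 150), 2 + 0.25 * seq_len(100) / 10)
  sp <- c(sp, seq(4.5, 2, length.out = 30), seq(2, 1.6, length.out = 20),
          seq(1.6, 1.9, length.out = 15))
  sp <- c(sp, rep(1.9, n - length(sp)))
  tr <- make_trace(sp + rnorm(n, 0, 0.05), depth = rep(40, n),
                   gyro = rnorm(n, 0, 0.02))
  ev <- detect_lunges(tr)
  if (nrow(ev)) expect_true(all(is.na(ev$dT_finOs)))
})

test_that("middle-lunge sampling is seeded, capped, and excludes solitary", {
  ev <- empty_lunge_table()
  add <- function(dive, k) {
    data.frame(lunge_id = NA, dive_id = dive,
               position_in_dive = if (k == 1) "solitary" else
                 c("first", rep("middle", k - 2), "last"),
               T_MO = cumsum(rep(30, k)) + dive * 1000)
  }
  evs <- do.call(rbind, list(add(1, 12), add(2, 8), add(3, 1)))
  evs[setdiff(names(ev), names(evs))] <- NA_real_
  class(evs) <- c("lunge_table", "data.frame")

  s1 <- sample_middle_lunges(evs, n = 30, seed = 7)
  s2 <- sample_middle_lunges(evs, n = 30, seed = 7)
  expect_identical(s1, s2)                       # seeded determinism
  expect_equal(nrow(s1), 12 + 8 - 4)             # all middles when pool < n
  expect_true(all(s1$position_in_dive == "middle"))
  s3 <- sample_middle_lunges(evs, n = 5, seed = 1)
  expect_equal(nrow(s3), 5)
  # solitary lunges never sampled
  expect_false(any(s1$dive_id == 3))
  lone <- evs[evs$position_in_dive == "solitary", ]
  expect_warning(out <- sample_middle_lunges(lone, 5), "no middle")
  expect_equal(nrow(out), 0)
})

test_that("kinematic means stabilise with sample size", {
  dep <- simulate_deployment(species_profile("minke"), n_dives = 6, seed = 19)
  ev <- detect_lunges(dep$trace)
  tab <- sample_size_stability(ev, sizes = c(5, 9, 15), replicates = 60,
                               seed = 3)
  # between-replicate sd of the U_MO mean decreases with size
  sds <- tab$sd[tab$param == "U_MO"]
  expect_true(all(diff(sds) < 0))
  # fixed seed: identical table on re-run
  tab2 <- sample_size_stability(ev, sizes = c(5, 9, 15), replicates = 60,
                                seed = 3)
  expect_identical(tab, tab2)
  # replicates = 1: sd undefined
  tab3 <- sample_size_stability(ev, sizes = 5, replicates = 1, seed = 1)
  expect_true(all(is.na(tab3$sd)))
  # oversized request capped with a warning
  expect_warning(sample_size_stability(ev, sizes = 10000, replicates = 2,
                                       seed = 1), "capped")
})

test_that("tailbeat periods are extracted and end with the final oscillation", {
  dep <- simulate_deployment(species_profile("blue"), n_dives = 1, seed = 6)
  ev <- detect_lunges(dep$trace)
  expect_gt(nrow(ev), 0)
  tb <- tailbeat_periods(dep$trace, ev[1, ])
  expect_true(length(tb$periods) >= 1)
  expect_true(all(tb$periods > 0))
  if (is.finite(tb$final_period)) {
    expect_equal(tb$periods[length(tb$periods)], tb$final_period)
    # tailbeats are much shorter than the final oscillation
    expect_true(all(head(tb$periods, -1) < tb$final_period))
  }
})

test_that("masked gaps split the trace and suppress spanning detections", {
  dep <- simulate_deployment(species_profile("minke"), n_dives = 1, seed = 23)
  tr <- dep$trace
  ev0 <- detect_lunges(tr)
  expect_gt(nrow(ev0), 0)
  # mask 3 s straddling the first lunge's deceleration
  k <- which(tr$t >= ev0$T_MO[1] - 1 & tr$t <= ev0$T_MO[1] + 2)
  tr$speed[k] <- NA
  tr2 <- tag_trace(tr$t, tr$depth, tr$pitch, tr$speed, tr$gyro_y)
  ev1 <- detect_lunges(tr2)
  expect_equal(nrow(ev1), nrow(ev0) - 1)
})
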