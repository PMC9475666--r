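test_that("tag_trace validates its grid and flags gaps", {
  t <- seq(0, 10, by = 0.1)
  tr <- tag_trace(t, t * 0 + 5, t * 0, t * 0 + 2, t * 0)
  expect_s3_class(tr, "tag_trace")
  expect_equal(trace_dt(tr), 0.1)
  sp <- rep(2, length(t)); sp[5] <- NA
  tr2 <- tag_trace(t, t * 0 + 5, t * 0, sp, t * 0)
  expect_true(tr2$masked[5])
  expect_error(tag_trace(rev(t), t, t, t, t), "increasing")
  expect_error(tag_trace(c(0, 0.1, 0.25), 1:3, 1:3, 1:3, 1:3), "irregular")
  expect_error(tag_trace(t, t[-1], t * 0, t * 0, t * 0), "length")
})

test_that("orientation-corrected depth rate handles shallow pitch by exclusion", {
  expect_equal(speed_from_ocdr(2, pi / 2), 2)
  expect_equal(speed_from_ocdr(1, pi / 6), 2)
  expect_true(is.na(speed_from_ocdr(1, 0.01, min_pitch = 0.35)))
  expect_true(is.na(speed_from_ocdr(1, 0)))          # never divides by zero
  # vectorised with mixed validity; negative pitch gives signed estimate
  out <- speed_from_ocdr(c(1, 1, -1), c(pi / 6, 0.1, -pi / 6))
  expect_equal(out, c(2, NA, 2))
})

test_that("dives are contiguous deep spans bounded by surface samples", {
  depth <- c(rep(0.3, 20), rep(30, 50), rep(0.4, 10), rep(80, 40),
             rep(0.2, 10))
  tr <- make_trace(rep(2, length(depth)), depth = depth)
  d <- find_dives(tr)
  expect_equal(nrow(d), 2)
  expect_equal(d$max_depth, c(30, 80))
  expect_equal(d$i_start, c(21L, 81L))
  expect_equal(nrow(find_dives(make_trace(rep(2, 50), depth = rep(0.5, 50)))),
               0)
})

test_that("tag trace CSV reader validates, resamples, and round-trips", {
  dep <- simulate_deployment(species_profile("minke"), n_dives = 1, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_tag_trace(dep$trace, path)
  tr <- read_tag_trace(path)
  expect_equal(nrow(tr), nrow(dep$trace))
  expect_equal(tr$speed, dep$trace$speed, tolerance = 1e-8)

  # missing column named in the error
  df <- utils::read.csv(path, comment.char = "#")
  utils::write.csv(df[, setdiff(names(df), "gyro_y")], path,
                   row.names = FALSE)
  expect_error(read_tag_trace(path), "gyro_y")

  # 12.5 Hz input resampled to 10 Hz with a warning; a linear speed ramp
  # is preserved exactly by the linear-interpolation resampler
  t125 <- seq(0, 20, by = 0.08)
  df <- data.frame(t = t125, depth = 10, pitch = 0, speed = 1 + 0.2 * t125,
                   gyro_y = 0)
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(tr2 <- read_tag_trace(path), "resampling")
  expect_equal(trace_dt(tr2), 0.1)
  expect_equal(tr2$speed, 1 + 0.2 * tr2$t, tolerance = 1e-12)

  # non-monotone time rejected
  df$t[5] <- df$t[7]
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_tag_trace(path), "increasing")
})
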