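test_that("triangular jaw area matches the isosceles-triangle model", {
  expect_equal(jaw_area_triangular(2, 3, O_jaw = 1), 3)
  expect_equal(jaw_area_triangular(2, 3, O_jaw = 1.0514), 3.1542)
  # linear in each argument
  for (i in 1:5) {
    W <- runif(1, 0.5, 3); L <- runif(1, 1, 5); O <- runif(1, 1, 1.2)
    expect_equal(jaw_area_triangular(2 * W, L, O),
                 2 * jaw_area_triangular(W, L, O))
    expect_equal(jaw_area_triangular(W, 2 * L, O),
                 2 * jaw_area_triangular(W, L, O))
  }
  expect_error(jaw_area_triangular(0, 3), "W_bz")
  expect_error(jaw_area_triangular(2, -1), "L_rbh")
  expect_error(jaw_area_triangular(2, 3, O_jaw = 0.9), "O_jaw")
})

test_that("allometric_value is an exact power law", {
  expect_equal(allometric_value(10, c(a = 1, b = 2)), 100)
  expect_equal(allometric_value(10, c(a = 2.5, b = 3)), 2500)
  expect_equal(allometric_value(7, c(a = 3, b = 0)), 3)   # b = 0 reference
  expect_equal(allometric_value(7, c(a = 3, b = 1)), 21)  # b = 1 reference
  # log10 of the output is exactly linear in log10(L) with slope b
  co <- c(a = 0.37, b = 2.41)
  L <- c(2, 5, 11, 23)
  lg <- log10(allometric_value(L, co))
  fit <- lm(lg ~ log10(L))
  expect_equal(unname(coef(fit)[2]), 2.41, tolerance = 1e-12)
  expect_error(allometric_value(-1, co), "L_body")
  expect_error(allometric_value(10, NULL), "coefficients")
})

test_that("shipped allometry reproduces species-mean masses within 10%", {
  cfg <- default_allometry()
  ref <- species_reference()
  for (i in seq_len(nrow(ref))) {
    M <- allometric_value(ref$L_body[i], cfg$species[[ref$species[i]]]$mass)
    expect_lt(abs(M - ref$M_kg[i]) / ref$M_kg[i], 0.10)
  }
})

test_that("complete_morphometrics fills derived fields and records the jaw source", {
  m <- complete_morphometrics("id1", "minke", L_body = 7.6, w_max = 1.0,
                              W_bz = 1.10, L_rbh = 2.09, A_jaw_direct = 1.12)
  expect_false(is.na(m$A_jaw_model))
  expect_identical(m$jaw_area_method, "direct")
  expect_equal(m$A_jaw, 1.12)
  expect_true(all(c(m$M_kg, m$L_VGB, m$S_wet) > 0))
  # model preferred when direct absent
  m2 <- complete_morphometrics("id2", "minke", 7.6, W_bz = 1.1, L_rbh = 2.1)
  expect_identical(m2$jaw_area_method, "model")
  # direct only: model area absent
  m3 <- complete_morphometrics("id3", "minke", 7.6, A_jaw_direct = 1.0)
  expect_true(is.na(m3$A_jaw_model))
  expect_identical(m3$jaw_area_method, "direct")
  # override flag forces the model area
  m4 <- complete_morphometrics("id4", "minke", 7.6, W_bz = 1.1, L_rbh = 2.1,
                               A_jaw_direct = 1.0, prefer_direct = FALSE)
  expect_identical(m4$jaw_area_method, "model")
  # no jaw source at all
  expect_error(complete_morphometrics("id5", "minke", 7.6), "jaw-area")
  expect_error(complete_morphometrics("id6", "orca", 7.6, A_jaw_direct = 1),
               "species")
  expect_error(complete_morphometrics("id7", "minke", 7.6, W_bz = 9,
                                      L_rbh = 2), "W_bz")
})

test_that("morphometrics CSV round-trips", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "# units: m, m2",
    "individual_id,species,L_body,w_max,W_bz,L_rbh,A_jaw_direct",
    "mn1,humpback,11.4,1.65,1.63,3.93,4.02",
    "bw1,blue,22.3,2.9,2.9,5.14,"
  ), path)
  ms <- read_morphometrics(path)
  expect_named(ms, c("mn1", "bw1"))
  expect_equal(ms$mn1$A_jaw, 4.02)
  expect_identical(ms$bw1$jaw_area_method, "model")
  writeLines("individual_id,species", path)
  expect_error(read_morphometrics(path), "L_body")
})
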