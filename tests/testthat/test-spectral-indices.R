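test_that("band extraction interpolates linearly and refuses extrapolation", {
  s <- reflectance_spectrum(c(800, 810), c(0.5, 0.6))
  expect_equal(reflectance_at(s, 805), 0.55)
  s2 <- reflectance_spectrum(c(890, 900, 910), c(0.46, 0.47, 0.48))
  expect_equal(reflectance_at(s2, 900), 0.47)
  s3 <- reflectance_spectrum(seq(400, 1100, by = 10), rep(0.5, 71))
  expect_error(reflectance_at(s3, 350), "outside")

  set.seed(3)
  for (i in 1:10) {
    wl <- sort(runif(50, 400, 1100)); wl <- wl[!duplicated(wl)]
    r <- runif(length(wl))
    s <- reflectance_spectrum(wl, r)
    lam <- runif(20, min(wl), max(wl))
    expect_equal(reflectance_at(s, lam), interp_oracle(wl, r, lam),
                 tolerance = 1e-12)
  }
})

test_that("water and vegetation indices follow their band-ratio definitions", {
  flat <- reflectance_spectrum(seq(400, 1700, by = 50), rep(0.4, 27))
  expect_equal(water_index(flat), 1)
  expect_equal(water_index_swir(flat), 1)
  expect_equal(delta_r(flat), 0)
  expect_equal(ndvi(flat), 0)

  s <- spectrum_with(c(`900` = 0.45, `970` = 0.436))
  expect_equal(water_index(s), 0.45 / 0.436)
  expect_equal(water_index(spectrum_with(c(`900` = 0.40, `970` = 0.50))), 0.8)

  expect_equal(water_index_swir(spectrum_with(c(`1000` = 0.60, `1450` = 0.20))), 3)
  expect_equal(water_index_swir(spectrum_with(c(`1000` = 0.60, `1450` = 0.40))), 1.5)

  expect_equal(delta_r(spectrum_with(c(`800` = 0.5, `1100` = 0.4))), 0.2)
  expect_equal(delta_r(spectrum_with(c(`800` = 0.4, `1100` = 0.5))), -0.25)

  expect_equal(ndvi(spectrum_with(c(`630` = 0.05, `780` = 0.5))), 0.45 / 0.55)
  expect_equal(ndvi(spectrum_with(c(`630` = 0, `780` = 0.5))), 1)
})

test_that("indices are invariant to uniform reflectance scaling", {
  set.seed(5)
  wl <- seq(400, 1700, by = 10)
  for (i in 1:10) {
    r <- runif(length(wl), 0.2, 0.9)
    s1 <- reflectance_spectrum(wl, r)
    c <- runif(1, 0.1, 1.1)
    s2 <- reflectance_spectrum(wl, pmin(c * r, 1))
    if (any(c * r > 1)) next
    expect_equal(water_index(s2), water_index(s1), tolerance = 1e-12)
    expect_equal(water_index_swir(s2), water_index_swir(s1), tolerance = 1e-12)
    expect_equal(delta_r(s2), delta_r(s1), tolerance = 1e-12)
    expect_equal(ndvi(s2), ndvi(s1), tolerance = 1e-12)
  }
})

test_that("NDVI stays in [-1, 1] and dR below 1 on random spectra", {
  set.seed(9)
  wl <- seq(400, 1200, by = 5)
  for (i in 1:50) {
    s <- reflectance_spectrum(wl, runif(length(wl), 0.01, 1))
    v <- ndvi(s)
    expect_gte(v, -1); expect_lte(v, 1)
    expect_lt(delta_r(s), 1)
  }
})

test_that("deepening a water-absorption trough raises the matching index", {
  wl <- seq(400, 1700, by = 2)
  base <- rep(0.5, length(wl))
  wi <- wis <- numeric(0)
  for (depth in seq(0, 0.3, by = 0.05)) {
    r <- base - depth * exp(-(wl - 970)^2 / (2 * 25^2)) -
      depth * exp(-(wl - 1450)^2 / (2 * 40^2))
    s <- reflectance_spectrum(wl, r)
    wi <- c(wi, water_index(s)); wis <- c(wis, water_index_swir(s))
  }
  expect_true(all(diff(wi) > 0))
  expect_true(all(diff(wis) > 0))
})

test_that("batch index computation skips bands the spectrum cannot cover", {
  vnir <- reflectance_spectrum(seq(400, 1100, by = 10), rep(0.5, 71))
  suppressMessages(got <- compute_indices(vnir))
  expect_setequal(got$name, c("WI", "dR", "NDVI"))

  swir <- reflectance_spectrum(seq(1000, 1700, by = 10), rep(0.5, 71))
  suppressMessages(got2 <- compute_indices(swir))
  expect_equal(got2$name, "WI_SWIR")

  full <- reflectance_spectrum(seq(400, 1700, by = 10), rep(0.5, 131))
  expect_setequal(compute_indices(full)$name, c("WI", "WI_SWIR", "dR", "NDVI"))
})

test_that("percent-scaled reflectance files are auto-detected", {
  expect_message(s <- reflectance_spectrum(c(800, 900), c(45, 50)), "percent")
  expect_equal(s$reflectance, c(0.45, 0.50))
})
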