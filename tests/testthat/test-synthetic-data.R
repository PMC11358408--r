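test_that("the drying curve is exponential toward its floor", {
  p <- default_profile("barley")
  expect_equal(drying_curve(0, p), 100)
  expect_equal(drying_curve(1e6, p), p$rwc_floor, tolerance = 1e-6)
  p10 <- species_profile("x", drying_tau_h = 10, rwc_floor = 0,
                         shrinkage_at_50 = 0.1, dry_matter_fraction = 0.1,
                         calibration = lmd_rwc_calibration(-1, 100),
                         response_models = list(
                           p = response_model("constant", value = 1)))
  expect_equal(drying_curve(10, p10), 100 * exp(-1), tolerance = 1e-9)
  t <- seq(0, 100, by = 0.5)
  expect_true(all(diff(drying_curve(t, p)) < 0))
})

test_that("response shapes behave as specified on dense grids", {
  lin <- response_model("linear", intercept = 0, slope = 0.01)
  expect_equal(expected_response(lin, 50), 0.5)

  od <- response_model("onset_decline", plateau = 1.03, onset = 60,
                       slope = 0.002)
  expect_equal(expected_response(od, 80), 1.03)
  grid <- seq(0, 100, by = 0.1)
  v <- expected_response(od, grid)
  expect_true(all(v[grid >= 60] == 1.03))
  below <- v[grid < 60]
  expect_true(all(diff(below) > 0)) # rises toward the onset plateau

  bi <- response_model("biphasic", baseline = 1, height = 0.5, peak = 70,
                       width = 15)
  expect_equal(expected_response(bi, 70), 1.5)
  vb <- expected_response(bi, grid)
  peak_idx <- which.max(vb)
  expect_equal(grid[peak_idx], 70)
  expect_true(all(diff(vb[grid <= 70]) > 0))
  expect_true(all(diff(vb[grid >= 70]) < 0))

  expect_error(response_model("biphasic", baseline = 1, height = 1, peak = 70),
               "width")
  expect_error(expected_response(lin, 150), "110")
})

test_that("identical seed and configuration give identical datasets", {
  d1 <- simulate_dataset(n_per_species = 10, seed = 99)
  d2 <- simulate_dataset(n_per_species = 10, seed = 99)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(n_per_species = 10, seed = 100)
  expect_false(identical(d1$samples, d3$samples))
})

test_that("generated masses are internally consistent with the water formulas", {
  d <- simulate_dataset(n_per_species = 25, seed = 4)
  s <- d$samples
  cals <- default_calibrations()
  for (sp in unique(s$species)) {
    ss <- s[s$species == sp, ]
    rwc_cal <- suppressWarnings(
      apply_calibration(cals[[sp]], compute_lmd(ss$m_f, ss$m_a)))
    rwc_direct <- suppressWarnings(
      compute_rwc_direct(ss$m_a, ss$m_d, ss$m_t))
    # both routes agree with the series RWC up to calibration truncation
    ser <- d$series[d$series$species == sp & d$series$parameter == "psi_psy", ]
    expect_equal(rwc_cal, ser$rwc, tolerance = 1e-9)
    expect_true(all(abs(rwc_direct - rwc_cal) < 2.5))
    expect_true(all(ss$m_a <= ss$m_f + 1e-9))
    expect_true(all(ss$m_d < ss$m_a))
    expect_true(all(compute_ewt(ss$m_a, ss$m_d, ss$area_cm2) > 0))
  }
  expect_setequal(unique(s$species), c("tobacco", "barley"))
  expect_equal(nrow(s), 50)
})

test_that("a noiseless linear response is recovered exactly by the pipeline", {
  prof <- species_profile(
    "clean", drying_tau_h = 10, rwc_floor = 0, shrinkage_at_50 = 0.1,
    dry_matter_fraction = 0.1,
    calibration = lmd_rwc_calibration(-1, 100),
    response_models = list(
      lin = response_model("linear", intercept = 0.2, slope = 0.004,
                           noise_sd = 0, leaf_effect_sd = 0)))
  d <- simulate_dataset(profiles = list(prof), n_per_species = 20, seed = 8)
  r <- compute_coefficients(d$series$rwc, d$series$value)
  expect_equal(r$b, 0.004, tolerance = 1e-9)
  expect_equal(r$a, 0.2, tolerance = 1e-7)
  expect_true(is.infinite(r$CR))
})

test_that("synthetic spectra encode the water-content phenomenology", {
  tb <- default_profile("tobacco"); br <- default_profile("barley")
  wi_b100 <- water_index(simulate_spectrum(100, br))
  wi_b50 <- water_index(simulate_spectrum(50, br))
  expect_lt(wi_b50, wi_b100)
  expect_lt(water_index_swir(simulate_spectrum(50, br)),
            water_index_swir(simulate_spectrum(100, br)))
  # stronger shrinkage slows the EWT decline, muting the WI response
  wi_t100 <- water_index(simulate_spectrum(100, tb))
  wi_t50 <- water_index(simulate_spectrum(50, tb))
  expect_lt(abs(wi_t100 - wi_t50), abs(wi_b100 - wi_b50))
  # no water, no trough: WI near the baseline ratio of 1
  dry <- species_profile("dry", drying_tau_h = 5, rwc_floor = 0,
                         shrinkage_at_50 = 0, dry_matter_fraction = 0.1,
                         calibration = lmd_rwc_calibration(-1, 100),
                         response_models = list(
                           p = response_model("constant", value = 1)))
  expect_equal(water_index(simulate_spectrum(0, dry)), 1, tolerance = 0.01)
  # determinism under a seed, variation without
  s1 <- simulate_spectrum(70, br, seed = 5, noise_sd = 0.002)
  s2 <- simulate_spectrum(70, br, seed = 5, noise_sd = 0.002)
  expect_identical(s1$reflectance, s2$reflectance)
})

test_that("theoretical CR matches the closed form for linear models", {
  m <- response_model("linear", intercept = 1, slope = 0.004,
                      noise_sd = 0.02, leaf_effect_sd = 0)
  th <- theoretical_coefficients(m)
  expect_equal(th$CR_theory, 0.004 * 10 / (0.02 * sqrt(2 / pi)),
               tolerance = 1e-9)
  expect_equal(th$slope_window, 0.004, tolerance = 1e-12)
})
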