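# frozen values for the 6-point worked series, computed once from the
# normal-equations oracle in helper-oracles.R
wx <- c(50, 60, 70, 80, 90, 100)
wy <- c(10, 12, 13, 16, 17, 20)

test_that("the linear fit matches the normal-equations oracle", {
  f <- fit_linear(wx, wy)
  expect_equal(f$a, 0.0952380952381, tolerance = 1e-9)
  expect_equal(f$b, 0.1942857142857, tolerance = 1e-9)
  expect_equal(f$r2, 0.981046676096, tolerance = 1e-9)

  exact <- fit_linear(wx, 2 + 0.1 * wx)
  expect_equal(exact$a, 2, tolerance = 1e-12)
  expect_equal(exact$b, 0.1, tolerance = 1e-12)
  expect_equal(exact$r2, 1, tolerance = 1e-12)

  set.seed(13)
  for (i in 1:20) {
    n <- sample(3:20, 1)
    x <- runif(n, 0, 100); y <- rnorm(n, 5 + 0.2 * x, 2)
    f <- fit_linear(x, y); o <- ols_oracle(x, y)
    expect_equal(f$a, o$a, tolerance = 1e-9)
    expect_equal(f$b, o$b, tolerance = 1e-9)
    expect_equal(f$r2, o$r2, tolerance = 1e-9)
  }

  const <- fit_linear(wx, rep(3, 6))
  expect_equal(const$b, 0, tolerance = 1e-12)
  expect_equal(const$r2, 1)
  expect_error(fit_linear(rep(70, 4), 1:4), "degenerate")
})

test_that("mean absolute deviation is the mean absolute residual", {
  f <- fit_linear(wx, wy)
  expect_equal(mean_abs_deviation(wx, wy, f), 0.425396825397, tolerance = 1e-9)
  exact <- fit_linear(wx, 2 + 0.1 * wx)
  expect_equal(mean_abs_deviation(wx, 2 + 0.1 * wx, exact), 0, tolerance = 1e-12)
  expect_equal(mean_abs_deviation(c(0, 1), c(1, -1), list(a = 0, b = 0)), 1)
})

test_that("windowing keeps the closed RWC interval", {
  w <- select_window(c(100, 75, 50, 25, 5), 1:5)
  expect_equal(w$rwc, c(100, 75, 50))
  w2 <- select_window(c(90, 60, 55), 1:3)
  expect_equal(w2$value, 1:3)
  w3 <- select_window(c(90, 60, 55, 20), 1:4, lo = 0, hi = 100)
  expect_equal(w3$value, 1:4)
})

test_that("coefficients reproduce the worked series and their identity", {
  r <- compute_coefficients(wx, wy, delta_s = 10, parameter = "demo")
  expect_equal(r$CR, 4.5671641791, tolerance = 1e-6)
  expect_equal(r$CS, 1.32467532468, tolerance = 1e-6)
  expect_equal(r$CI, 2.90043290043, tolerance = 1e-6)
  expect_equal(r$y_bar, mean(wy))
  expect_equal(r$CR, r$delta_s * r$CS / r$CI, tolerance = 1e-9)
  expect_true(r$reliable)

  perfect <- compute_coefficients(wx, 2 + 0.1 * wx)
  expect_true(is.infinite(perfect$CR))
  expect_true(perfect$perfect_fit)

  set.seed(17)
  noise <- compute_coefficients(runif(200, 50, 100), rnorm(200))
  expect_lt(noise$CR, 0.4)
  expect_false(noise$reliable)

  expect_error(compute_coefficients(c(60, 70), c(1, 2)), "insufficient")
  expect_error(compute_coefficients(c(60, 60, 60), c(1, 2, 3)), "degenerate")
})

test_that("CR is scale-free in y; CS and CI are scale- but not shift-free", {
  set.seed(19)
  x <- runif(30, 50, 100)
  y <- 2 + 0.05 * x + rnorm(30, 0, 0.3)
  base <- compute_coefficients(x, y)
  scaled <- compute_coefficients(x, 7 * y)
  expect_equal(scaled$CR, base$CR, tolerance = 1e-9)
  expect_equal(scaled$CS, base$CS, tolerance = 1e-9)
  expect_equal(scaled$CI, base$CI, tolerance = 1e-9)
  shifted <- compute_coefficients(x, y + 50)
  expect_equal(shifted$CR, base$CR, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(shifted$CS, base$CS)))
  expect_false(isTRUE(all.equal(shifted$CI, base$CI)))
})

test_that("CR does not depend on percent vs fractional RWC scaling", {
  set.seed(23)
  x <- runif(25, 50, 100)
  y <- 1 + 0.02 * x + rnorm(25, 0, 0.1)
  pct <- compute_coefficients(x, y, delta_s = 10, window = c(50, 100))
  frac <- compute_coefficients(x / 100, y, delta_s = 0.1, window = c(0.5, 1))
  expect_equal(frac$CR, pct$CR, tolerance = 1e-9)
})

test_that("ranking sorts by coefficient with ties flagged and Inf first", {
  res <- data.frame(parameter = c("a", "b", "c"), species = "s",
                    CR = c(2.5, 1.2, 0.1), CS = 1, CI = 1, r2 = 1, n = 10,
                    group = NA, reliable = c(TRUE, TRUE, FALSE))
  rk <- rank_parameters(res)
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$parameter, c("a", "b", "c"))
  expect_false(any(rk$tie))

  res$CR <- c(1.2, 1.2, Inf)
  expect_warning(rk2 <- rank_parameters(res), "ties")
  expect_equal(rk2$parameter[1], "c")
  expect_true(all(rk2$tie[2:3]))

  res3 <- data.frame(parameter = c("hi", "lo"), species = "s",
                     CR = c(0.5, 0.3), CS = 1, CI = 1, r2 = 1, n = 10,
                     group = NA, reliable = c(TRUE, FALSE))
  expect_equal(rank_parameters(res3)$reliable, c(TRUE, FALSE))
})

test_that("group rank sums aggregate ranks and average coefficients", {
  res <- data.frame(
    parameter = c("NPQ_1", "PhiPSII_st", "FvFm", "NPQ_st"),
    species = "tobacco", group = "chl_fluorescence",
    CR = c(1.2032, 1.1858, 0.6686, 0.4870),
    CS = c(2, 1.5, 1, 0.5), CI = c(4, 3, 2, 1), r2 = 0.5, n = 20,
    reliable = TRUE, stringsAsFactors = FALSE)
  g <- group_rank_sums(res)
  cr_row <- g[g$coefficient == "CR", ]
  expect_equal(cr_row$rank_sum, sum(1:4))
  expect_equal(cr_row$mean_value, 0.88615, tolerance = 1e-9)

  res2 <- data.frame(parameter = letters[1:4], species = "s",
                     group = rep(c("g1", "g2"), each = 2),
                     CR = c(4, 3, 2, 1), CS = c(4, 3, 2, 1),
                     CI = c(4, 3, 2, 1), r2 = 1, n = 10, reliable = TRUE)
  g2 <- group_rank_sums(res2, coefficients = "CR")
  expect_equal(g2$rank_sum[g2$group == "g1"], 3)
  expect_equal(g2$rank_sum[g2$group == "g2"], 7)

  res2$group[2] <- NA
  expect_error(group_rank_sums(res2), "without a group")
})

test_that("coefficient correlations use OLS r2 with finite pairs only", {
  res <- data.frame(CR = seq(0.2, 2, length.out = 10))
  res$CS <- 2 * res$CR
  expect_equal(correlate_coefficients(res, "CR", "CS"), 1, tolerance = 1e-12)

  set.seed(29)
  ind <- data.frame(CR = rnorm(1000), CS = rnorm(1000))
  expect_lt(correlate_coefficients(ind, "CR", "CS"), 0.01)

  const <- data.frame(CR = 1:5, CS = rep(2, 5))
  expect_equal(correlate_coefficients(const, "CR", "CS"), 0)

  withinf <- data.frame(CR = c(1, 2, 3, Inf), CS = c(2, 4, 6, 8))
  expect_message(r2 <- correlate_coefficients(withinf, "CR", "CS"), "excluded")
  expect_equal(r2, 1, tolerance = 1e-12)
  expect_error(correlate_coefficients(withinf[3:4, ], "CR", "CS"),
               "insufficient")
})

test_that("expected CR falls with noise and rises with slope", {
  set.seed(31)
  x <- runif(2000, 50, 100)
  cr_by_sigma <- vapply(c(0.01, 0.02, 0.04), function(s)
    compute_coefficients(x, 1 + 0.004 * x + rnorm(2000, 0, s))$CR, numeric(1))
  expect_true(all(diff(cr_by_sigma) < 0))
  cr_by_slope <- vapply(c(0.002, 0.004, 0.008), function(b)
    compute_coefficients(x, 1 + b * x + rnorm(2000, 0, 0.02))$CR, numeric(1))
  expect_true(all(diff(cr_by_slope) > 0))
})
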