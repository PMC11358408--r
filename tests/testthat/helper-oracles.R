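# Independent oracles the test suite checks the implementation against.
# These deliberately avoid the code paths they verify.

# closed-form normal-equations OLS
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- sy / n - b * sx / n
  res <- y - (a + b * x)
  ss_tot <- sum((y - sy / n)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(res^2) / ss_tot
  list(a = a, b = b, r2 = r2)
}

# brute-force piecewise-linear interpolation by explicit bracketing
interp_oracle <- function(wl, r, lam) {
  vapply(lam, function(l) {
    if (l < wl[1] || l > wl[length(wl)]) stop("out of range")
    i <- max(which(wl <= l))
    if (wl[i] == l) return(r[i])
    w <- (l - wl[i]) / (wl[i + 1] - wl[i])
    (1 - w) * r[i] + w * r[i + 1]
  }, numeric(1))
}

# a spectrum with exact reflectance values at chosen wavelengths,
# linearly bridged in between
spectrum_with <- function(bands, ...) {
  reflectance_spectrum(as.numeric(names(bands)), as.numeric(bands), ...)
}

# battery of linear response parameters with prescribed theoretical CRs
# (same slope, noise chosen so CR_k = b * delta_s / (sigma_k * sqrt(2/pi)))
cr_battery <- function(cr_targets, b = 0.01, delta_s = 10) {
  sigma <- b * delta_s / (cr_targets * sqrt(2 / pi))
  data.frame(parameter = sprintf("p%02d", seq_along(cr_targets)),
             b = b, sigma = sigma, cr_theory = cr_targets,
             stringsAsFactors = FALSE)
}

# simulate one battery replicate and return the estimated CR per parameter
simulate_battery_cr <- function(battery, n = 40, window = c(50, 100)) {
  vapply(seq_len(nrow(battery)), function(k) {
    x <- runif(n, window[1], window[2])
    y <- 1 + battery$b[k] * x + rnorm(n, 0, battery$sigma[k])
    compute_coefficients(x, y, parameter = battery$parameter[k])$CR
  }, numeric(1))
}
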