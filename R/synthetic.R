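#' Response-shape model of a monitored parameter vs. RWC
#'
#' The shape library of the synthetic generator, covering the response
#' phenomenology seen in desiccating leaves:
#' * `linear` — steady rise or decline with RWC (water potential,
#'   NPQ_1-like);
#' * `onset_decline` — flat plateau down to an onset RWC, then linear
#'   decline (water indices that only move once the leaf is quite dry);
#' * `biphasic` — baseline plus a Gaussian bump peaking at an interior
#'   RWC (NPQ at steady state, which rises then falls);
#' * `logistic_decline` — smooth sigmoidal drop between an upper and a
#'   lower level (quantum-yield parameters);
#' * `constant` — no true response, scatter only.
#'
#' Noise has two components: a leaf-to-leaf random intercept
#' (`leaf_effect_sd`) and independent measurement noise (`noise_sd`),
#' both additive Gaussian in the parameter's own units.
#'
#' @param kind One of `"linear"`, `"onset_decline"`, `"biphasic"`,
#'   `"logistic_decline"`, `"constant"`.
#' @param ... Kind-specific parameters: linear `intercept`, `slope`;
#'   onset_decline `plateau`, `onset` (% RWC), `slope`; biphasic
#'   `baseline`, `height`, `peak` (% RWC), `width` (% RWC);
#'   logistic_decline `upper`, `lower`, `midpoint` (% RWC),
#'   `steepness`; constant `value`.
#' @param noise_sd Measurement noise SD, parameter units (>= 0).
#' @param leaf_effect_sd Leaf-to-leaf SD, parameter units (>= 0).
#' @return An object of class `response_model`.
#' @export
response_model <- function(kind = c("linear", "onset_decline", "biphasic",
                                    "logistic_decline", "constant"),
                           ..., noise_sd = 0, leaf_effect_sd = 0) {
  kind <- match.arg(kind)
  stopifnot(noise_sd >= 0, leaf_effect_sd >= 0)
  params <- list(...)
  need <- switch(kind,
    linear = c("intercept", "slope"),
    onset_decline = c("plateau", "onset", "slope"),
    biphasic = c("baseline", "height", "peak", "width"),
    logistic_decline = c("upper", "lower", "midpoint", "steepness"),
    constant = "value")
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop(sprintf("response_model('%s') needs parameter(s): %s",
                 kind, paste(missing, collapse = ", ")), call. = FALSE)
  if (kind %in% c("onset_decline", "biphasic")) {
    at <- if (kind == "onset_decline") params$onset else params$peak
    if (at <= 0 || at > 100)
      stop("onset/peak RWC must lie in (0, 100]", call. = FALSE)
  }
  if (kind == "biphasic" && params$width <= 0)
    stop("biphasic width must be positive", call. = FALSE)
  structure(list(kind = kind, params = params,
                 noise_sd = noise_sd, leaf_effect_sd = leaf_effect_sd),
            class = "response_model")
}

#' Deterministic mean response of a model at given RWC
#'
#' @param model A [response_model()].
#' @param rwc RWC values, percent, in `[0, 110]`. Vectorized.
#' @return Mean parameter value(s), without noise.
#' @export
expected_response <- function(model, rwc) {
  stopifnot(inherits(model, "response_model"), is.numeric(rwc))
  if (any(rwc < 0 | rwc > 110, na.rm = TRUE))
    stop("rwc outside [0, 110]", call. = FALSE)
  p <- model$params
  switch(model$kind,
    linear = p$intercept + p$slope * rwc,
    onset_decline = ifelse(rwc >= p$onset, p$plateau,
                           p$plateau - p$slope * (p$onset - rwc)),
    biphasic = p$baseline + p$height * exp(-(rwc - p$peak)^2 / (2 * p$width^2)),
    logistic_decline = p$lower + (p$upper - p$lower) /
      (1 + exp(-p$steepness * (rwc - p$midpoint))),
    constant = rep(p$value, length(rwc)))
}

#' Construct a species drying/response profile
#'
#' Everything the generator needs about one species: drying kinetics,
#' shrinkage, dry-matter fraction, the ground-truth LMD-to-RWC
#' calibration, and the per-parameter response models.
#'
#' @param name Species label.
#' @param drying_tau_h Time constant of the exponential RWC decline, h.
#' @param rwc_floor Asymptotic RWC as the leaf air-dries, percent.
#' @param shrinkage_at_50 Fractional leaf-area loss when RWC reaches
#'   50%, in `[0, 1)` (strongly shrinking dicot leaves ~0.3; rigid
#'   parallel-veined monocot leaves ~0.08).
#' @param dry_matter_fraction Dry mass / fresh mass, in (0, 1).
#' @param calibration An [lmd_rwc_calibration()]: the profile's
#'   ground-truth LMD-to-RWC line.
#' @param response_models Named list of [response_model()]s, one per
#'   monitored parameter.
#' @param groups Optional named character vector mapping parameter names
#'   to reliability groups.
#' @param mean_fresh_mass_mg,mean_fresh_area_cm2 Typical fresh sample
#'   mass and area used to draw per-sample sizes.
#' @return An object of class `species_profile`.
#' @export
species_profile <- function(name, drying_tau_h, rwc_floor = 0,
                            shrinkage_at_50, dry_matter_fraction,
                            calibration, response_models,
                            groups = NULL,
                            mean_fresh_mass_mg = 400,
                            mean_fresh_area_cm2 = 10) {
  stopifnot(is.character(name), drying_tau_h > 0,
            rwc_floor >= 0, rwc_floor < 100,
            shrinkage_at_50 >= 0, shrinkage_at_50 < 1,
            dry_matter_fraction > 0, dry_matter_fraction < 1,
            inherits(calibration, "lmd_rwc_calibration"),
            is.list(response_models), length(response_models) >= 1L,
            !is.null(names(response_models)))
  stopifnot(all(vapply(response_models, inherits, TRUE, "response_model")))
  structure(list(name = name, drying_tau_h = drying_tau_h,
                 rwc_floor = rwc_floor, shrinkage_at_50 = shrinkage_at_50,
                 dry_matter_fraction = dry_matter_fraction,
                 calibration = calibration,
                 response_models = response_models,
                 groups = groups,
                 mean_fresh_mass_mg = mean_fresh_mass_mg,
                 mean_fresh_area_cm2 = mean_fresh_area_cm2),
            class = "species_profile")
}

#' RWC of a detached leaf after t hours of drying
#'
#' Exponential decline toward an asymptotic floor:
#' `RWC(t) = floor + (100 - floor) * exp(-t / tau)`; strictly decreasing
#' in time, 100 at detachment.
#'
#' @param t_h Hours since detachment, >= 0. Vectorized.
#' @param profile A [species_profile()].
#' @return RWC, percent.
#' @export
drying_curve <- function(t_h, profile) {
  stopifnot(inherits(profile, "species_profile"), is.numeric(t_h))
  if (any(t_h < 0, na.rm = TRUE)) stop("t_h must be >= 0", call. = FALSE)
  profile$rwc_floor +
    (100 - profile$rwc_floor) * exp(-t_h / profile$drying_tau_h)
}

# fractional area loss at a given RWC, linear in (100 - rwc), anchored so
# that shrinkage_at_50 is reached at RWC = 50, capped below 1
shrinkage_at <- function(profile, rwc) {
  pmin(profile$shrinkage_at_50 * (100 - rwc) / 50, 0.95)
}

# relative equivalent water thickness: water mass falls with RWC while the
# area shrinks, so strong shrinkage slows the EWT decline
ewt_relative <- function(profile, rwc) {
  (rwc / 100) / (1 - shrinkage_at(profile, rwc))
}

#' Built-in illustrative species profiles
#'
#' Two contrasting profiles used throughout the examples and tests: a
#' slowly drying, strongly shrinking whole-leaf dicot (`"tobacco"`-like,
#' tau = 48 h, 30% area loss at RWC 50%) and a fast-drying, weakly
#' shrinking monocot leaf segment (`"barley"`-like, tau = 6 h, 8% area
#' loss). Response-model parameter values are illustrative defaults that
#' reproduce the qualitative response shapes of desiccating leaves
#' (plateaued water indices in the shrinking species, rising NDVI under
#' shrinkage, biphasic steady-state NPQ, weak FvFm response); they are
#' not fitted to any instrument dataset.
#'
#' @param name `"tobacco"` or `"barley"`.
#' @return A [species_profile()].
#' @export
default_profile <- function(name = c("tobacco", "barley")) {
  name <- match.arg(name)
  cal <- default_calibrations()[[name]]
  if (name == "tobacco") {
    models <- list(
      psi_psy = response_model("linear", intercept = -4.4, slope = 0.040,
                               noise_sd = 0.12, leaf_effect_sd = 0.08),
      psi_press = response_model("linear", intercept = -4.0, slope = 0.036,
                                 noise_sd = 0.25, leaf_effect_sd = 0.15),
      WI_D = response_model("onset_decline", plateau = 1.03, onset = 40,
                            slope = 0.0008, noise_sd = 0.004,
                            leaf_effect_sd = 0.003),
      WI_B = response_model("onset_decline", plateau = 1.04, onset = 40,
                            slope = 0.0009, noise_sd = 0.004,
                            leaf_effect_sd = 0.003),
      WI_SWIR = response_model("onset_decline", plateau = 3.0, onset = 45,
                               slope = 0.004, noise_sd = 0.05,
                               leaf_effect_sd = 0.04),
      dR_D = response_model("linear", intercept = -0.12, slope = 0.0016,
                            noise_sd = 0.010, leaf_effect_sd = 0.008),
      dR_B = response_model("linear", intercept = -0.14, slope = 0.0018,
                            noise_sd = 0.010, leaf_effect_sd = 0.008),
      NDVI_D = response_model("linear", intercept = 0.86, slope = -0.0009,
                              noise_sd = 0.012, leaf_effect_sd = 0.010),
      NDVI_B = response_model("linear", intercept = 0.70, slope = -0.0014,
                              noise_sd = 0.010, leaf_effect_sd = 0.008),
      SPAD = response_model("linear", intercept = 52, slope = -0.12,
                            noise_sd = 1.6, leaf_effect_sd = 1.4),
      FvFm = response_model("logistic_decline", upper = 0.81, lower = 0.45,
                            midpoint = 35, steepness = 0.12,
                            noise_sd = 0.012, leaf_effect_sd = 0.010),
      PhiPSII_st = response_model("logistic_decline", upper = 0.62,
                                  lower = 0.05, midpoint = 60,
                                  steepness = 0.07, noise_sd = 0.035,
                                  leaf_effect_sd = 0.025),
      NPQ_1 = response_model("linear", intercept = 0.35, slope = 0.012,
                             noise_sd = 0.09, leaf_effect_sd = 0.06),
      NPQ_st = response_model("biphasic", baseline = 0.8, height = 1.0,
                              peak = 65, width = 20, noise_sd = 0.18,
                              leaf_effect_sd = 0.12)
    )
  } else {
    models <- list(
      psi_psy = response_model("linear", intercept = -4.8, slope = 0.044,
                               noise_sd = 0.12, leaf_effect_sd = 0.08),
      psi_press = response_model("linear", intercept = -3.4, slope = 0.030,
                                 noise_sd = 0.40, leaf_effect_sd = 0.25),
      WI_D = response_model("onset_decline", plateau = 1.06, onset = 75,
                            slope = 0.0024, noise_sd = 0.004,
                            leaf_effect_sd = 0.003),
      WI_B = response_model("onset_decline", plateau = 1.05, onset = 70,
                            slope = 0.0020, noise_sd = 0.004,
                            leaf_effect_sd = 0.003),
      WI_SWIR = response_model("onset_decline", plateau = 3.1, onset = 85,
                               slope = 0.024, noise_sd = 0.09,
                               leaf_effect_sd = 0.06),
      dR_D = response_model("linear", intercept = 0.02, slope = 0.0005,
                            noise_sd = 0.012, leaf_effect_sd = 0.010),
      dR_B = response_model("linear", intercept = 0.02, slope = 0.0006,
                            noise_sd = 0.012, leaf_effect_sd = 0.010),
      NDVI_D = response_model("linear", intercept = 0.80, slope = 0.0002,
                              noise_sd = 0.012, leaf_effect_sd = 0.010),
      NDVI_B = response_model("linear", intercept = 0.66, slope = 0.0004,
                              noise_sd = 0.012, leaf_effect_sd = 0.010),
      SPAD = response_model("linear", intercept = 44, slope = 0.03,
                            noise_sd = 1.8, leaf_effect_sd = 1.5),
      FvFm = response_model("logistic_decline", upper = 0.80, lower = 0.50,
                            midpoint = 30, steepness = 0.10,
                            noise_sd = 0.014, leaf_effect_sd = 0.010),
      PhiPSII_st = response_model("logistic_decline", upper = 0.58,
                                  lower = 0.10, midpoint = 55,
                                  steepness = 0.06, noise_sd = 0.030,
                                  leaf_effect_sd = 0.020),
      NPQ_1 = response_model("linear", intercept = 0.6, slope = 0.008,
                             noise_sd = 0.10, leaf_effect_sd = 0.07),
      NPQ_st = response_model("biphasic", baseline = 1.0, height = 0.8,
                              peak = 70, width = 18, noise_sd = 0.16,
                              leaf_effect_sd = 0.10)
    )
  }
  groups <- c(psi_psy = "water_potential", psi_press = "water_potential",
              WI_D = "water_index", WI_B = "water_index",
              WI_SWIR = "water_index",
              dR_D = "structure", dR_B = "structure",
              NDVI_D = "chlorophyll_content", NDVI_B = "chlorophyll_content",
              SPAD = "chlorophyll_content",
              FvFm = "chl_fluorescence", PhiPSII_st = "chl_fluorescence",
              NPQ_1 = "chl_fluorescence", NPQ_st = "chl_fluorescence")
  species_profile(
    name = name,
    drying_tau_h = if (name == "tobacco") 48 else 6,
    rwc_floor = 2,
    shrinkage_at_50 = if (name == "tobacco") 0.30 else 0.08,
    dry_matter_fraction = if (name == "tobacco") 0.12 else 0.10,
    calibration = cal, response_models = models, groups = groups,
    mean_fresh_mass_mg = if (name == "tobacco") 800 else 200,
    mean_fresh_area_cm2 = if (name == "tobacco") 20 else 8)
}

#' Simulate a desiccating-leaf dataset
#'
#' Draws per-sample harvest times covering the drying curve, computes the
#' true RWC, constructs internally consistent masses (fresh, actual, dry,
#' turgid) and shrunken leaf area, and draws every monitored parameter as
#' mean response + leaf random intercept + measurement noise. Fully
#' reproducible from the seed.
#'
#' Mass construction inverts the profile's ground-truth calibration
#' (`LMD = (RWC - intercept)/slope`), so running [compute_lmd()] and
#' [apply_calibration()] on the emitted table recovers the true RWC, and
#' the direct-route masses satisfy `RWC = (m_a - m_d) * 100/(m_t - m_d)`
#' exactly.
#'
#' @param profiles List of [species_profile()]s (default: both built-in
#'   profiles).
#' @param n_per_species Samples per species.
#' @param seed Integer seed; identical seed and configuration give
#'   identical output.
#' @param rwc_range Range of target RWC values the harvest design
#'   covers (default `c(45, 100)`, spanning the evaluation window).
#' @return A list with components
#'   `samples` (wide per-sample table: ids, masses, area, time, one
#'   column per parameter), `series` (tidy long table: species,
#'   parameter, group, sample_id, rwc, value — the reliability-module
#'   input, using calibrated RWC), and `truth` (per-parameter
#'   ground-truth: model kind, window slope of the mean response, noise
#'   SDs, theoretical CR over the window).
#' @export
simulate_dataset <- function(profiles = list(default_profile("tobacco"),
                                             default_profile("barley")),
                             n_per_species = 40, seed = 1,
                             rwc_range = c(45, 100)) {
  stopifnot(is.list(profiles), length(profiles) >= 1L, n_per_species >= 1,
            length(rwc_range) == 2L, rwc_range[1L] < rwc_range[2L])
  if (inherits(profiles, "species_profile")) profiles <- list(profiles)
  set.seed(as.integer(seed))
  samples <- list(); series <- list(); truth <- list()
  for (profile in profiles) {
    sp <- profile$name
    # evenly spread target RWC with a small jitter, mapped to harvest times
    rwc_target <- seq(rwc_range[1L], rwc_range[2L],
                      length.out = n_per_species) +
      stats::runif(n_per_species, -1, 1)
    rwc_target <- pmin(pmax(rwc_target, profile$rwc_floor + 1), 100)
    t_h <- -profile$drying_tau_h *
      log((rwc_target - profile$rwc_floor) / (100 - profile$rwc_floor))
    rwc_true <- drying_curve(t_h, profile)

    m_f <- profile$mean_fresh_mass_mg * exp(stats::rnorm(n_per_species, 0, 0.1))
    lmd_true <- (rwc_true - profile$calibration$intercept) /
      profile$calibration$slope
    lmd_true <- pmax(lmd_true, 0)
    m_a <- m_f * (1 - lmd_true / 100)
    m_d <- profile$dry_matter_fraction * m_f
    # turgid mass consistent with the direct RWC identity at the true RWC
    m_t <- m_d + (m_a - m_d) * 100 / pmax(rwc_true, 1e-6)
    area_fresh <- profile$mean_fresh_area_cm2 *
      exp(stats::rnorm(n_per_species, 0, 0.08))
    area <- area_fresh * (1 - shrinkage_at(profile, rwc_true))
    ids <- sprintf("%s_%03d", sp, seq_len(n_per_species))

    wide <- data.frame(sample_id = ids, species = sp, time_h = t_h,
                       m_f = m_f, m_a = m_a, m_d = m_d, m_t = m_t,
                       area_cm2 = area, stringsAsFactors = FALSE)
    rwc_cal <- suppressWarnings(
      apply_calibration(profile$calibration, compute_lmd(m_f, m_a)))

    for (pname in names(profile$response_models)) {
      model <- profile$response_models[[pname]]
      mu <- expected_response(model, pmin(rwc_true, 110))
      leaf <- stats::rnorm(n_per_species, 0, model$leaf_effect_sd)
      eps <- stats::rnorm(n_per_species, 0, model$noise_sd)
      val <- mu + leaf + eps
      wide[[pname]] <- val
      series[[length(series) + 1L]] <- data.frame(
        species = sp, parameter = pname,
        group = unname(if (is.null(profile$groups)) NA_character_
                       else profile$groups[[pname]]),
        sample_id = ids, rwc = rwc_cal, value = val,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <-
        cbind(data.frame(species = sp, parameter = pname,
                         stringsAsFactors = FALSE),
              theoretical_coefficients(model, window = c(50, 100)))
    }
    samples[[length(samples) + 1L]] <- wide
  }
  list(samples = do.call(rbind, samples),
       series = do.call(rbind, series),
       truth = do.call(rbind, truth))
}

#' Theoretical reliability coefficients of a response model
#'
#' For a response model observed with Gaussian noise of total SD
#' `sigma = sqrt(noise_sd^2 + leaf_effect_sd^2)`, the mean absolute
#' residual around the best linear approximation tends to
#' `sigma * sqrt(2/pi)` (plus any model-lack-of-fit), so a linear model
#' has theoretical `CR = |slope| * delta_s / (sigma * sqrt(2/pi))`. For
#' the nonlinear shapes the best linear slope over the window is obtained
#' by least squares on a dense RWC grid and the lack-of-fit deviation is
#' folded into the expected absolute residual (Gaussian approximation).
#'
#' @param model A [response_model()].
#' @param delta_s RWC step, percent (default 10).
#' @param window Evaluation window, percent.
#' @return A one-row data.frame: `kind`, `slope_window` (best linear
#'   slope of the mean response over the window), `sigma` (total noise
#'   SD), `CR_theory`.
#' @export
theoretical_coefficients <- function(model, delta_s = 10,
                                     window = c(50, 100)) {
  stopifnot(inherits(model, "response_model"))
  grid <- seq(window[1L], window[2L], length.out = 2001L)
  mu <- expected_response(model, grid)
  f <- fit_linear(grid, mu)
  lack <- mu - (f$a + f$b * grid)
  sigma <- sqrt(model$noise_sd^2 + model$leaf_effect_sd^2)
  # E|lack + N(0, sigma^2)| averaged over the grid; folded-normal mean
  if (sigma > 0) {
    ead <- mean(sigma * sqrt(2 / pi) * exp(-lack^2 / (2 * sigma^2)) +
                  abs(lack) * (1 - 2 * stats::pnorm(-abs(lack) / sigma)))
  } else {
    ead <- mean(abs(lack))
  }
  cr <- if (ead == 0) Inf else abs(f$b) * delta_s / ead
  data.frame(kind = model$kind, slope_window = f$b, sigma = sigma,
             expected_dy_bar = ead, CR_theory = cr,
             stringsAsFactors = FALSE)
}

#' Simulate a leaf reflectance spectrum at a given RWC
#'
#' Builds a smooth synthetic spectrum over 400-1700 nm: a chlorophyll
#' absorption region in the VIS (deepening with the apparent chlorophyll
#' concentration, which rises as the leaf shrinks), a high NIR plateau,
#' and Gaussian water-absorption troughs at 970 and 1450 nm whose depths
#' scale with the profile's relative equivalent water thickness at that
#' RWC. Optional additive Gaussian noise, deterministic per seed.
#'
#' @param rwc RWC, percent, in `[0, 100]`.
#' @param profile A [species_profile()] (controls shrinkage, hence the
#'   EWT trajectory).
#' @param seed Optional integer seed for the noise.
#' @param noise_sd Additive reflectance noise SD (default 0, noiseless).
#' @param wavelength_nm Wavelength grid (default 400-1700 nm in 2 nm
#'   steps).
#' @param side,mode,sample_id Metadata for the returned spectrum.
#' @return A [reflectance_spectrum()].
#' @export
simulate_spectrum <- function(rwc, profile, seed = NULL, noise_sd = 0,
                              wavelength_nm = seq(400, 1700, by = 2),
                              side = "adaxial", mode = "diffusive",
                              sample_id = NA_character_) {
  stopifnot(is.numeric(rwc), length(rwc) == 1L, rwc >= 0, rwc <= 100,
            inherits(profile, "species_profile"))
  lam <- wavelength_nm
  ewt_rel <- ewt_relative(profile, rwc)
  chl_apparent <- 1 / (1 - shrinkage_at(profile, rwc))

  # NIR plateau with a gentle downward slope into the SWIR
  base <- 0.08 + 0.40 / (1 + exp(-(lam - 715) / 18)) -
    0.00005 * pmax(lam - 1100, 0)
  # chlorophyll absorption: red trough at 670 nm, deepens with apparent Chl
  chl_trough <- 0.10 * (1 - exp(-0.9 * chl_apparent)) *
    exp(-(lam - 670)^2 / (2 * 45^2))
  # water absorption troughs; depths scale with relative EWT (saturating);
  # the 1450 nm feature is far stronger, putting R1000/R1450 near 3 for a
  # hydrated leaf while R900/R970 stays near 1
  w970 <- 0.045 * (1 - exp(-1.2 * ewt_rel)) * exp(-(lam - 970)^2 / (2 * 25^2))
  w1450 <- 0.38 * (1 - exp(-1.8 * ewt_rel)) * exp(-(lam - 1450)^2 / (2 * 40^2))

  refl <- base - chl_trough - w970 - w1450
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    refl <- refl + stats::rnorm(length(lam), 0, noise_sd)
  }
  refl <- pmin(pmax(refl, 0.001), 0.999)
  reflectance_spectrum(lam, refl, side = side, mode = mode,
                       sample_id = sample_id)
}

#' Simulate a fluorescence induction trace from a record
#'
#' Inverse of [extract_record()]: builds a timestamped piecewise trace
#' whose landmark levels are exactly the record's values — dark
#' measuring flashes at `F0`, a dark saturating pulse reaching `FM`,
#' actinic onset with a fluorescence transient relaxing toward `Fst`
#' (clamped to `Fst` over the final steady-state window), and a pulse
#' train whose peaks interpolate from `FMp1` (pulse at 1 min of actinic
#' light) to `FMpst` (last pulse, at 10 min). On the noiseless trace
#' [extract_record()] returns the input record exactly.
#'
#' @param record A [fluorescence_record()].
#' @param seed Optional integer seed for the noise.
#' @param noise_sd Additive noise SD in a.u. (default 0).
#' @param dt_s Sampling interval, seconds.
#' @param dark_s Dark measuring phase before the dark pulse, seconds.
#' @param relax_s Dark relaxation between the dark pulse and actinic
#'   onset, seconds.
#' @param light_s Actinic phase length, seconds (default 600 = 10 min).
#' @param pulse_every_s Interval between light-phase pulses, seconds.
#' @param steady_window_s Final window clamped at `Fst`, seconds; should
#'   match the window used at extraction.
#' @return An [induction_trace()].
#' @export
simulate_fluorescence_trace <- function(record, seed = NULL, noise_sd = 0,
                                        dt_s = 0.2, dark_s = 30,
                                        relax_s = 120, light_s = 600,
                                        pulse_every_s = 60,
                                        steady_window_s = 30) {
  stopifnot(inherits(record, "fluorescence_record"))
  pulse_width <- 0.8
  t_dark_pulse <- dark_s
  t_on <- dark_s + pulse_width + relax_s
  light_pulse_offsets <- seq(pulse_every_s, light_s, by = pulse_every_s)
  light_pulses <- t_on + light_pulse_offsets
  t_end <- max(light_pulses) + pulse_width + 2
  time_s <- seq(0, t_end, by = dt_s)

  # light-phase pulse peaks: FMp1 at the 1-min pulse, FMpst at the last,
  # linear in between (NPQ develops over the induction)
  n_lp <- length(light_pulses)
  peaks <- seq(record$FMp1, record$FMpst, length.out = n_lp)

  # base signal: F0 in the dark, induction transient relaxing to Fst
  f <- rep(record$F0, length(time_s))
  light <- time_s >= t_on
  f_peak <- record$Fst + 0.6 * (record$FMp1 - record$Fst)
  tau_ind <- 90
  f[light] <- record$Fst +
    (f_peak - record$Fst) * exp(-(time_s[light] - t_on) / tau_ind)
  # clamp the steady-state window (and beyond) to Fst exactly
  last_pulse <- light_pulses[n_lp]
  f[time_s >= last_pulse - steady_window_s] <- record$Fst

  # overlay the saturating pulses
  set_pulse <- function(f, onset, level) {
    idx <- time_s >= onset & time_s <= onset + pulse_width
    f[idx] <- level
    f
  }
  f <- set_pulse(f, t_dark_pulse, record$FM)
  for (i in seq_len(n_lp)) f <- set_pulse(f, light_pulses[i], peaks[i])

  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    f <- pmax(f + stats::rnorm(length(f), 0, noise_sd), 1e-6)
  }
  induction_trace(time_s, f,
                  pulse_times_s = c(t_dark_pulse, light_pulses),
                  actinic_on_s = t_on, pulse_width_s = pulse_width)
}
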