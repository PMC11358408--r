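#' Leaf mass decrease (LMD)
#'
#' Percentage of fresh mass lost since leaf detachment,
#' `LMD = (m_f - m_a) * 100 / m_f`. LMD is the non-destructive proxy for
#' water loss used throughout the pipeline; it is converted to relative
#' water content via a species-specific linear calibration
#' (see [fit_lmd_rwc_calibration()]).
#'
#' @param m_f Fresh mass at detachment (mg, or any mass unit; the result is
#'   dimensionless in mass).
#' @param m_a Actual mass at measurement time, same unit as `m_f`.
#' @return LMD in percent, in `[0, 100)`. Vectorized over both arguments.
#' @examples
#' compute_lmd(200, 150) # 25
#' @export
compute_lmd <- function(m_f, m_a) {
  stopifnot(is.numeric(m_f), is.numeric(m_a))
  if (any(m_f <= 0 | m_a <= 0, na.rm = TRUE))
    stop("masses must be positive", call. = FALSE)
  if (any(m_a > m_f, na.rm = TRUE))
    stop("actual mass m_a exceeds fresh mass m_f", call. = FALSE)
  (m_f - m_a) * 100 / m_f
}

#' Relative water content from masses (direct, destructive route)
#'
#' `RWC = (m_a - m_d) * 100 / (m_t - m_d)`, where `m_t` is the fully
#' turgid mass and `m_d` the dry mass. Values slightly above 100 are
#' allowed with a warning (supersaturation or weighing noise); they are
#' not clamped.
#'
#' @param m_a Actual mass.
#' @param m_d Dry mass.
#' @param m_t Turgid (fully rehydrated) mass.
#' @return RWC in percent. Vectorized.
#' @examples
#' compute_rwc_direct(90, 30, 150) # 50
#' @export
compute_rwc_direct <- function(m_a, m_d, m_t) {
  stopifnot(is.numeric(m_a), is.numeric(m_d), is.numeric(m_t))
  if (any(m_t <= m_d, na.rm = TRUE))
    stop("turgid mass m_t must exceed dry mass m_d", call. = FALSE)
  if (any(m_a < m_d, na.rm = TRUE))
    stop("actual mass m_a below dry mass m_d", call. = FALSE)
  if (any(m_a > m_t, na.rm = TRUE))
    warning("m_a > m_t: RWC above 100% retained (not clamped)", call. = FALSE)
  (m_a - m_d) * 100 / (m_t - m_d)
}

#' Construct an LMD-to-RWC linear calibration
#'
#' A calibration maps leaf mass decrease (percent) to relative water
#' content (percent) as `RWC = slope * LMD + intercept`. Usually produced
#' by [fit_lmd_rwc_calibration()]; this constructor also lets known
#' coefficients (e.g. from a previous destructive calibration experiment)
#' be supplied directly.
#'
#' @param slope Percent RWC per percent LMD (negative for drying leaves).
#' @param intercept RWC at LMD = 0, percent.
#' @param r2 Coefficient of determination of the calibration fit, in
#'   `[0, 1]`; `NA` when unknown.
#' @param n Number of calibration pairs; `NA` when unknown.
#' @return An object of class `lmd_rwc_calibration`.
#' @seealso [default_calibrations()] for the tobacco and barley
#'   calibrations shipped with the package.
#' @export
lmd_rwc_calibration <- function(slope, intercept, r2 = NA_real_, n = NA_integer_) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  if (!is.na(r2) && (r2 < 0 || r2 > 1))
    stop("r2 must lie in [0, 1]", call. = FALSE)
  if (!is.na(n) && n < 2)
    stop("a calibration needs at least 2 pairs", call. = FALSE)
  structure(
    list(slope = slope, intercept = intercept,
         r2 = as.numeric(r2), n = as.integer(n)),
    class = "lmd_rwc_calibration"
  )
}

#' @export
print.lmd_rwc_calibration <- function(x, ...) {
  cat(sprintf("LMD -> RWC calibration: RWC = %.4f * LMD + %.4f", x$slope, x$intercept))
  if (!is.na(x$r2)) cat(sprintf("  (R2 = %.4f, n = %d)", x$r2, x$n))
  cat("\n")
  invisible(x)
}

#' Fit the LMD-to-RWC calibration by ordinary least squares
#'
#' Fits `RWC = slope * LMD + intercept` (free intercept, unweighted OLS
#' minimizing squared RWC residuals) to paired observations from a
#' destructive calibration experiment.
#'
#' @param lmd Leaf mass decrease values, percent.
#' @param rwc Directly measured relative water content values, percent.
#' @return An [lmd_rwc_calibration()] object with `slope`, `intercept`,
#'   `r2` and `n` filled in.
#' @examples
#' cal <- fit_lmd_rwc_calibration(c(0, 50), c(100, 45))
#' cal$slope # -1.1
#' @export
fit_lmd_rwc_calibration <- function(lmd, rwc) {
  stopifnot(is.numeric(lmd), is.numeric(rwc), length(lmd) == length(rwc))
  keep <- is.finite(lmd) & is.finite(rwc)
  lmd <- lmd[keep]; rwc <- rwc[keep]
  if (length(lmd) < 2L)
    stop("need at least 2 complete (LMD, RWC) pairs", call. = FALSE)
  f <- fit_linear(lmd, rwc)
  lmd_rwc_calibration(slope = f$b, intercept = f$a, r2 = f$r2, n = length(lmd))
}

#' Convert LMD to RWC with a calibration
#'
#' Applies `RWC = slope * LMD + intercept`. No clamping: calibrated RWC
#' slightly above 100 or below 0 is preserved (calibration intercepts
#' genuinely exceed 100 for well-watered leaves) and reported with a
#' warning so downstream windowing stays honest.
#'
#' @param cal An [lmd_rwc_calibration()] object.
#' @param lmd LMD values, percent. Vectorized.
#' @return Calibrated RWC, percent.
#' @examples
#' apply_calibration(default_calibrations()$tobacco, 0) # 100.37
#' @export
apply_calibration <- function(cal, lmd) {
  stopifnot(inherits(cal, "lmd_rwc_calibration"), is.numeric(lmd))
  out <- cal$slope * lmd + cal$intercept
  oob <- sum(out > 100 | out < 0, na.rm = TRUE)
  if (oob > 0)
    warning(sprintf("%d calibrated RWC value(s) outside [0, 100] retained", oob),
            call. = FALSE)
  out
}

#' Species calibrations shipped with the package
#'
#' LMD-to-RWC calibrations for detached tobacco whole leaves and barley
#' leaf segments, obtained from destructive calibration experiments in
#' which LMD and direct RWC were measured on the same samples
#' (tobacco: `RWC = -1.1085 * LMD + 100.37`; barley:
#' `RWC = -1.0986 * LMD + 98.221`). These are the defaults used by the
#' built-in species profiles of the synthetic generator and by
#' [run_pipeline()] when `calibration = "fixed"`.
#'
#' @return A named list of [lmd_rwc_calibration()] objects with elements
#'   `tobacco` and `barley`.
#' @export
default_calibrations <- function() {
  list(
    tobacco = lmd_rwc_calibration(-1.1085, 100.37),
    barley  = lmd_rwc_calibration(-1.0986, 98.221)
  )
}

#' Equivalent water thickness (EWT)
#'
#' Leaf water mass per unit actual leaf area,
#' `EWT = (m_a - m_d) / area`, in g cm^-2 when masses are grams and area
#' cm^2. Because the area is the *actual* (possibly shrunken) area, EWT
#' declines more slowly than RWC in species whose leaves shrink strongly
#' during desiccation.
#'
#' @param m_a Actual mass (g).
#' @param m_d Dry mass (g).
#' @param area_cm2 Actual sample area (cm^2).
#' @return EWT in g cm^-2. Vectorized.
#' @export
compute_ewt <- function(m_a, m_d, area_cm2) {
  stopifnot(is.numeric(m_a), is.numeric(m_d), is.numeric(area_cm2))
  if (any(area_cm2 <= 0, na.rm = TRUE))
    stop("leaf area must be positive", call. = FALSE)
  if (any(m_a < m_d, na.rm = TRUE))
    stop("actual mass m_a below dry mass m_d", call. = FALSE)
  (m_a - m_d) / area_cm2
}

#' Actual mass for long measurement protocols
#'
#' For protocols during which the leaf keeps losing water (diffusive
#' reflectance, light-adapted fluorescence), the actual mass is taken as
#' the arithmetic mean of the sample weight before and after the
#' measurement.
#'
#' @param m_before,m_after Sample mass before / after the protocol.
#' @return The mean mass. If `m_after > m_before` (condensation or a
#'   weighing error) a warning is emitted and the mean is still returned.
#' @export
averaged_actual_mass <- function(m_before, m_after) {
  stopifnot(is.numeric(m_before), is.numeric(m_after))
  if (any(m_before <= 0 | m_after <= 0, na.rm = TRUE))
    stop("masses must be positive", call. = FALSE)
  if (any(m_after > m_before, na.rm = TRUE))
    warning("m_after > m_before: mass gained during protocol; mean returned",
            call. = FALSE)
  (m_before + m_after) / 2
}
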