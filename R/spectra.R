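#' Construct a reflectance spectrum
#'
#' A sampled leaf reflectance curve: a strictly increasing wavelength grid
#' (nm) and dimensionless reflectance fractions in `[0, 1]`. Files from
#' some instruments store reflectance in percent; when any value exceeds
#' 1.5 the whole curve is assumed percent-scaled and divided by 100 (a
#' message is emitted).
#'
#' @param wavelength_nm Strictly increasing wavelengths, nm.
#' @param reflectance Reflectance values, same length, fraction in
#'   `[0, 1]` (or percent, auto-detected).
#' @param side Leaf side the spectrum was measured from: `"adaxial"`
#'   (upper) or `"abaxial"` (lower). Carried as metadata; index names use
#'   the conventional D/B suffixes.
#' @param mode `"diffusive"` (integrating sphere) or `"directional"`.
#'   Metadata only; indices are computed identically.
#' @param sample_id Sample identifier.
#' @return An object of class `reflectance_spectrum`.
#' @export
reflectance_spectrum <- function(wavelength_nm, reflectance,
                                 side = c("adaxial", "abaxial"),
                                 mode = c("diffusive", "directional"),
                                 sample_id = NA_character_) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  stopifnot(is.numeric(wavelength_nm), is.numeric(reflectance))
  if (length(wavelength_nm) != length(reflectance))
    stop("wavelength and reflectance lengths differ", call. = FALSE)
  if (length(wavelength_nm) < 2L)
    stop("a spectrum needs at least 2 samples", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(!is.finite(reflectance)))
    stop("non-finite reflectance values", call. = FALSE)
  if (any(reflectance > 1.5)) {
    message("reflectance values > 1.5 detected: assuming percent scale, dividing by 100")
    reflectance <- reflectance / 100
  }
  if (any(reflectance < 0 | reflectance > 1))
    stop("reflectance must lie in [0, 1]", call. = FALSE)
  structure(
    list(wavelength_nm = as.numeric(wavelength_nm),
         reflectance = as.numeric(reflectance),
         side = side, mode = mode, sample_id = sample_id),
    class = "reflectance_spectrum"
  )
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("reflectance_spectrum: %d samples, %.0f-%.0f nm, %s/%s, sample %s\n",
              length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
              x$side, x$mode, x$sample_id))
  invisible(x)
}

spectrum_covers <- function(spectrum, lambda_nm) {
  lambda_nm >= min(spectrum$wavelength_nm) & lambda_nm <= max(spectrum$wavelength_nm)
}

#' Reflectance at a nominal wavelength
#'
#' Linear interpolation between the two bracketing grid samples; exact
#' sample value when the wavelength lies on the grid. Instrument grids
#' differ (6 nm monochromator slit vs. hyperspectral bands), so band
#' extraction by interpolation at the exact nominal wavelength keeps the
#' indices grid-independent. No extrapolation.
#'
#' @param spectrum A [reflectance_spectrum()].
#' @param lambda_nm Target wavelength(s), nm, within the grid range.
#' @return Interpolated reflectance fraction(s).
#' @export
reflectance_at <- function(spectrum, lambda_nm) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"), is.numeric(lambda_nm))
  if (any(!spectrum_covers(spectrum, lambda_nm)))
    stop(sprintf("wavelength outside spectrum range [%g, %g] nm",
                 min(spectrum$wavelength_nm), max(spectrum$wavelength_nm)),
         call. = FALSE)
  stats::approx(spectrum$wavelength_nm, spectrum$reflectance,
                xout = lambda_nm, method = "linear", ties = "ordered")$y
}

#' Water index WI = R900/R970
#'
#' Ratio of reflectance at 900 nm (reference) to 970 nm (water absorption
#' trough). Deeper water absorption at 970 nm (wetter leaf) raises WI;
#' desiccation shallows the trough and lowers WI toward the baseline
#' ratio of ~1.
#'
#' @param spectrum A [reflectance_spectrum()] covering 900 and 970 nm.
#' @return WI, dimensionless.
#' @export
water_index <- function(spectrum) {
  r900 <- reflectance_at(spectrum, 900)
  r970 <- reflectance_at(spectrum, 970)
  if (r970 <= 0) stop("WI undefined: R970 = 0", call. = FALSE)
  r900 / r970
}

#' SWIR water index WI_SWIR = R1000/R1450
#'
#' Ratio probing the much stronger water absorption trough at 1450 nm;
#' magnitudes are typically around 3 for hydrated leaves, several-fold
#' larger than WI.
#'
#' @param spectrum A [reflectance_spectrum()] covering 1000 and 1450 nm.
#' @return WI_SWIR, dimensionless.
#' @export
water_index_swir <- function(spectrum) {
  r1000 <- reflectance_at(spectrum, 1000)
  r1450 <- reflectance_at(spectrum, 1450)
  if (r1450 <= 0) stop("WI_SWIR undefined: R1450 = 0", call. = FALSE)
  r1000 / r1450
}

#' Relative NIR reflectance slope dR = (R800 - R1100)/R800
#'
#' Describes the decline of reflectance across the 800-1100 nm region;
#' positive when reflectance falls with wavelength, negative when it
#' rises. Sensitive to internal leaf structure rather than water
#' absorption, and can change sign during desiccation.
#'
#' @param spectrum A [reflectance_spectrum()] covering 800 and 1100 nm.
#' @return dR, dimensionless, always < 1.
#' @export
delta_r <- function(spectrum) {
  r800 <- reflectance_at(spectrum, 800)
  r1100 <- reflectance_at(spectrum, 1100)
  if (r800 <= 0) stop("dR undefined: R800 = 0", call. = FALSE)
  (r800 - r1100) / r800
}

#' Normalized difference vegetation index
#'
#' `NDVI = (R780 - R630)/(R780 + R630)`, a chlorophyll/greenness proxy in
#' `[-1, 1]`. During desiccation of strongly shrinking leaves the
#' apparent chlorophyll concentration rises, so NDVI can *increase* as
#' the leaf dries.
#'
#' @param spectrum A [reflectance_spectrum()] covering 630 and 780 nm.
#' @return NDVI, dimensionless in `[-1, 1]`.
#' @export
ndvi <- function(spectrum) {
  r780 <- reflectance_at(spectrum, 780)
  r630 <- reflectance_at(spectrum, 630)
  if (r780 + r630 <= 0) stop("NDVI undefined: R780 + R630 = 0", call. = FALSE)
  (r780 - r630) / (r780 + r630)
}

index_bands <- list(
  WI = c(900, 970),
  WI_SWIR = c(1000, 1450),
  dR = c(800, 1100),
  NDVI = c(630, 780)
)

#' Compute all reflectance indices a spectrum supports
#'
#' Evaluates WI, WI_SWIR, dR and NDVI, skipping (with a message) any
#' index whose required bands fall outside the spectrum's wavelength
#' range — e.g. NDVI on a 1000-1700 nm SWIR spectrum.
#'
#' @param spectrum A [reflectance_spectrum()].
#' @return A data.frame with columns `name`, `value`, `side`,
#'   `sample_id`; one row per computable index.
#' @export
compute_indices <- function(spectrum) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"))
  funs <- list(WI = water_index, WI_SWIR = water_index_swir,
               dR = delta_r, NDVI = ndvi)
  rows <- lapply(names(funs), function(nm) {
    bands <- index_bands[[nm]]
    if (!all(spectrum_covers(spectrum, bands))) {
      message(sprintf("skipping %s: bands %s nm outside spectrum range",
                      nm, paste(bands, collapse = "/")))
      return(NULL)
    }
    data.frame(name = nm, value = funs[[nm]](spectrum),
               side = spectrum$side, sample_id = spectrum$sample_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(name = character(), value = numeric(),
                      side = character(), sample_id = character(),
                      stringsAsFactors = FALSE)
  out
}
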