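#' Construct a protocol-level fluorescence record
#'
#' The five fluorescence levels produced by the quenching-analysis
#' protocol: minimal (`F0`) and maximal (`FM`) fluorescence of the
#' dark-adapted sample, maximal fluorescence under actinic light after
#' 1 min (`FMp1`) and at steady state (`FMpst`), and the steady-state
#' fluorescence itself (`Fst`). All in arbitrary units; every derived
#' parameter is a ratio and therefore unit-free.
#'
#' @param F0,FM,FMp1,FMpst,Fst Fluorescence levels, all > 0, with
#'   `FM >= F0` and `Fst <= FMpst`.
#' @param sample_id Sample identifier.
#' @return An object of class `fluorescence_record`.
#' @export
fluorescence_record <- function(F0, FM, FMp1, FMpst, Fst,
                                sample_id = NA_character_) {
  vals <- c(F0 = F0, FM = FM, FMp1 = FMp1, FMpst = FMpst, Fst = Fst)
  stopifnot(is.numeric(vals), length(vals) == 5L)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all fluorescence levels must be positive and finite", call. = FALSE)
  if (F0 > FM) stop("F0 exceeds FM", call. = FALSE)
  if (Fst > FMpst) stop("Fst exceeds FM'st", call. = FALSE)
  structure(list(F0 = F0, FM = FM, FMp1 = FMp1, FMpst = FMpst, Fst = Fst,
                 sample_id = sample_id),
            class = "fluorescence_record")
}

#' @export
print.fluorescence_record <- function(x, ...) {
  cat(sprintf(
    "fluorescence_record %s: F0=%.3g FM=%.3g FM'1=%.3g FM'st=%.3g Fst=%.3g\n",
    x$sample_id, x$F0, x$FM, x$FMp1, x$FMpst, x$Fst))
  invisible(x)
}

#' Maximum quantum yield of PSII photochemistry
#'
#' `FV/FM = (FM - F0)/FM` from the dark-adapted state; around 0.8 in
#' healthy leaves and only weakly responsive to mild desiccation.
#'
#' @param F0 Minimal dark-adapted fluorescence (> 0).
#' @param FM Maximal dark-adapted fluorescence (>= F0).
#' @return FV/FM, dimensionless in `[0, 1)`.
#' @export
fv_fm <- function(F0, FM) {
  stopifnot(is.numeric(F0), is.numeric(FM))
  if (any(FM <= 0 | F0 <= 0, na.rm = TRUE))
    stop("F0 and FM must be positive", call. = FALSE)
  if (any(F0 > FM, na.rm = TRUE))
    stop("F0 exceeds FM", call. = FALSE)
  (FM - F0) / FM
}

#' Effective quantum yield of PSII in the light-adapted steady state
#'
#' `PhiPSII_st = (FM'st - Fst)/FM'st`, from the steady state reached
#' after 10 min of actinic light.
#'
#' @param Fst Steady-state fluorescence (> 0).
#' @param FMpst Maximal fluorescence at steady state (>= Fst).
#' @return PhiPSII_st, dimensionless in `[0, 1]`.
#' @export
phi_psii_st <- function(Fst, FMpst) {
  stopifnot(is.numeric(Fst), is.numeric(FMpst))
  if (any(FMpst <= 0, na.rm = TRUE))
    stop("FM'st must be positive", call. = FALSE)
  if (any(Fst > FMpst, na.rm = TRUE))
    stop("Fst exceeds FM'st", call. = FALSE)
  (FMpst - Fst) / FMpst
}

#' Nonphotochemical quenching
#'
#' `NPQ = (FM - FM')/FM'`, used both at 1 min of actinic light
#' (`FMp = FMp1`, giving NPQ_1) and at steady state (`FMp = FMpst`,
#' giving NPQ_st). A slightly negative NPQ (FM' above FM, a
#' noise/relaxation artifact) is returned with a warning, not clipped:
#' clipping would bias the reliability statistics downstream.
#'
#' @param FM Maximal dark-adapted fluorescence.
#' @param FMp Maximal light-adapted fluorescence (FM' at 1 min or at
#'   steady state).
#' @return NPQ, dimensionless.
#' @export
npq <- function(FM, FMp) {
  stopifnot(is.numeric(FM), is.numeric(FMp))
  if (any(FMp <= 0, na.rm = TRUE))
    stop("FM' must be positive", call. = FALSE)
  out <- (FM - FMp) / FMp
  if (any(out < 0, na.rm = TRUE))
    warning("negative NPQ (FM' > FM) returned unclipped", call. = FALSE)
  out
}

#' All four fluorescence parameters from one record
#'
#' @param record A [fluorescence_record()].
#' @return A data.frame with columns `sample_id`, `parameter`
#'   (`FvFm`, `PhiPSII_st`, `NPQ_1`, `NPQ_st`) and `value`.
#' @export
fluorescence_params <- function(record) {
  stopifnot(inherits(record, "fluorescence_record"))
  data.frame(
    sample_id = record$sample_id,
    parameter = c("FvFm", "PhiPSII_st", "NPQ_1", "NPQ_st"),
    value = c(fv_fm(record$F0, record$FM),
              phi_psii_st(record$Fst, record$FMpst),
              npq(record$FM, record$FMp1),
              npq(record$FM, record$FMpst)),
    stringsAsFactors = FALSE
  )
}

#' Construct a fluorescence induction trace
#'
#' A timestamped fluorescence signal from the quenching protocol: dark
#' measuring flashes, a dark saturating pulse, actinic light onset, and a
#' train of saturating pulses during induction.
#'
#' @param time_s Strictly increasing sample times, seconds.
#' @param fluorescence Fluorescence signal, same length, a.u.
#' @param pulse_times_s Onset times of the saturating pulses, within the
#'   trace span.
#' @param actinic_on_s Time at which the actinic light was switched on.
#' @param pulse_width_s Saturating-pulse length, seconds (default 0.8).
#' @return An object of class `induction_trace`.
#' @export
induction_trace <- function(time_s, fluorescence, pulse_times_s,
                            actinic_on_s, pulse_width_s = 0.8) {
  stopifnot(is.numeric(time_s), is.numeric(fluorescence),
            is.numeric(pulse_times_s), is.numeric(actinic_on_s))
  if (length(time_s) != length(fluorescence))
    stop("time and fluorescence lengths differ", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (length(pulse_times_s) &&
      (min(pulse_times_s) < min(time_s) || max(pulse_times_s) > max(time_s)))
    stop("pulse times outside trace span", call. = FALSE)
  structure(list(time_s = time_s, fluorescence = fluorescence,
                 pulse_times_s = sort(pulse_times_s),
                 actinic_on_s = actinic_on_s,
                 pulse_width_s = pulse_width_s),
            class = "induction_trace")
}

in_pulse <- function(trace, pulse_onset) {
  trace$time_s >= pulse_onset &
    trace$time_s <= pulse_onset + trace$pulse_width_s
}

# smoothed peak of a saturating pulse: mean of the top 3 in-pulse samples.
# A raw max over the noisy pulse plateau is upward-biased by the extreme
# order statistic; averaging the top samples removes most of that bias
# while still tracking the plateau level.
pulse_peak <- function(trace, pulse_onset) {
  v <- sort(trace$fluorescence[in_pulse(trace, pulse_onset)],
            decreasing = TRUE)
  if (!length(v)) stop("no samples within the saturating pulse", call. = FALSE)
  mean(v[seq_len(min(3L, length(v)))])
}

#' Extract a fluorescence record from an induction trace
#'
#' Locates the protocol landmarks in a timestamped trace and reduces it
#' to the five levels of a [fluorescence_record()]:
#' * `F0`: mean of the dark measuring-flash samples before the first
#'   saturating pulse (robust to single-sample noise);
#' * `FM`: smoothed peak (mean of the top 3 samples) within the dark
#'   saturating pulse — on a noiseless plateau this is the maximum, and
#'   under noise it avoids the upward bias of the extreme order
#'   statistic;
#' * `FMp1`: smoothed peak within the light-phase pulse whose onset is
#'   nearest 60 s after actinic onset (within `one_min_tol_s`);
#' * `FMpst`: smoothed peak within the last pulse;
#' * `Fst`: mean of the samples in the final `steady_window_s` seconds
#'   before the last pulse.
#'
#' @param trace An [induction_trace()].
#' @param steady_window_s Length of the pre-pulse window treated as
#'   steady state, seconds (default 30).
#' @param one_min_tol_s Tolerance for locating the "1 min" pulse,
#'   seconds (default 10).
#' @param sample_id Identifier for the returned record.
#' @return A [fluorescence_record()].
#' @export
extract_record <- function(trace, steady_window_s = 30, one_min_tol_s = 10,
                           sample_id = NA_character_) {
  stopifnot(inherits(trace, "induction_trace"))
  dark_pulses <- trace$pulse_times_s[trace$pulse_times_s < trace$actinic_on_s]
  light_pulses <- trace$pulse_times_s[trace$pulse_times_s >= trace$actinic_on_s]
  if (length(dark_pulses) < 1L)
    stop("extraction failed: no dark-phase saturating pulse", call. = FALSE)
  if (length(light_pulses) < 2L)
    stop("extraction failed: need >= 2 light-phase saturating pulses", call. = FALSE)

  first_pulse <- min(trace$pulse_times_s)
  dark_idx <- trace$time_s < first_pulse
  if (!any(dark_idx))
    stop("extraction failed: no dark samples before first pulse", call. = FALSE)
  F0 <- mean(trace$fluorescence[dark_idx])

  FM <- pulse_peak(trace, dark_pulses[1L])

  offset <- light_pulses - trace$actinic_on_s
  near1 <- which.min(abs(offset - 60))
  if (abs(offset[near1] - 60) > one_min_tol_s)
    stop("extraction failed: no saturating pulse near 1 min of actinic light",
         call. = FALSE)
  FMp1 <- pulse_peak(trace, light_pulses[near1])

  last_pulse <- light_pulses[length(light_pulses)]
  FMpst <- pulse_peak(trace, last_pulse)

  st_idx <- trace$time_s >= last_pulse - steady_window_s &
    trace$time_s < last_pulse
  if (!any(st_idx))
    stop("extraction failed: no samples in the steady-state window", call. = FALSE)
  Fst <- mean(trace$fluorescence[st_idx])

  fluorescence_record(F0 = F0, FM = FM, FMp1 = FMp1, FMpst = FMpst,
                      Fst = Fst, sample_id = sample_id)
}
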