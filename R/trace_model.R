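#' Construct a ROTEM amplitude trace
#'
#' A `rotem_trace` is a sampled clot-firmness time series for one assay
#' channel: time in seconds from assay start (recalcification/activation)
#' against clot amplitude in mm. Amplitudes are unsigned firmness (the
#' two-sided TEMogram is folded), and irregular sampling is allowed.
#'
#' Rows with identical time and amplitude are collapsed; identical times with
#' differing amplitudes are rejected, so times are strictly increasing in the
#' returned object.
#'
#' @param times numeric vector of seconds, non-decreasing.
#' @param amplitudes numeric vector of clot firmness in mm, same length as
#'   `times`, all `>= 0`.
#' @param channel channel label, e.g. `"extem"`, `"rico"`, `"rico_haemate"`,
#'   `"fibtem"`.
#' @return an object of class `rotem_trace`: a list with elements `channel`,
#'   `times`, `amplitudes`.
#' @export
#' @examples
#' tr <- rotem_trace(c(0, 60, 120), c(0, 1, 4))
#' extract_mcf(tr)
rotem_trace <- function(times, amplitudes, channel = "extem") {
  if (!is.numeric(times) || !is.numeric(amplitudes))
    abort_invalid_input("times and amplitudes must be numeric")
  if (length(times) != length(amplitudes))
    abort_invalid_input("times and amplitudes must have the same length")
  if (anyNA(times) || anyNA(amplitudes) || any(!is.finite(times)) || any(!is.finite(amplitudes)))
    abort_invalid_input("times and amplitudes must be finite and non-missing")
  if (length(times) < 2L)
    abort_invalid_input("a trace needs at least 2 samples")
  if (is.unsorted(times))
    abort_invalid_input("times must be non-decreasing")
  if (any(amplitudes < 0))
    abort_invalid_input("amplitudes must be >= 0 mm")
  if (!is.character(channel) || length(channel) != 1L)
    abort_invalid_input("channel must be a single string")

  dup <- duplicated(times)
  if (any(dup)) {
    same <- vapply(which(dup), function(i) {
      amplitudes[i] == amplitudes[match(times[i], times)]
    }, logical(1))
    if (!all(same))
      abort_invalid_input("duplicate timestamps with conflicting amplitudes")
    times <- times[!dup]
    amplitudes <- amplitudes[!dup]
  }
  if (length(times) < 2L)
    abort_invalid_input("a trace needs at least 2 distinct time points")

  structure(list(channel = channel, times = as.numeric(times),
                 amplitudes = as.numeric(amplitudes)),
            class = "rotem_trace")
}

#' @export
print.rotem_trace <- function(x, ...) {
  cat(sprintf("<rotem_trace '%s': %d samples, %.1f-%.1f s, MCF %.1f mm>\n",
              x$channel, length(x$times), min(x$times), max(x$times),
              max(x$amplitudes)))
  invisible(x)
}

check_trace <- function(trace) {
  if (!inherits(trace, "rotem_trace"))
    abort_invalid_input("expected a rotem_trace object")
  if (anyDuplicated(trace$times))
    abort_invalid_input("trace has duplicate timestamps")
  invisible(trace)
}

# first time the piecewise-linear amplitude reaches `threshold` from below;
# NA_real_ if never reached.
first_crossing <- function(trace, threshold) {
  a <- trace$amplitudes
  t <- trace$times
  hit <- which(a >= threshold)
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1L]
  if (i == 1L) return(t[1L])
  # linear interpolation between bracketing samples
  t[i - 1L] + (threshold - a[i - 1L]) / (a[i] - a[i - 1L]) * (t[i] - t[i - 1L])
}

#' Clotting time (CT)
#'
#' Time from assay start until the amplitude first reaches a small threshold
#' (conventionally 2 mm); a measure of the initiation of clot formation.
#' Crossings are linearly interpolated between samples.
#'
#' @param trace a [rotem_trace].
#' @param threshold_mm amplitude threshold in mm (default 2, the usual ROTEM
#'   convention).
#' @return CT in seconds, or `NA_real_` if the threshold is never reached.
#' @export
extract_ct <- function(trace, threshold_mm = 2) {
  check_trace(trace)
  if (!is_scalar_number(threshold_mm) || threshold_mm <= 0)
    abort_invalid_parameter("threshold_mm must be a positive number")
  first_crossing(trace, threshold_mm)
}

#' Clot formation time (CFT)
#'
#' Time for the amplitude to rise from `low_mm` (the CT threshold) to
#' `high_mm`; the speed of clot formation. Weak clots — e.g. after ristocetin
#' in subjects with functional VWF — routinely never reach 20 mm, in which
#' case the CFT is absent.
#'
#' @inheritParams extract_ct
#' @param low_mm lower threshold in mm (default 2).
#' @param high_mm upper threshold in mm (default 20).
#' @return CFT in seconds, or `NA_real_` if `high_mm` is never reached.
#' @export
extract_cft <- function(trace, low_mm = 2, high_mm = 20) {
  check_trace(trace)
  if (!is_scalar_number(low_mm) || !is_scalar_number(high_mm))
    abort_invalid_parameter("low_mm and high_mm must be numbers")
  if (low_mm >= high_mm)
    abort_invalid_parameter("low_mm must be < high_mm")
  t_lo <- first_crossing(trace, low_mm)
  t_hi <- first_crossing(trace, high_mm)
  if (is.na(t_lo) || is.na(t_hi)) return(NA_real_)
  t_hi - t_lo
}

#' Maximum clot firmness (MCF)
#'
#' Maximum amplitude attained over the record; overall clot strength.
#'
#' @inheritParams extract_ct
#' @return MCF in mm.
#' @export
extract_mcf <- function(trace) {
  check_trace(trace)
  max(trace$amplitudes)
}

#' Clot-formation velocity curve
#'
#' First difference quotient of amplitude with respect to time, in mm per
#' minute, timestamped at interval midpoints. No smoothing is applied: the
#' only downstream use is the 30-minute area, which is smoothing-invariant.
#'
#' @inheritParams extract_ct
#' @return data.frame with columns `time_s` (interval midpoints) and
#'   `velocity_mm_min`.
#' @export
velocity_curve <- function(trace) {
  check_trace(trace)
  dt <- diff(trace$times)
  da <- diff(trace$amplitudes)
  data.frame(time_s = trace$times[-length(trace$times)] + dt / 2,
             velocity_mm_min = da / dt * 60)
}

# amplitude of the piecewise-linear trace at an arbitrary time inside its span
interp_amplitude <- function(trace, at) {
  stats::approx(trace$times, trace$amplitudes, xout = at, rule = 1)$y
}

#' Area under the clot-velocity curve at 30 minutes (AUC30)
#'
#' Integral of the first-derivative (velocity) curve of the amplitude trace
#' from assay start to 30 minutes, times a device scale factor. For a
#' piecewise-linear trace the velocity is piecewise constant and the integral
#' is exact; by the fundamental theorem of calculus it telescopes to
#' `scale * (amplitude(30 min) - amplitude(start))`, so for a zero-baseline
#' trace AUC30 is simply the scaled interpolated amplitude at 30 minutes.
#'
#' The scale factor reproduces device-magnitude AUC values (hundreds to
#' thousands); every downstream Ricotem statistic is a ratio of AUCs and is
#' therefore invariant to this choice.
#'
#' @inheritParams extract_ct
#' @param scale device scale factor (default 100).
#' @param end_min integration end in minutes (default 30).
#' @return scaled area (unitless device AUC), `>= 0` for non-decreasing
#'   traces.
#' @export
auc30 <- function(trace, scale = 100, end_min = 30) {
  check_trace(trace)
  if (!is_scalar_number(scale) || scale <= 0)
    abort_invalid_parameter("scale must be a positive number")
  end_s <- end_min * 60
  if (max(trace$times) < end_s)
    abort_insufficient_span(sprintf(
      "trace ends at %.1f s; %.0f min (%.0f s) required - no extrapolation",
      max(trace$times), end_min, end_s))
  start_s <- max(0, min(trace$times))
  scale * (interp_amplitude(trace, end_s) - interp_amplitude(trace, start_s))
}

#' Extract the standard clot parameters from one trace
#'
#' Convenience wrapper returning CT, CFT, MCF and AUC30 together. AUC30 is
#' `NA` when the trace does not span 30 minutes.
#'
#' @inheritParams auc30
#' @param ct_threshold_mm CT threshold in mm.
#' @param cft_high_mm upper CFT threshold in mm.
#' @return one-row data.frame with columns `channel`, `ct_s`, `cft_s`,
#'   `mcf_mm`, `auc30`.
#' @export
clot_parameters <- function(trace, ct_threshold_mm = 2, cft_high_mm = 20,
                            scale = 100) {
  check_trace(trace)
  auc <- tryCatch(auc30(trace, scale = scale),
                  ricotem_insufficient_span = function(e) NA_real_)
  data.frame(channel = trace$channel,
             ct_s = extract_ct(trace, ct_threshold_mm),
             cft_s = extract_cft(trace, ct_threshold_mm, cft_high_mm),
             mcf_mm = extract_mcf(trace),
             auc30 = auc)
}
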