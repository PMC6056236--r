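#' Generate a stochastic electrical vestibular stimulus (EVS)
#'
#' Draws Gaussian white noise, applies a zero-phase (forward-backward)
#' Butterworth low-pass filter, removes the mean, and rescales the trace so
#' that its largest absolute value equals \code{peak_mA}. The defaults give
#' the bandwidth-limited stimulus commonly used to probe vestibulo-motor
#' coupling: 0--20 Hz noise with a 4 mA peak, whose root-mean-square
#' amplitude is then an emergent property of the realization (typically
#' 1--1.5 mA) rather than an enforced one.
#'
#' @param duration_s Trial duration in seconds.
#' @param fs Sampling rate in Hz; must exceed twice \code{cutoff_hz}.
#' @param cutoff_hz Low-pass cutoff in Hz.
#' @param filter_order Order of the one-pass Butterworth filter (the
#'   forward-backward application doubles the effective attenuation).
#' @param peak_mA Target peak amplitude in mA; \code{0} yields an all-zero
#'   trace.
#' @param seed Integer seed; a fixed seed reproduces the trace bit for bit.
#' @return An object of class \code{evs_stimulus}: a list with
#'   \code{samples} (mA), \code{fs}, \code{cutoff_hz}, \code{filter_order},
#'   \code{peak_mA} and \code{seed}.
#' @examples
#' evs <- generate_evs(2, 250, seed = 1)
#' max(abs(evs$samples))  # exactly 4 mA
#' @export
generate_evs <- function(duration_s, fs, cutoff_hz = 20, filter_order = 4,
                         peak_mA = 4, seed = 1) {
  if (!is.finite(duration_s) || duration_s <= 0)
    stop_invalid("duration_s must be positive, got %s", format(duration_s))
  if (!is.finite(fs) || fs <= 2 * cutoff_hz)
    stop_invalid("fs (%s Hz) must exceed twice the cutoff (%s Hz)",
                 format(fs), format(cutoff_hz))
  if (filter_order < 1) stop_invalid("filter_order must be >= 1")
  if (peak_mA < 0) stop_invalid("peak_mA must be non-negative")
  n <- as.integer(round(duration_s * fs))
  set.seed(seed)
  x <- stats::rnorm(n)
  bf <- signal::butter(filter_order, cutoff_hz / (fs / 2), type = "low")
  x <- signal::filtfilt(bf, x)
  x <- x - mean(x)
  pk <- max(abs(x))
  x <- if (peak_mA == 0 || pk == 0) numeric(n) else x * (peak_mA / pk)
  structure(
    list(samples = x, fs = fs, cutoff_hz = cutoff_hz,
         filter_order = filter_order, peak_mA = peak_mA, seed = seed),
    class = "evs_stimulus"
  )
}

#' Describe how the stimulus couples into the shear force
#'
#' The body's mechanical response to a vestibular disturbance is modelled as
#' the stimulus passed through a low-pass filter (the musculoskeletal system
#' attenuates high frequencies), delayed by the latency of the
#' balance-correcting response, and multiplied by a possibly time-varying
#' gain. A zero-gain window can be specified to suspend the coupling around a
#' motor-state transition.
#'
#' @param gain Unitless (N per mA) multiplier: either a scalar or a vector
#'   with one value per stimulus sample.
#' @param lag_ms Response latency in ms (the medium-latency balance response
#'   is around 200 ms).
#' @param response_cutoff_hz Cutoff of the mechanical low-pass in Hz;
#'   \code{Inf} disables the filter.
#' @param null_window Optional \code{c(start_s, end_s)}: gain is forced to
#'   zero on this half-open interval of trial time.
#' @return An object of class \code{coupling_profile}.
#' @export
coupling_profile <- function(gain = 1, lag_ms = 200, response_cutoff_hz = 10,
                             null_window = NULL) {
  if (any(gain < 0)) stop_invalid("coupling gain must be non-negative")
  if (lag_ms < 0) stop_invalid("lag_ms must be non-negative")
  if (!is.null(null_window) &&
      (length(null_window) != 2 || null_window[2] < null_window[1]))
    stop_invalid("null_window must be c(start_s, end_s) with start <= end")
  structure(
    list(gain = gain, lag_ms = lag_ms,
         response_cutoff_hz = response_cutoff_hz, null_window = null_window),
    class = "coupling_profile"
  )
}

#' Shear-force response evoked by a vestibular stimulus
#'
#' Computes \code{gain(t) * [h * stimulus](t - lag)}, where \code{h} is a
#' zero-phase low-pass filter at the profile's response cutoff. Samples that
#' would require stimulus values from before the trial start are zero, and
#' the output is exactly zero inside the profile's null window.
#'
#' @param stimulus An \code{evs_stimulus}.
#' @param profile A \code{coupling_profile}.
#' @return Numeric vector of shear force (N), same length as the stimulus.
#' @export
coupling_response <- function(stimulus, profile) {
  stopifnot(inherits(stimulus, "evs_stimulus"),
            inherits(profile, "coupling_profile"))
  x <- stimulus$samples
  n <- length(x)
  if (n == 0) stop_invalid("stimulus is empty")
  fs <- stimulus$fs
  lag_n <- as.integer(round(profile$lag_ms / 1000 * fs))
  if (lag_n >= n) stop_invalid("lag (%s ms) exceeds the trial length",
                               format(profile$lag_ms))
  f <- if (is.finite(profile$response_cutoff_hz) &&
           profile$response_cutoff_hz < fs / 2) {
    lowpass_zerophase(x, fs, profile$response_cutoff_hz, order = 2)
  } else {
    x
  }
  shifted <- c(numeric(lag_n), f[seq_len(n - lag_n)])
  g <- rep_len(profile$gain, n)
  if (!is.null(profile$null_window)) {
    i0 <- min(max(sec_to_idx(profile$null_window[1], fs), 1L), n + 1L)
    i1 <- min(max(sec_to_idx(profile$null_window[2], fs), 1L), n + 1L)
    if (i1 > i0) g[i0:(i1 - 1L)] <- 0
  }
  g * shifted
}
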