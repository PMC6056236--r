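# Scale <-> frequency factor for the Morlet wavelet: the Fourier period of a
# Morlet at scale s is 4*pi*s / (omega0 + sqrt(2 + omega0^2)).
morlet_scale_factor <- function(omega0) (omega0 + sqrt(2 + omega0^2)) / (4 * pi)

# Continuous Morlet wavelet transform evaluated at the requested analysis
# frequencies, via FFT multiplication with the wavelet's frequency-domain
# form. The record is reflection-padded at both ends (then zero-padded to a
# power of two) to soften edge effects. Returns a complex matrix
# (samples x frequencies).
morlet_cwt <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  dt <- 1 / fs
  scales <- morlet_scale_factor(omega0) / freqs       # in seconds
  p <- min(n, as.integer(ceiling(4 * max(scales) * fs)))
  xp <- c(x[seq(p, 1L)], x, x[seq(n, n - p + 1L)])
  nfft <- 2^ceiling(log2(length(xp)))
  xp <- c(xp, numeric(nfft - length(xp)))
  xf <- stats::fft(xp)
  k <- 0:(nfft - 1)
  omega <- 2 * pi * ifelse(k <= nfft / 2, k, k - nfft) / (nfft * dt)
  pos <- omega > 0
  out <- matrix(0 + 0i, n, length(freqs))
  for (j in seq_along(freqs)) {
    s <- scales[j]
    psi <- numeric(nfft)
    psi[pos] <- pi^(-1 / 4) * sqrt(2 * pi * s / dt) *
      exp(-(s * omega[pos] - omega0)^2 / 2)
    w <- stats::fft(xf * psi, inverse = TRUE) / nfft
    out[, j] <- w[(p + 1L):(p + n)]
  }
  out
}

#' Single-trial Morlet auto- and cross-spectra
#'
#' Decomposes a stimulus record \code{x} and a force record \code{y} with a
#' continuous complex Morlet wavelet on a grid of analysis frequencies and
#' forms the time-dependent auto-spectra \eqn{P_{xx} = |W_x|^2},
#' \eqn{P_{yy} = |W_y|^2} and cross-spectrum
#' \eqn{P_{xy} = W_x \overline{W_y}}. Before the transform, \code{y} is
#' advanced by \code{lag_ms} relative to \code{x} so that force activity
#' occurring \code{lag_ms} after the stimulus (the latency of the
#' vestibular balance-correcting response) is aligned at zero lag; the
#' reported time axis is shifted back by \code{lag_ms}, so \code{tau_axis}
#' reads in force-record time.
#'
#' @param x Stimulus samples (or an \code{evs_stimulus}).
#' @param y Force samples, same length and rate as \code{x}.
#' @param fs Sampling rate in Hz.
#' @param freqs Analysis frequencies in Hz; default 1--20 Hz in 1 Hz steps
#'   (a Morlet cannot be evaluated at 0 Hz, so the "0--20 Hz" band starts
#'   at the 1 Hz grid point).
#' @param lag_ms Stimulus-to-response lag in ms (default 200).
#' @param omega0 Morlet centre parameter (default 6).
#' @return An object of class \code{timefreq_spectra} with matrices
#'   \code{pxx}, \code{pyy} (real, non-negative) and \code{pxy} (complex),
#'   each samples x frequencies, plus \code{tau_axis} (s), \code{freq_axis}
#'   (Hz), \code{lag_ms}, \code{fs}, \code{n_trials = 1} and a
#'   cone-of-influence vector \code{coi_s} (the e-folding time of edge
#'   effects at each frequency).
#' @export
morlet_spectra <- function(x, y, fs, freqs = 1:20, lag_ms = 200, omega0 = 6) {
  if (inherits(x, "evs_stimulus")) x <- x$samples
  if (length(x) != length(y))
    stop_invalid("x and y must have the same length (%d vs %d)",
                 length(x), length(y))
  if (any(freqs <= 0) || any(freqs > fs / 2))
    stop_invalid("analysis frequencies must lie in (0, fs/2]")
  n <- length(x)
  lag_n <- as.integer(round(lag_ms / 1000 * fs))
  if (lag_n >= n) stop_invalid("lag of %s ms exceeds the record", lag_ms)
  m <- n - lag_n
  xs <- x[seq_len(m)]
  ys <- y[seq_len(m) + lag_n]
  wx <- morlet_cwt(xs, fs, freqs, omega0)
  wy <- morlet_cwt(ys, fs, freqs, omega0)
  structure(
    list(pxx = Mod(wx)^2, pyy = Mod(wy)^2, pxy = wx * Conj(wy),
         tau_axis = (seq_len(m) - 1) / fs + lag_ms / 1000,
         freq_axis = freqs, lag_ms = lag_ms, fs = fs, n_trials = 1L,
         coi_s = sqrt(2) * morlet_scale_factor(omega0) / freqs,
         norm = NULL),
    class = "timefreq_spectra")
}

# Interpolate all spectral channels of a timefreq_spectra onto a new tau
# grid (linear interpolation; real and imaginary parts independently).
resample_spectra <- function(spectra, new_tau, new_axis = new_tau) {
  old <- spectra$tau_axis
  if (new_tau[1] < old[1] - 1e-9 ||
      new_tau[length(new_tau)] > old[length(old)] + 1e-9)
    stop_invalid("requested window [%g, %g] s exceeds the record [%g, %g] s",
                 new_tau[1], new_tau[length(new_tau)], old[1],
                 old[length(old)])
  interp <- function(v) stats::approx(old, v, xout = new_tau, rule = 2)$y
  out <- spectra
  out$pxx <- apply(spectra$pxx, 2, interp)
  out$pyy <- apply(spectra$pyy, 2, interp)
  out$pxy <- apply(Re(spectra$pxy), 2, interp) +
    1i * apply(Im(spectra$pxy), 2, interp)
  out$tau_axis <- new_axis
  out
}

#' Movement-time normalization of trial spectra
#'
#' Stretches or compresses the movement time of a trial's spectra so that
#' trials with different step timing can be averaged. For locomotor
#' initiation the extracted window runs from 2D before the transition onset
#' to D after it (D = onset to third toe-off), mapped onto a normalized
#' axis from -2 to 1 with the onset at 0. For termination it runs from D
#' before the transition end (D = third-to-last heel-strike to transition
#' end) to 2D after, mapped onto -1 to 2 with the end at 0. Auto- and
#' cross-spectra are linearly interpolated (real and imaginary parts
#' independently) onto \code{target_len} points.
#'
#' @param spectra A \code{timefreq_spectra}.
#' @param seg A \code{phase_segmentation} providing the markers and D.
#' @param target_len Common number of time points after resampling
#'   (typically the average segment length across trials).
#' @param protocol Protocol name.
#' @return A \code{timefreq_spectra} whose \code{tau_axis} is in normalized
#'   movement-time units (D = 1).
#' @export
normalize_movement_time <- function(spectra, seg, target_len, protocol) {
  stopifnot(inherits(spectra, "timefreq_spectra"),
            inherits(seg, "phase_segmentation"))
  D <- seg$D
  if (protocol == "locomotor_termination") {
    marker <- (seg$transition_end - 1) / seg$fs
    lo <- -1; hi <- 2
  } else {
    marker <- (seg$transition_onset - 1) / seg$fs
    lo <- -2; hi <- 1
  }
  axis_norm <- seq(lo, hi, length.out = target_len)
  new_tau <- marker + D * axis_norm
  out <- resample_spectra(spectra, new_tau, new_axis = axis_norm)
  out$norm <- list(mode = "movement_time", D = D, marker_s = marker,
                   span = c(lo, hi))
  out
}

#' Extract a fixed-width window of spectra centred on a transition marker
#'
#' For the non-normalized analyses the transition marker is placed in the
#' middle of a fixed window (3 s for locomotor protocols, 7 s for the
#' posture protocol) and the spectra are re-gridded onto a tau axis
#' relative to the marker, so that windows from different trials share one
#' axis and can be averaged.
#'
#' @param spectra A \code{timefreq_spectra}.
#' @param center_s Marker time in s (force-record time).
#' @param width_s Window width in s.
#' @return A \code{timefreq_spectra} with \code{tau_axis} running from
#'   \code{-width_s/2} to \code{width_s/2}, marker at 0.
#' @export
center_window <- function(spectra, center_s, width_s) {
  stopifnot(inherits(spectra, "timefreq_spectra"))
  fs <- spectra$fs
  half <- width_s / 2
  rel <- seq(-round(half * fs), round(half * fs)) / fs
  out <- resample_spectra(spectra, center_s + rel, new_axis = rel)
  out$norm <- list(mode = "centered", marker_s = center_s, width_s = width_s)
  out
}

#' Trial-averaged wavelet coherence
#'
#' Averages auto- and cross-spectra across trials and forms the
#' time-frequency coherence
#' \deqn{C(\tau,f) = \frac{|\bar P_{xy}(\tau,f)|^2}
#'   {\bar P_{xx}(\tau,f)\,\bar P_{yy}(\tau,f)},}
#' which lies in [0, 1] by the Cauchy-Schwarz inequality. With a single
#' trial the ratio is identically 1 (no averaging, hence no magnitude
#' penalty for phase inconsistency), which is why the significance limit is
#' defined only for two or more trials.
#'
#' @param spectra_list List of \code{timefreq_spectra} sharing tau and
#'   frequency axes.
#' @param alpha Significance level for the confidence limit (default 0.01,
#'   the 99\% limit).
#' @return An object of class \code{coherence_map}: matrix \code{c}
#'   (time x frequency), axes, trial count \code{L}, \code{alpha} and the
#'   confidence limit \code{cl} (\code{NA} when \code{L = 1}).
#' @export
average_and_cohere <- function(spectra_list, alpha = 0.01) {
  if (inherits(spectra_list, "timefreq_spectra"))
    spectra_list <- list(spectra_list)
  L <- length(spectra_list)
  if (L < 1) stop_invalid("need at least one trial")
  ref <- spectra_list[[1]]
  for (s in spectra_list[-1]) {
    if (length(s$tau_axis) != length(ref$tau_axis) ||
        max(abs(s$tau_axis - ref$tau_axis)) > 1e-6 ||
        length(s$freq_axis) != length(ref$freq_axis) ||
        max(abs(s$freq_axis - ref$freq_axis)) > 1e-9)
      stop_invalid("trials do not share tau/frequency axes")
  }
  pxx <- Reduce(`+`, lapply(spectra_list, `[[`, "pxx")) / L
  pyy <- Reduce(`+`, lapply(spectra_list, `[[`, "pyy")) / L
  pxy <- Reduce(`+`, lapply(spectra_list, `[[`, "pxy")) / L
  cmat <- Mod(pxy)^2 / (pxx * pyy)
  cmat[!is.finite(cmat)] <- 0
  structure(
    list(c = cmat, tau_axis = ref$tau_axis, freq_axis = ref$freq_axis,
         L = L, alpha = alpha,
         cl = if (L >= 2) coherence_confidence_limit(L, alpha) else NA_real_,
         lag_ms = ref$lag_ms, norm = ref$norm),
    class = "coherence_map")
}

#' Streaming accumulation of trial spectra
#'
#' \code{coherence_accumulator} starts an empty running sum of auto- and
#' cross-spectra; \code{add_trial_spectra} folds one trial in;
#' \code{accumulated_coherence} returns the trial-averaged
#' \code{coherence_map}. Equivalent to collecting all trials in a list and
#' calling \code{\link{average_and_cohere}}, but with constant memory --
#' useful when averaging hundreds of full-length trial spectra or pooling
#' across subjects.
#'
#' @return \code{coherence_accumulator()}: an accumulator;
#'   \code{add_trial_spectra()}: the updated accumulator;
#'   \code{accumulated_coherence()}: a \code{coherence_map}.
#' @export
coherence_accumulator <- function() {
  structure(list(L = 0L, pxx = NULL, pyy = NULL, pxy = NULL,
                 tau_axis = NULL, freq_axis = NULL, lag_ms = NULL,
                 norm = NULL),
            class = "coherence_accumulator")
}

#' @rdname coherence_accumulator
#' @param acc A \code{coherence_accumulator}.
#' @param spectra A \code{timefreq_spectra}.
#' @export
add_trial_spectra <- function(acc, spectra) {
  stopifnot(inherits(acc, "coherence_accumulator"),
            inherits(spectra, "timefreq_spectra"))
  if (acc$L == 0L) {
    acc$pxx <- spectra$pxx
    acc$pyy <- spectra$pyy
    acc$pxy <- spectra$pxy
    acc$tau_axis <- spectra$tau_axis
    acc$freq_axis <- spectra$freq_axis
    acc$lag_ms <- spectra$lag_ms
    acc$norm <- spectra$norm
  } else {
    if (length(spectra$tau_axis) != length(acc$tau_axis) ||
        max(abs(spectra$tau_axis - acc$tau_axis)) > 1e-6 ||
        length(spectra$freq_axis) != length(acc$freq_axis))
      stop_invalid("trial does not share the accumulator's axes")
    acc$pxx <- acc$pxx + spectra$pxx
    acc$pyy <- acc$pyy + spectra$pyy
    acc$pxy <- acc$pxy + spectra$pxy
  }
  acc$L <- acc$L + 1L
  acc
}

#' @rdname coherence_accumulator
#' @param alpha Significance level for the confidence limit.
#' @export
accumulated_coherence <- function(acc, alpha = 0.01) {
  stopifnot(inherits(acc, "coherence_accumulator"))
  if (acc$L < 1L) stop_invalid("accumulator is empty")
  L <- acc$L
  cmat <- Mod(acc$pxy / L)^2 / ((acc$pxx / L) * (acc$pyy / L))
  cmat[!is.finite(cmat)] <- 0
  structure(
    list(c = cmat, tau_axis = acc$tau_axis, freq_axis = acc$freq_axis,
         L = L, alpha = alpha,
         cl = if (L >= 2) coherence_confidence_limit(L, alpha) else NA_real_,
         lag_ms = acc$lag_ms, norm = acc$norm),
    class = "coherence_map")
}

#' Significance threshold for trial-averaged coherence
#'
#' Closed-form confidence limit for magnitude coherence averaged over
#' \code{L} independent segments: \eqn{1 - \alpha^{1/(L-1)}}. Estimated
#' coherence below this value is indistinguishable from zero coupling at
#' level \code{alpha}. At the 99\% level this gives 0.045 for L = 100,
#' 0.005 for L = 1000 and 0.008 for L = 600 (3-decimal rounding).
#'
#' @param L Number of averaged segments (>= 2).
#' @param alpha Significance level in (0, 1).
#' @return Threshold in (0, 1).
#' @export
coherence_confidence_limit <- function(L, alpha = 0.01) {
  if (any(L < 2)) stop_invalid("confidence limit requires L >= 2 segments")
  if (any(alpha <= 0 | alpha >= 1)) stop_invalid("alpha must be in (0, 1)")
  1 - alpha^(1 / (L - 1))
}

#' Band-averaged coherence time course
#'
#' Arithmetic mean of the coherence over the grid frequencies inside
#' \code{[f_lo, f_hi]} at each time point; the temporal evolution of the
#' coherence in a band (0--10 Hz in the standard analyses, i.e. grid
#' points 1--10 Hz).
#'
#' @param map A \code{coherence_map}.
#' @param f_lo,f_hi Band limits in Hz (inclusive).
#' @return \code{data.frame(tau, coherence)}.
#' @export
band_average <- function(map, f_lo = 1, f_hi = 10) {
  stopifnot(inherits(map, "coherence_map"))
  sel <- map$freq_axis >= f_lo & map$freq_axis <= f_hi
  if (!any(sel)) stop_invalid("no analysis frequencies in [%g, %g] Hz",
                              f_lo, f_hi)
  data.frame(tau = map$tau_axis,
             coherence = rowMeans(map$c[, sel, drop = FALSE]))
}

#' Zero out non-significant coherence
#'
#' Sets every coherence value that does not exceed the map's confidence
#' limit to zero (the threshold is exclusive: values equal to the limit are
#' non-significant).
#'
#' @param map A \code{coherence_map} with a finite confidence limit.
#' @return The masked \code{coherence_map}.
#' @export
mask_nonsignificant <- function(map) {
  stopifnot(inherits(map, "coherence_map"))
  if (!is.finite(map$cl))
    stop_invalid("map has no confidence limit (single-trial coherence)")
  map$c[map$c <= map$cl] <- 0
  map
}
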