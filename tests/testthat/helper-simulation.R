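# Shared fixtures, all generated in code.

# Minimal hand-built timefreq_spectra (bypasses the wavelet transform) for
# algebra-level tests of averaging, resampling and coherence.
make_spectra <- function(wx, wy, tau, freqs, fs = 250, lag_ms = 0) {
  structure(
    list(pxx = Mod(wx)^2, pyy = Mod(wy)^2, pxy = wx * Conj(wy),
         tau_axis = tau, freq_axis = freqs, lag_ms = lag_ms, fs = fs,
         n_trials = 1L, coi_s = rep(0, length(freqs)), norm = NULL),
    class = "timefreq_spectra")
}

# Spectra of one trial of mutually independent stimulus/force noise.
independent_noise_spectra <- function(duration_s, fs, seed, freqs = 1:20) {
  x <- generate_evs(duration_s, fs, seed = seed)$samples
  set.seed(seed + 500000L)
  y <- stats::rnorm(length(x))
  morlet_spectra(x, y, fs, freqs = freqs, lag_ms = 200)
}

# Simulate one initiation trial and return its spectra windowed around the
# detected transition onset, together with the trial's ground truth.
initiation_window <- function(seed, width_s = 3, coupling = list(),
                              fs = 250) {
  cfg <- simulation_config("locomotor_initiation", fs = fs, seed = seed,
                           coupling = coupling)
  tr <- simulate_trial(cfg)
  res <- analyze_trial_events(tr)
  marker <- (res$transition$onset - 1) / fs
  shear <- tr$plates[[1]]$fy_N + tr$plates[[2]]$fy_N
  sp <- morlet_spectra(tr$stimulus$samples, shear, fs, lag_ms = 200)
  list(window = center_window(sp, marker, width_s), truth = tr$truth,
       marker = marker, seg = res$segmentation)
}

# Average coherence of the masked map over tau bins falling inside a list
# of c(start_s, end_s) intervals given relative to a marker.
masked_mean_in <- function(map, intervals, marker) {
  sel <- rep(FALSE, length(map$tau_axis))
  for (iv in intervals) {
    sel <- sel | (map$tau_axis >= iv[1] - marker &
                    map$tau_axis < iv[2] - marker)
  }
  if (!any(sel)) return(NA_real_)
  mean(map$c[sel, ])
}
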