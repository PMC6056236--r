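#' @keywords internal
"_PACKAGE"

# Derive a reproducible 31-bit sub-seed from a trial seed and a component
# counter, so each random component (stimulus, sway, noise, timing jitter)
# draws from its own stream and adding a component never perturbs the
# others. Constant-time Lehmer-style mixing; every product stays below
# 2^53, so the arithmetic is exact in doubles.
sub_seed <- function(seed, counter) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + ((as.numeric(counter) %% m) + 1) * 69621) %% m
  s <- (s * 48271) %% m
  as.integer(s)
}

# Zero-phase (forward-backward) Butterworth low-pass. `order` is the order of
# the underlying one-pass filter; filtfilt doubles the effective order and
# cancels the phase, matching the usual "zero lag" description. The record is
# extended at both ends by odd (point-symmetric) reflection before filtering
# so that signals with a non-zero level or trend do not pick up start-up
# transients.
lowpass_zerophase <- function(x, fs, cutoff_hz, order = 2) {
  stopifnot(fs > 2 * cutoff_hz)
  n <- length(x)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  p <- min(n - 1L, as.integer(ceiling(3 * fs / cutoff_hz)) * 10L)
  if (p < 1L) return(signal::filtfilt(bf, x))
  head_pad <- 2 * x[1] - x[seq(p + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - p)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(p + 1L):(p + n)]
}

# Low-pass-filtered Gaussian noise rescaled to a target RMS (used for postural
# sway on the CoP and shear channels). Extra samples are generated and the
# filter warm-up cropped so the retained stretch is stationary.
filtered_noise <- function(n, fs, cutoff_hz, rms, seed) {
  set.seed(seed)
  m <- as.integer(ceiling(4 * fs / cutoff_hz))
  x <- stats::rnorm(n + 2L * m)
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  x <- signal::filtfilt(bf, x)[(m + 1L):(m + n)]
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s > 0) x <- x * (rms / s)
  x
}

# Raised-cosine ramp from 0 to 1 over n samples.
raised_cosine <- function(n) {
  if (n <= 1) return(rep(1, max(n, 0)))
  (1 - cos(pi * seq(0, 1, length.out = n))) / 2
}

# Half-open [start, end) sample interval in seconds -> 1-based index range.
sec_to_idx <- function(t, fs) as.integer(round(t * fs)) + 1L

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

# Contiguous runs of TRUE in a logical vector: data.frame(start, end) with
# half-open [start, end) 1-based indices.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep] + 1L)
}

# FNV-1a hash of a character scalar, reported as 8 hex digits. Used to stamp
# output files with the configuration they came from. The xor only touches the
# low byte (input bytes are < 256), so it can be done exactly in doubles.
fnv1a_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- bitwXor(as.integer(h %% 256), b)
    h <- h - (h %% 256) + low
    # 32-bit modular multiply split into 16-bit halves to stay exact in doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}
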