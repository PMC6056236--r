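# Direct (time-domain) convolution with the analytic Morlet wavelet at one
# frequency and one time point -- an independent oracle for the FFT path.
direct_morlet_power <- function(x, fs, f, tau_idx, omega0 = 6) {
  s <- vestcoh:::morlet_scale_factor(omega0) / f
  half <- round(4 * s * fs)
  k <- (-half):half
  t <- k / fs
  psi <- pi^(-1 / 4) / sqrt(s) * exp(1i * omega0 * t / s - t^2 / (2 * s^2))
  idx <- tau_idx + k
  keep <- idx >= 1 & idx <= length(x)
  Mod(sum(x[idx[keep]] * Conj(psi[keep])) / fs)^2
}

test_that("identical inputs give a cross-spectrum equal to the auto-spectrum", {
  x <- generate_evs(5, 250, seed = 1)$samples
  sp <- morlet_spectra(x, x, 250, lag_ms = 0)
  expect_equal(Re(sp$pxy), sp$pxx, tolerance = 1e-12)
  expect_lt(max(abs(Im(sp$pxy))), 1e-12 * max(sp$pxx))
  expect_true(all(sp$pxx >= 0) && all(sp$pyy >= 0))
})

test_that("a 5 Hz sinusoid peaks at the 5 Hz grid point, matching the
          direct-convolution oracle", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  x <- sin(2 * pi * 5 * t)
  sp <- morlet_spectra(x, x, fs, lag_ms = 0)
  med <- apply(sp$pxx, 2, median)
  expect_equal(sp$freq_axis[which.max(med)], 5)
  mid <- length(x) %/% 2
  oracle <- sapply(sp$freq_axis, function(f)
    direct_morlet_power(x, fs, f, mid))
  expect_equal(sp$freq_axis[which.max(oracle)], 5)
  # shape agreement between FFT path and direct convolution at mid-record
  expect_equal(sp$pxx[mid, ] / max(sp$pxx[mid, ]), oracle / max(oracle),
               tolerance = 0.02)
})

test_that("a 200 ms delayed copy analyzed at 200 ms lag has zero phase", {
  fs <- 250
  x <- generate_evs(30, fs, seed = 2)$samples
  lag_n <- 50
  y <- c(numeric(lag_n), x[seq_len(length(x) - lag_n)])
  sp <- morlet_spectra(x, y, fs, lag_ms = 200)
  mid <- nrow(sp$pxy) %/% 2
  ph <- Arg(sp$pxy[mid, sp$freq_axis <= 10])
  expect_true(all(abs(ph) < 0.05))
})

test_that("mismatched lengths and oversized lags are rejected", {
  expect_error(morlet_spectra(1:100, 1:99, 250), "length")
  expect_error(morlet_spectra(rnorm(100), rnorm(100), 250, lag_ms = 2000),
               "lag")
  expect_error(morlet_spectra(rnorm(100), rnorm(100), 250, freqs = c(0, 5)),
               "frequencies")
})

test_that("the reported tau axis is shifted by the analysis lag", {
  x <- rnorm(1000)
  sp <- morlet_spectra(x, x, 250, lag_ms = 200)
  expect_equal(sp$tau_axis[1], 0.2)
})

test_that("resampling to the same grid is the identity", {
  tau <- (0:99) / 50
  wx <- matrix(complex(real = rnorm(500), imaginary = rnorm(500)), 100, 5)
  wy <- matrix(complex(real = rnorm(500), imaginary = rnorm(500)), 100, 5)
  sp <- make_spectra(wx, wy, tau, 1:5, fs = 50)
  out <- vestcoh:::resample_spectra(sp, tau)
  expect_equal(out$pxx, sp$pxx, tolerance = 1e-9)
  expect_equal(out$pxy, sp$pxy, tolerance = 1e-9)
})

test_that("movement-time normalization preserves constants and lines", {
  fs <- 100
  n <- 1200
  tau <- (0:(n - 1)) / fs
  const <- matrix(2.5, n, 3)
  line <- matrix(rep(seq(0, 1, length.out = n), 3), n, 3)
  sp <- make_spectra(matrix(1 + 0i, n, 3), matrix(1 + 0i, n, 3), tau, 1:3,
                     fs = fs)
  sp$pxx <- line
  sp$pyy <- const
  seg <- vestcoh:::new_segmentation(onset = 601, end = 701,
                                    phases = list(), D = 2, fs = fs)
  seg$D <- 2                                       # window [2 s, 8 s)
  out <- normalize_movement_time(sp, seg, target_len = 301,
                                 protocol = "locomotor_initiation")
  expect_equal(out$pyy, matrix(2.5, 301, 3))
  # the line t/tau_max sampled at the window's tau positions
  expect_tau <- 6 + 2 * seq(-2, 1, length.out = 301)
  expect_equal(out$pxx[, 1], expect_tau / tau[n] * 1, tolerance = 1e-9)
  expect_equal(out$tau_axis, seq(-2, 1, length.out = 301))
})

test_that("windows that exceed the record are rejected", {
  sp <- make_spectra(matrix(1 + 0i, 100, 2), matrix(1 + 0i, 100, 2),
                     (0:99) / 50, 1:2, fs = 50)
  expect_error(center_window(sp, 0.1, 3), "exceeds")
})

test_that("coherence is identically one for a single trial and for y = x", {
  sp <- independent_noise_spectra(5, 250, seed = 3)
  m1 <- average_and_cohere(list(sp))
  expect_equal(unname(range(m1$c)), c(1, 1))
  expect_true(is.na(m1$cl))
  trials <- lapply(1:4, function(s) {
    x <- generate_evs(4, 250, seed = s)$samples
    morlet_spectra(x, x, 250, lag_ms = 0)
  })
  m <- average_and_cohere(trials)
  expect_equal(unname(range(m$c)), c(1, 1), tolerance = 1e-12)
})

test_that("coherence lies in [0, 1] for arbitrary random spectra", {
  set.seed(99)
  for (L in c(2, 3, 7)) {
    trials <- lapply(seq_len(L), function(i) {
      wx <- matrix(complex(real = rnorm(600), imaginary = rnorm(600)), 200, 3)
      wy <- matrix(complex(real = rnorm(600), imaginary = rnorm(600)), 200, 3)
      make_spectra(wx, wy, (0:199) / 100, 1:3, fs = 100)
    })
    m <- average_and_cohere(trials)
    expect_true(all(m$c >= 0 & m$c <= 1))
  }
})

test_that("coherence is invariant to per-trial positive rescaling", {
  trials <- lapply(1:5, function(s) independent_noise_spectra(3, 250, 40 + s))
  m0 <- average_and_cohere(trials)
  scaled <- lapply(trials, function(sp) {
    sp$pxx <- 4 * sp$pxx          # x scaled by 2
    sp$pyy <- 9 * sp$pyy          # y scaled by 3
    sp$pxy <- 6 * sp$pxy
    sp
  })
  m1 <- average_and_cohere(scaled)
  expect_equal(m0$c, m1$c, tolerance = 1e-12)
})

test_that("axis mismatches between trials are rejected", {
  a <- make_spectra(matrix(1 + 0i, 10, 2), matrix(1 + 0i, 10, 2),
                    (0:9) / 10, 1:2, fs = 10)
  b <- make_spectra(matrix(1 + 0i, 10, 2), matrix(1 + 0i, 10, 2),
                    (0:9) / 10 + 0.5, 1:2, fs = 10)
  expect_error(average_and_cohere(list(a, b)), "axes")
})

test_that("the accumulator reproduces list-based averaging exactly", {
  trials <- lapply(1:6, function(s) independent_noise_spectra(2, 250, 70 + s))
  m_list <- average_and_cohere(trials)
  acc <- coherence_accumulator()
  for (tr in trials) acc <- add_trial_spectra(acc, tr)
  m_acc <- accumulated_coherence(acc)
  expect_equal(m_acc$c, m_list$c, tolerance = 1e-12)
  expect_equal(m_acc$L, m_list$L)
  expect_equal(m_acc$cl, m_list$cl)
})

test_that("the confidence limit reproduces the printed thresholds", {
  expect_equal(round(coherence_confidence_limit(100, 0.01), 3), 0.045)
  expect_equal(round(coherence_confidence_limit(1000, 0.01), 3), 0.005)
  expect_equal(round(coherence_confidence_limit(600, 0.01), 3), 0.008)
  expect_equal(coherence_confidence_limit(2, 0.01), 0.99)
})

test_that("the confidence limit falls with more trials and rises with the
          confidence level", {
  L <- c(2, 5, 10, 50, 100, 500, 1000)
  expect_true(all(diff(coherence_confidence_limit(L, 0.01)) < 0))
  # a stricter significance level (higher confidence) raises the threshold
  a <- c(0.001, 0.01, 0.05, 0.2)
  expect_true(all(diff(coherence_confidence_limit(100, a)) < 0))
  expect_error(coherence_confidence_limit(1, 0.01), "L >= 2")
  expect_error(coherence_confidence_limit(10, 1.5), "alpha")
})

test_that("exceedance of the limit under independence matches alpha", {
  set.seed(7)
  L <- 40
  reps <- 30
  for (alpha in c(0.05, 0.01)) {
    cl <- coherence_confidence_limit(L, alpha)
    hits <- replicate(reps, {
      wx <- matrix(complex(real = rnorm(L * 50), imaginary = rnorm(L * 50)),
                   L, 50)
      wy <- matrix(complex(real = rnorm(L * 50), imaginary = rnorm(L * 50)),
                   L, 50)
      pxy <- colMeans(wx * Conj(wy))
      co <- Mod(pxy)^2 / (colMeans(Mod(wx)^2) * colMeans(Mod(wy)^2))
      mean(co > cl)
    })
    expect_lt(abs(mean(hits) - alpha), 0.4 * alpha + 0.003)
  }
})

test_that("band averaging is the arithmetic mean over in-band frequencies", {
  cmat <- matrix(0, 50, 20)
  map <- structure(list(c = cmat + 0.3, tau_axis = (0:49) / 10,
                        freq_axis = 1:20, L = 10, alpha = 0.01,
                        cl = 0.1, lag_ms = 0, norm = NULL),
                   class = "coherence_map")
  b <- band_average(map, 1, 10)
  expect_equal(b$coherence, rep(0.3, 50))
  map$c[] <- 0
  map$c[, 4] <- 1                      # one in-band frequency out of ten
  expect_equal(band_average(map, 1, 10)$coherence, rep(0.1, 50))
  expect_error(band_average(map, 30, 40), "frequencies")
})

test_that("masking zeroes exactly the non-significant cells", {
  cmat <- matrix(c(0.02, 0.045, 0.0451, 0.2), 2, 2)
  map <- structure(list(c = cmat, tau_axis = 1:2, freq_axis = 1:2,
                        L = 100, alpha = 0.01, cl = 0.045, lag_ms = 0,
                        norm = NULL),
                   class = "coherence_map")
  out <- mask_nonsignificant(map)
  expect_equal(out$c, matrix(c(0, 0, 0.0451, 0.2), 2, 2))
})
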