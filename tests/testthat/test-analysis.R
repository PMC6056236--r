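make_map <- function(cmat, tau, freqs = seq_len(ncol(cmat)), cl = 0.045,
                     L = 100) {
  structure(list(c = cmat, tau_axis = tau, freq_axis = freqs, L = L,
                 alpha = 0.01, cl = cl, lag_ms = 0, norm = NULL),
            class = "coherence_map")
}

test_that("a series that never drops below the limit yields no null period", {
  b <- data.frame(tau = seq(-1.5, 1.5, by = 0.01), coherence = 0.3)
  np <- detect_null_period(b, 0.045, 0)
  expect_false(np$found)
  expect_equal(np$duration, 0)
})

test_that("a constructed sub-limit run is recovered exactly", {
  tau <- seq(4, 8, by = 0.004)
  co <- rep(0.3, length(tau))
  co[tau >= 5.6 & tau < 6.4] <- 0.01
  np <- detect_null_period(data.frame(tau = tau, coherence = co), 0.045,
                           6.0, search_s = 1.5)
  expect_true(np$found)
  expect_equal(np$onset_lead, 0.4, tolerance = 0.005)
  expect_equal(np$duration, 0.8, tolerance = 0.005)
})

test_that("a run preceding the marker is used when none contains it", {
  tau <- seq(-2, 2, by = 0.01)
  co <- rep(0.3, length(tau))
  co[tau >= -1.2 & tau < -0.7] <- 0.01
  np <- detect_null_period(data.frame(tau = tau, coherence = co), 0.045, 0)
  expect_true(np$found)
  expect_equal(np$drop_time, -1.2, tolerance = 0.005)
  expect_equal(np$duration, 0.5, tolerance = 0.005)
})

test_that("a marker outside the series is rejected", {
  b <- data.frame(tau = seq(0, 1, by = 0.01), coherence = 0.3)
  expect_error(detect_null_period(b, 0.045, 5), "outside")
})

test_that("per-phase peaks and the tie-breaking rule are honoured", {
  tau <- seq(-1, 1, by = 0.01)
  cmat <- matrix(0, length(tau), 20)
  cmat[tau >= 0.2 & tau < 0.3, 6] <- 0.4
  map <- make_map(cmat, tau)
  pk <- peak_by_phase(map, list(standing = c(-1, 0), transition = c(0, 1)))
  expect_equal(pk$peak[pk$phase == "transition"], 0.4)
  expect_equal(pk$freq[pk$phase == "transition"], 6)
  # uniform map: ties resolve to the lowest frequency, earliest time
  uni <- make_map(matrix(0.2, length(tau), 20), tau)
  pk <- peak_by_phase(uni, list(all = c(-1, 1)))
  expect_equal(pk$freq, 1)
  expect_equal(pk$tau, -1)
  expect_equal(pk$peak, 0.2)
  expect_error(peak_by_phase(map, list(late = c(5, 6))), "empty")
})

test_that("phases with larger injected gain carry larger peaks", {
  hi_lo <- replicate(10, NA)
  reps <- 10
  wins <- 0
  for (r in seq_len(reps)) {
    acc <- coherence_accumulator()
    for (i in 1:20) {
      w <- initiation_window(
        seed = 5000 + r * 100 + i,
        coupling = list(standing_gain = 0.3, transition_gain = 0.08,
                        swing_gain = 0.08, null_window = NULL))
      acc <- add_trial_spectra(acc, w$window)
    }
    m <- accumulated_coherence(acc)
    pk <- peak_by_phase(m, list(standing = c(-1.5, -0.2),
                                transition = c(0, 0.5)))
    wins <- wins + (pk$peak[pk$phase == "standing"] >
                      pk$peak[pk$phase == "transition"])
  }
  expect_gte(wins, 9)
})

test_that("pooling identical single-trial stacks leaves coherence at one", {
  stacks <- lapply(1:10, function(s) {
    x <- generate_evs(3, 250, seed = s)$samples
    list(morlet_spectra(x, x, 250, lag_ms = 0))
  })
  m <- pool_subjects(stacks)
  expect_equal(unname(range(m$c)), c(1, 1), tolerance = 1e-12)
  expect_equal(m$L, 10)
})

test_that("pooling a stack with itself leaves the coherence unchanged", {
  stack <- lapply(1:5, function(s) independent_noise_spectra(2, 250, 90 + s))
  m1 <- pool_subjects(list(stack))
  m2 <- pool_subjects(list(stack, stack))
  expect_equal(m1$c, m2$c, tolerance = 1e-12)
  expect_equal(m2$L, 10)
})

test_that("null-period recovery error shrinks with more trials", {
  wins <- lapply(1:75, function(i) initiation_window(seed = 8200 + i))
  err <- sapply(c(25, 75), function(L) {
    acc <- coherence_accumulator()
    for (i in seq_len(L)) acc <- add_trial_spectra(acc, wins[[i]]$window)
    m <- accumulated_coherence(acc)
    b <- band_average(m, 1, 10)
    np <- detect_null_period(b, m$cl, 0, search_s = 1.5)
    abs(np$onset_lead - 0.4) + abs(np$duration - 0.8)
  })
  expect_lte(err[2], err[1] + 0.05)
})
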