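make_const_trial <- function(fz_total = 800, n = 5000, fs = 250,
                             noise_sd = 0, seed = 1) {
  set.seed(seed)
  plate <- function(frac) list(
    fx_N = numeric(n), fy_N = numeric(n),
    fz_N = fz_total * frac + rnorm(n, 0, noise_sd * frac),
    cop_x_m = numeric(n), cop_y_m = numeric(n))
  structure(list(stimulus = NULL,
                 plates = list(plate(0.5), plate(0.5)), fs = fs,
                 protocol = "locomotor_initiation",
                 head_orientation = "forward", body_weight_N = fz_total,
                 truth = NULL),
            class = "trial_recording")
}

test_that("body weight is the baseline mean of the total vertical force", {
  tr <- make_const_trial(800)
  expect_equal(estimate_body_weight(tr, c(0, 10)), 800)
})

test_that("body weight estimate respects the noise standard error", {
  # SD 5 N split over two plates, 5000 samples: SE = 5/sqrt(5000) = 0.07 N
  set.seed(42)
  n <- 5000
  plate <- function() list(fx_N = numeric(n), fy_N = numeric(n),
                           fz_N = 400 + rnorm(n, 0, 5 / sqrt(2)),
                           cop_x_m = numeric(n), cop_y_m = numeric(n))
  tr <- structure(list(plates = list(plate(), plate()), fs = 250,
                       protocol = "locomotor_initiation",
                       head_orientation = "forward", body_weight_N = 800),
                  class = "trial_recording")
  expect_lt(abs(estimate_body_weight(tr, c(0, 20)) - 800), 0.3)
})

test_that("an empty or out-of-range baseline is rejected", {
  tr <- make_const_trial()
  expect_error(estimate_body_weight(tr, c(5, 5)), "baseline")
  expect_error(estimate_body_weight(tr, c(100, 200)), "baseline")
})

test_that("toe-off is the first sample below five percent of body weight", {
  fs <- 250
  bw <- 800
  # trapezoid dropping below 0.05*bw = 40 N first at sample 1200
  fz <- rep(400, 2000)
  fz[1150:1199] <- seq(400, 41, length.out = 50)
  fz[1200:1400] <- 10
  fz[1401:1450] <- seq(10, 400, length.out = 50)
  fz[1451:2000] <- 400
  ev <- detect_gait_events(cbind(foot = fz), bw, fs)
  expect_equal(ev$per_foot[[1]]$toe_offs, 1200)
  # heel-strike: first sample back above threshold after the toe-off
  expect_equal(ev$per_foot[[1]]$heel_strikes,
               1400 + which(fz[1401:1450] >= 40)[1])
})

test_that("force that never crosses the threshold yields no events", {
  ev <- detect_gait_events(cbind(rep(300, 1000)), 800, 250)
  expect_length(ev$per_foot[[1]]$toe_offs, 0)
  expect_equal(nrow(ev$events), 0)
  expect_error(detect_gait_events(cbind(rep(300, 1000)), -1, 250),
               "body_weight_N")
})

test_that("detected events match simulator ground truth within one sample", {
  for (s in c(101, 202)) {
    for (p in c("locomotor_initiation", "locomotor_termination")) {
      tr <- simulate_trial(simulation_config(p, seed = s))
      res <- analyze_trial_events(tr)
      det <- res$events$events
      dto <- sort((det$sample[det$event == "toe_off"] - 1) / tr$fs)
      dhs <- sort((det$sample[det$event == "heel_strike"] - 1) / tr$fs)
      tto <- sort(unlist(tr$truth$toe_offs))
      ths <- sort(unlist(tr$truth$heel_strikes))
      expect_length(dto, length(tto))
      expect_length(dhs, length(ths))
      expect_lt(max(abs(dto - tto)), 1.01 / tr$fs)
      expect_lt(max(abs(dhs - ths)), 1.01 / tr$fs)
    }
  }
})

test_that("net CoP is the load-weighted plate average", {
  n <- 100
  plate <- function(fz, x) list(fx_N = numeric(n), fy_N = numeric(n),
                                fz_N = rep(fz, n), cop_x_m = rep(x, n),
                                cop_y_m = numeric(n))
  # all load on the plate at x = 0.3
  nc <- net_cop(list(plate(800, 0.3), plate(0, 0)))
  expect_equal(unname(nc[, "x"]), rep(0.3, n))
  # equal load on plates at 0 and 0.6: midpoint
  nc <- net_cop(list(plate(400, 0), plate(400, 0.6)))
  expect_equal(unname(nc[, "x"]), rep(0.3, n))
})

test_that("net CoP follows the closed form under a loading ramp", {
  n <- 500
  w <- seq(0.1, 0.9, length.out = n)
  p1 <- list(fx_N = numeric(n), fy_N = numeric(n), fz_N = 800 * (1 - w),
             cop_x_m = rep(0, n), cop_y_m = numeric(n))
  p2 <- list(fx_N = numeric(n), fy_N = numeric(n), fz_N = 800 * w,
             cop_x_m = rep(0.6, n), cop_y_m = numeric(n))
  nc <- net_cop(list(p1, p2))
  expect_equal(unname(nc[, "x"]), 0.6 * w)
})

test_that("unloaded samples are flagged as undefined", {
  n <- 10
  p <- list(fx_N = numeric(n), fy_N = numeric(n),
            fz_N = c(rep(0.5, 5), rep(800, 5)),
            cop_x_m = rep(0.2, n), cop_y_m = numeric(n))
  nc <- net_cop(list(p))
  expect_true(all(is.na(nc[1:5, "x"])))
  expect_true(all(nc[6:10, "x"] == 0.2))
})

test_that("CoP speed recovers constant, ramp and sinusoid derivatives", {
  fs <- 250
  n <- 1000
  expect_equal(cop_speed(rep(0.25, n), fs), rep(0, n), tolerance = 1e-12)
  ramp <- 0.1 * (seq_len(n) - 1) / fs
  sp <- cop_speed(ramp, fs)
  expect_equal(sp[100:900], rep(0.1, 801), tolerance = 0.002)
  t <- (seq_len(5 * fs) - 1) / fs
  sine <- 0.01 * sin(2 * pi * 2 * t)
  sp <- cop_speed(sine, fs)
  expect_equal(max(sp[100:1100]), 2 * pi * 2 * 0.01, tolerance = 0.05 * 2 * pi * 2 * 0.01)
})

test_that("transition onset is the first sustained suprathreshold sample", {
  fs <- 250
  speed <- c(rep(0.01, 6 * fs), rep(0.2, 2 * fs), rep(0.01, 2 * fs))
  speed <- speed + rep(c(0, 1e-4), length.out = length(speed))  # nonzero SD
  k <- detect_transition(speed, fs, c(0, 5), "onset")
  expect_equal(k, 6 * fs + 1)
  expect_error(detect_transition(rep(0.01, 10 * fs) +
                                   rep(c(0, 1e-4), 5 * fs), fs,
                                 c(0, 5), "onset"),
               "not found")
})

test_that("transition markers match simulator annotations within 50 ms", {
  for (s in c(31, 32, 33)) {
    tr <- simulate_trial(simulation_config("posture_shift", seed = s))
    res <- analyze_trial_events(tr)
    onset_s <- (res$transition$onset - 1) / tr$fs
    expect_lt(abs(onset_s - tr$truth$transition_onset), 0.05)
  }
})

test_that("phase segmentation applies the protocol definitions directly", {
  fs <- 250
  ev <- data.frame(foot = c("R", "L", "R"),
                   sample = round(c(6.8, 7.4, 8.0) * fs) + 1L,
                   event = "toe_off")
  seg <- segment_phases(ev, list(onset = round(6 * fs) + 1L),
                        "locomotor_initiation", 30 * fs, fs)
  expect_equal(seg$phases$transition,
               c(round(6 * fs) + 1L, round(6.8 * fs) + 1L))
  expect_equal(seg$phases$first_step,
               c(round(6.8 * fs) + 1L, round(7.4 * fs) + 1L))
  expect_equal(seg$D, 2.0)
  # posture
  seg <- segment_phases(data.frame(foot = character(), sample = integer(),
                                   event = character()),
                        list(onset = round(6 * fs) + 1L,
                             end = round(7.1 * fs) + 1L),
                        "posture_shift", 15 * fs, fs)
  expect_equal(seg$phases$shifted_posture[1], round(7.1 * fs) + 1L)
  expect_equal(seg$D, 1.1)
  expect_error(segment_phases(ev, list(onset = NULL),
                              "locomotor_initiation", 30 * fs, fs),
               "missing")
})

test_that("segmentation covers the record without gaps and D matches truth", {
  for (s in c(61, 62, 63, 64, 65)) {
    tr <- simulate_trial(simulation_config("locomotor_initiation", seed = s))
    res <- analyze_trial_events(tr)
    seg <- res$segmentation
    ph <- seg$phases
    expect_equal(ph$quiet_standing[2], ph$transition[1])
    expect_equal(ph$transition[2], ph$first_step[1])
    expect_equal(ph$first_step[2], ph$walking[1])
    expect_lt(abs(seg$D - tr$truth$D), 2.01 / tr$fs)
  }
})

test_that("event detection is invariant to uniform force rescaling", {
  tr <- simulate_trial(simulation_config("locomotor_initiation", seed = 77))
  fz <- cbind(left = tr$plates[[1]]$fz_N, right = tr$plates[[2]]$fz_N)
  a <- detect_gait_events(fz, tr$body_weight_N, tr$fs)
  b <- detect_gait_events(2.5 * fz, 2.5 * tr$body_weight_N, tr$fs)
  expect_identical(a$events$sample, b$events$sample)
})
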