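# Default coupling gain (N per mA). Chosen so that, with the default
# broadband force-channel noise of 1 N, the single-bin EVS-shear coherence
# during quiet standing sits near 0.3 in the middle of the 1-10 Hz band --
# the level at which vestibulo-motor coupling is typically observed in
# standing subjects.
VESTCOH_DEFAULT_GAIN <- 0.23

default_step_timing <- function(protocol) {
  switch(protocol,
    locomotor_initiation = list(
      onset_s = 8, onset_jitter_s = 0.15, transition_dur_s = 0.7,
      step_period_s = 0.6, period_jitter_s = 0.02, n_steps = 6,
      settle_s = 0.5, step_length_m = 0.65),
    locomotor_termination = list(
      stand_s = 1.5, start_transition_s = 0.5, onset_jitter_s = 0.1,
      step_period_s = 0.6, period_jitter_s = 0.02, n_steps = 6,
      settle_s = 0.7, step_length_m = 0.65),
    posture_shift = list(
      onset_s = 6, onset_jitter_s = 0.15, shift_dur_s = 0.8)
  )
}

default_coupling <- function() {
  list(standing_gain = VESTCOH_DEFAULT_GAIN,
       transition_gain = VESTCOH_DEFAULT_GAIN,
       swing_gain = VESTCOH_DEFAULT_GAIN,
       ds_multiplier = 2,
       lag_ms = 200, response_cutoff_hz = 10,
       null_window = "auto")
}

#' Configuration of a synthetic trial
#'
#' Collects every parameter of the trial generator: the protocol (locomotor
#' initiation, locomotor termination, or a lateral posture-to-posture weight
#' shift), timing of the movement, body weight, noise levels, and the
#' vestibulo-motor coupling profile. Defaults follow the standard study
#' conditions: 30 s locomotor trials and 15 s posture trials, at least 5 s of
#' quiet standing before the transition, and a 0-20 Hz stochastic vestibular
#' stimulus with 4 mA peak amplitude.
#'
#' @param protocol One of \code{"locomotor_initiation"},
#'   \code{"locomotor_termination"}, \code{"posture_shift"}.
#' @param duration_s Trial length in seconds (default 30 for locomotor
#'   protocols, 15 for the posture shift).
#' @param fs Sampling rate in Hz (must exceed 40 Hz so the 20 Hz stimulus
#'   band is representable).
#' @param body_weight_N Subject body weight in N.
#' @param step_timing Named list overriding the protocol's timing defaults
#'   (onset time, step period, number of steps, jitters, ...).
#' @param noise_sd_N SD of the broadband measurement noise added to the net
#'   shear force, in N.
#' @param sway_cop_rms_m RMS of the low-frequency (2 Hz low-passed) postural
#'   sway of the centre of pressure, in m.
#' @param sway_shear_rms_N RMS of the sway-related shear force, in N
#'   (standing shear RMS of roughly 0.4 N is typical of quiet stance).
#' @param fz_noise_sd_N SD of per-plate vertical-force noise, in N.
#' @param coupling Named list overriding the coupling defaults:
#'   \code{standing_gain}, \code{transition_gain}, \code{swing_gain} (N/mA),
#'   \code{ds_multiplier} (double-support gain relative to swing),
#'   \code{lag_ms}, \code{response_cutoff_hz}, and \code{null_window}
#'   (\code{"auto"} places a zero-gain window of 0.8 s starting 0.4 s before
#'   the transition marker; \code{NULL} disables it; or an explicit
#'   \code{c(start_s, end_s)}).
#' @param head_orientation \code{"forward"} couples the stimulus into the
#'   mediolateral shear (Fy); \code{"left"} into the anteroposterior shear
#'   (Fx), mirroring the craniocentric direction of the vestibular error.
#' @param seed Integer seed; all randomness in the trial derives from it.
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(protocol = c("locomotor_initiation",
                                           "locomotor_termination",
                                           "posture_shift"),
                              duration_s = NULL, fs = 250,
                              body_weight_N = 750,
                              step_timing = list(), noise_sd_N = 1,
                              sway_cop_rms_m = 0.002,
                              sway_shear_rms_N = 0.4,
                              fz_noise_sd_N = 0.5,
                              coupling = list(),
                              head_orientation = c("forward", "left"),
                              seed = 1) {
  protocol <- match.arg(protocol)
  head_orientation <- match.arg(head_orientation)
  if (is.null(duration_s))
    duration_s <- if (protocol == "posture_shift") 15 else 30
  if (duration_s <= 0) stop_invalid("duration_s must be positive")
  if (fs <= 40) stop_invalid("fs must exceed 40 Hz (stimulus band is 0-20 Hz)")
  if (body_weight_N <= 0) stop_invalid("body_weight_N must be positive")
  st <- utils::modifyList(default_step_timing(protocol), step_timing)
  cp <- utils::modifyList(default_coupling(), coupling)
  cfg <- structure(
    list(protocol = protocol, duration_s = duration_s, fs = fs,
         body_weight_N = body_weight_N, step_timing = st,
         noise_sd_N = noise_sd_N, sway_cop_rms_m = sway_cop_rms_m,
         sway_shear_rms_N = sway_shear_rms_N, fz_noise_sd_N = fz_noise_sd_N,
         coupling = cp, head_orientation = head_orientation,
         seed = as.integer(seed)),
    class = "simulation_config")
  check_timing_fits(cfg)
  cfg
}

check_timing_fits <- function(cfg) {
  st <- cfg$step_timing
  end_need <- switch(cfg$protocol,
    locomotor_initiation =
      st$onset_s + 3 * st$onset_jitter_s + st$transition_dur_s +
      (st$n_steps + 1) * (st$step_period_s + 3 * st$period_jitter_s) +
      st$settle_s,
    locomotor_termination =
      st$stand_s + st$start_transition_s +
      (st$n_steps + 1) * (st$step_period_s + 3 * st$period_jitter_s) +
      st$settle_s + 5,
    posture_shift = st$onset_s + 3 * st$onset_jitter_s + st$shift_dur_s + 1)
  if (end_need > cfg$duration_s)
    stop_invalid("step timings do not fit the %.1f s trial (need ~%.1f s)",
                 cfg$duration_s, end_need)
  invisible(cfg)
}

# Evaluate a piecewise raised-cosine profile defined by nodes (t, v) on a
# sample grid. Flat before the first and after the last node.
piecewise_rc <- function(t, node_t, node_v) {
  stopifnot(length(node_t) == length(node_v), !is.unsorted(node_t))
  out <- numeric(length(t))
  out[t <= node_t[1]] <- node_v[1]
  out[t >= node_t[length(node_t)]] <- node_v[length(node_v)]
  seg <- findInterval(t, node_t)
  inside <- seg >= 1 & seg < length(node_t) & t > node_t[1]
  i <- seg[inside]
  u <- (t[inside] - node_t[i]) / (node_t[i + 1] - node_t[i])
  out[inside] <- node_v[i] + (node_v[i + 1] - node_v[i]) *
    (1 - cos(pi * u)) / 2
  out
}

# Closed-form time at which a raised-cosine segment from (t0,v0) to (t1,v1)
# crosses level `thr` (assumes thr strictly between v0 and v1).
rc_crossing <- function(t0, v0, t1, v1, thr) {
  u <- acos(1 - 2 * (thr - v0) / (v1 - v0)) / pi
  t0 + u * (t1 - t0)
}

# Given a foot's fz nodes, return closed-form toe-off / heel-strike times at
# the `thr` threshold: falling crossings are toe-offs, rising crossings after
# a toe-off are heel-strikes. Independent of the run-based event detector.
foot_events_from_nodes <- function(node_t, node_v, thr) {
  to <- hs <- numeric(0)
  airborne <- node_v[1] < thr
  for (i in seq_len(length(node_t) - 1)) {
    v0 <- node_v[i]; v1 <- node_v[i + 1]
    if (!airborne && v0 >= thr && v1 < thr) {
      to <- c(to, rc_crossing(node_t[i], v0, node_t[i + 1], v1, thr))
      airborne <- TRUE
    } else if (airborne && v0 < thr && v1 >= thr) {
      hs <- c(hs, rc_crossing(node_t[i], v0, node_t[i + 1], v1, thr))
      airborne <- FALSE
    }
  }
  list(toe_offs = to, heel_strikes = hs)
}

# Build the walking block shared by both locomotor protocols: alternating
# toe-off/heel-strike times with per-step period jitter, plus the per-foot
# fz nodes implementing a raised-cosine load transfer whose double-support
# overlap is 40% of the step period (20% of the stride).
walk_block <- function(first_to, n_steps, period, jitter, bw, seed) {
  set.seed(seed)
  periods <- pmax(period + stats::rnorm(n_steps, 0, jitter), 0.3)
  to <- first_to + c(0, cumsum(periods[-n_steps]))
  swing <- 0.6 * periods
  hs <- to + swing                      # landing of the foot that left at to
  feet <- rep(c("R", "L"), length.out = n_steps)
  list(to = to, hs = hs, feet = feet, periods = periods)
}

#' Simulate a full trial recording
#'
#' Generates the stimulus, per-plate vertical forces and centre-of-pressure
#' trajectories for the configured protocol, a shear-force channel equal to
#' postural-sway noise plus the lagged, low-pass-filtered, gain-scheduled
#' response to the stimulus, and a ground-truth sidecar (event times,
#' transition markers, normalization duration D, double-support intervals
#' and the zero-gain null window). Two forceplates are used, one per foot
#' (left at mediolateral position -0.1 m, right at +0.1 m).
#'
#' Ground-truth gait events and transition markers are computed in closed
#' form from the generating templates (raised-cosine crossings of the 5%
#' body-weight level; threshold crossings of the noise-free
#' centre-of-pressure speed), so they are independent of the run-based
#' detectors in this package and can serve as their oracle.
#'
#' @param config A \code{simulation_config}.
#' @return An object of class \code{trial_recording}: stimulus, a list of
#'   per-plate channel lists (\code{fx_N}, \code{fy_N}, \code{fz_N},
#'   \code{cop_x_m}, \code{cop_y_m}), sampling rate, protocol metadata and a
#'   \code{truth} list.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  fs <- config$fs
  n <- as.integer(round(config$duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  bw <- config$body_weight_N
  st <- config$step_timing
  cp <- config$coupling
  seed <- config$seed

  evs <- generate_evs(config$duration_s, fs, cutoff_hz = 20, filter_order = 4,
                      peak_mA = 4, seed = sub_seed(seed, 0L))

  set.seed(sub_seed(seed, 1L))
  tl <- build_timeline(config)

  fzL <- piecewise_rc(t, tl$nodesL$t, tl$nodesL$v)
  fzR <- piecewise_rc(t, tl$nodesR$t, tl$nodesR$v)

  # Plate geometry: cop_y is mediolateral (left foot -0.1 m, right +0.1 m),
  # cop_x is anteroposterior and advances with each step.
  copLy <- rep(-0.1, n); copRy <- rep(0.1, n)
  copLx <- step_progression(t, tl, "L", st)
  copRx <- step_progression(t, tl, "R", st)

  # Noise-free net CoP (fz-weighted plate positions): the transition markers
  # are annotated from this template.
  tot <- pmax(fzL + fzR, 1e-9)
  net_x_clean <- (copLx * fzL + copRx * fzR) / tot
  net_y_clean <- (copLy * fzL + copRy * fzR) / tot

  sway_x <- filtered_noise(n, fs, 2, config$sway_cop_rms_m, sub_seed(seed, 2L))
  sway_y <- filtered_noise(n, fs, 2, config$sway_cop_rms_m, sub_seed(seed, 3L))

  baseline <- if (config$protocol == "locomotor_termination") {
    c(config$duration_s - 5, config$duration_s)
  } else {
    c(0, 5)
  }
  ann <- annotate_transition(net_x_clean, net_y_clean, sway_x, sway_y,
                             fs, baseline, config$protocol, tl)

  # Ground-truth gait events from closed-form crossings of the generating
  # raised-cosine templates at the 5% body-weight level.
  thr <- 0.05 * bw
  evL <- foot_events_from_nodes(tl$nodesL$t, tl$nodesL$v, thr)
  evR <- foot_events_from_nodes(tl$nodesR$t, tl$nodesR$v, thr)
  # Events are defined as the first *sample* past the threshold, so quantize
  # the continuous crossing times onto the sampling grid accordingly.
  quant <- function(tt) (floor(tt * fs) + 1) / fs
  evL <- lapply(evL, quant)
  evR <- lapply(evR, quant)
  if (config$protocol == "locomotor_termination") {
    all_hs <- sort(c(evL$heel_strikes, evR$heel_strikes))
    ann$onset <- all_hs[length(all_hs)]  # transition starts at last heel-strike
  } else if (config$protocol == "locomotor_initiation") {
    ann$end <- min(c(evL$toe_offs, evR$toe_offs))  # transition ends at first toe-off
  }

  # Gain schedule over trial time, then the zero-gain window anchored to the
  # annotated transition marker.
  gvec <- build_gain_vector(t, tl, cp, config$protocol)
  nullw <- cp$null_window
  if (identical(nullw, "auto")) {
    nullw <- c(ann$onset - 0.4, ann$onset + 0.4)
  }
  if (!is.null(nullw)) {               # effective gain is zero in the window
    gvec[t >= nullw[1] & t < nullw[2]] <- 0
  }
  profile <- coupling_profile(gain = gvec, lag_ms = cp$lag_ms,
                              response_cutoff_hz = cp$response_cutoff_hz,
                              null_window = nullw)
  coupled <- coupling_response(evs, profile)

  sway_fx <- filtered_noise(n, fs, 2, config$sway_shear_rms_N, sub_seed(seed, 4L))
  sway_fy <- filtered_noise(n, fs, 2, config$sway_shear_rms_N, sub_seed(seed, 5L))

  fx_tot <- tl$shear_x_det + sway_fx
  fy_tot <- tl$shear_y_det + sway_fy
  if (config$head_orientation == "forward") {
    fy_tot <- fy_tot + coupled          # mediolateral response
  } else {
    fx_tot <- fx_tot + coupled          # anteroposterior response
  }

  # Distribute net shear across plates in proportion to the load each foot
  # carries, then add independent per-plate measurement noise.
  shareR <- fzR / tot
  shareL <- 1 - shareR
  set.seed(sub_seed(seed, 6L))
  nz <- function(sd) stats::rnorm(n, 0, sd)
  sdp <- config$noise_sd_N / sqrt(2)
  plates <- list(
    list(fx_N = fx_tot * shareL + nz(sdp),
         fy_N = fy_tot * shareL + nz(sdp),
         fz_N = pmax(fzL + nz(config$fz_noise_sd_N), 0),
         cop_x_m = copLx + sway_x + nz(1e-4),
         cop_y_m = copLy + sway_y + nz(1e-4)),
    list(fx_N = fx_tot * shareR + nz(sdp),
         fy_N = fy_tot * shareR + nz(sdp),
         fz_N = pmax(fzR + nz(config$fz_noise_sd_N), 0),
         cop_x_m = copRx + sway_x + nz(1e-4),
         cop_y_m = copRy + sway_y + nz(1e-4))
  )

  truth <- list(
    toe_offs = list(left = evL$toe_offs, right = evR$toe_offs),
    heel_strikes = list(left = evL$heel_strikes, right = evR$heel_strikes),
    transition_onset = ann$onset,
    transition_end = ann$end,
    null_window = nullw,
    D = truth_duration_D(config$protocol, ann, evL, evR),
    double_support = tl$double_support,
    baseline = baseline,
    gain = gvec
  )

  structure(
    list(stimulus = evs, plates = plates, fs = fs,
         protocol = config$protocol,
         head_orientation = config$head_orientation,
         body_weight_N = bw, truth = truth, config = config),
    class = "trial_recording")
}

# Normalization duration D: initiation, transition onset to third toe-off;
# termination, third-to-last foot-strike to the end of the transition phase;
# posture shift, the transition itself.
truth_duration_D <- function(protocol, ann, evL, evR) {
  all_to <- sort(c(evL$toe_offs, evR$toe_offs))
  all_hs <- sort(c(evL$heel_strikes, evR$heel_strikes))
  switch(protocol,
    locomotor_initiation = all_to[3] - ann$onset,
    locomotor_termination = ann$end - all_hs[length(all_hs) - 2],
    posture_shift = ann$end - ann$onset)
}

# Per-protocol deterministic templates: per-foot fz nodes, step events,
# deterministic shear components and the phase boundaries the gain schedule
# needs. All times in seconds.
build_timeline <- function(config) {
  st <- config$step_timing
  bw <- config$body_weight_N
  fs <- config$fs
  n <- as.integer(round(config$duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  seed <- config$seed

  if (config$protocol == "posture_shift") {
    set.seed(sub_seed(seed, 10L))
    on <- st$onset_s + stats::rnorm(1, 0, st$onset_jitter_s)
    end <- on + st$shift_dur_s
    # preferred leg = right: ramp to a 90/10 load split
    nodesR <- list(t = c(0, on, end), v = bw * c(0.5, 0.5, 0.9))
    nodesL <- list(t = c(0, on, end), v = bw * c(0.5, 0.5, 0.1))
    shear_y <- 8 * biphasic_lobe(t, on, st$shift_dur_s)
    return(list(nodesL = nodesL, nodesR = nodesR,
                nominal_onset = on, nominal_end = end,
                walk = NULL, double_support = list(),
                shear_x_det = numeric(n), shear_y_det = shear_y))
  }

  if (config$protocol == "locomotor_initiation") {
    set.seed(sub_seed(seed, 10L))
    on <- st$onset_s + stats::rnorm(1, 0, st$onset_jitter_s)
    td <- st$transition_dur_s
    to1 <- on + td
    wb <- walk_block(to1, st$n_steps, st$step_period_s, st$period_jitter_s,
                     bw, sub_seed(seed, 11L))
    fznodes <- walking_fz_nodes(wb, bw, st$settle_s,
                                pre = list(
                                  R = list(t = c(0, on, on + 0.3 * td),
                                           v = bw * c(0.5, 0.5, 0.6)),
                                  L = list(t = c(0, on, on + 0.3 * td),
                                           v = bw * c(0.5, 0.5, 0.4))))
    shear_y <- 8 * biphasic_lobe(t, on, td) + walking_shear(t, wb, 3)
    shear_x <- walking_shear(t, wb, 5)
    ds <- double_support_intervals(wb)
    return(list(nodesL = fznodes$L, nodesR = fznodes$R,
                nominal_onset = on, nominal_end = to1, walk = wb,
                double_support = ds,
                shear_x_det = shear_x, shear_y_det = shear_y))
  }

  # locomotor_termination: brief start transition, walking, then the
  # analyzed stop: last heel-strike followed by a settle back to 50/50.
  on0 <- st$stand_s
  td0 <- st$start_transition_s
  to1 <- on0 + td0
  wb <- walk_block(to1, st$n_steps, st$step_period_s, st$period_jitter_s,
                   bw, sub_seed(seed, 11L))
  fznodes <- walking_fz_nodes(wb, bw, st$settle_s,
                              pre = list(
                                R = list(t = c(0, on0, on0 + 0.3 * td0),
                                         v = bw * c(0.5, 0.5, 0.6)),
                                L = list(t = c(0, on0, on0 + 0.3 * td0),
                                         v = bw * c(0.5, 0.5, 0.4))))
  last_hs <- wb$hs[length(wb$hs)]
  shear_y <- walking_shear(t, wb, 3) + 8 * biphasic_lobe(t, last_hs, st$settle_s)
  shear_x <- walking_shear(t, wb, 5)
  ds <- double_support_intervals(wb)
  list(nodesL = fznodes$L, nodesR = fznodes$R,
       nominal_onset = last_hs, nominal_end = last_hs + st$settle_s,
       walk = wb, double_support = ds,
       shear_x_det = shear_x, shear_y_det = shear_y)
}

# One positive-then-negative shear lobe over [t0, t0 + dur].
biphasic_lobe <- function(t, t0, dur) {
  u <- (t - t0) / dur
  ifelse(u >= 0 & u <= 1, sin(2 * pi * u), 0)
}

# Small oscillatory shear at the step rate while walking.
walking_shear <- function(t, wb, amp) {
  t0 <- wb$to[1]
  t1 <- wb$hs[length(wb$hs)]
  u <- (t - t0) / mean(wb$periods)
  ifelse(t >= t0 & t <= t1, amp * sin(2 * pi * u / 2), 0)
}

double_support_intervals <- function(wb) {
  n <- length(wb$to)
  out <- list()
  for (i in seq_len(n - 1)) out[[i]] <- c(wb$hs[i], wb$to[i + 1])
  out
}

# Per-foot fz node lists implementing: pre-transition loading (given in
# `pre`), alternating swings with raised-cosine transfers during double
# support, a final landing, and a settle back to half body weight each.
walking_fz_nodes <- function(wb, bw, settle_s, pre) {
  nodes <- list(R = pre$R, L = pre$L)
  n <- length(wb$to)
  add <- function(f, tt, vv) {
    nodes[[f]]$t <<- c(nodes[[f]]$t, tt)
    nodes[[f]]$v <<- c(nodes[[f]]$v, vv)
  }
  for (i in seq_len(n)) {
    f <- wb$feet[i]                      # foot leaving the ground
    o <- setdiff(c("R", "L"), f)         # stance foot
    add(f, wb$to[i], 0)                  # airborne at toe-off
    add(o, wb$to[i], bw)                 # stance carries full load
    add(f, wb$hs[i], 0)                  # still zero at landing instant
    if (i < n) {
      add(f, wb$to[i + 1], bw)           # load up over double support
      add(o, wb$hs[i], bw)               # hold, then unload
    }
  }
  last_hs <- wb$hs[n]
  last_foot <- wb$feet[n]
  other <- setdiff(c("R", "L"), last_foot)
  add(last_foot, last_hs + settle_s, bw * 0.5)
  add(other, last_hs, bw)
  add(other, last_hs + settle_s, bw * 0.5)
  nodes
}

# Anteroposterior CoP position of one foot: constant while loaded, advancing
# by one step length at each of its landings.
step_progression <- function(t, tl, foot, st) {
  if (is.null(tl$walk)) return(numeric(length(t)))
  wb <- tl$walk
  x <- numeric(length(t))
  pos <- 0
  for (i in seq_along(wb$to)) {
    if (wb$feet[i] == foot) {
      pos <- pos + st$step_length_m
      x[t >= wb$hs[i]] <- pos
    }
  }
  x
}

# Transition markers annotated on the measurement-noise-free CoP (template
# plus postural sway) with the canonical rule: baseline mean + 3 SD of the
# CoP speed, excursions shorter than 50 ms ignored. Postural sway is part of
# the trajectory the marker is defined on, so the annotation includes it;
# only measurement noise separates a detection on the recorded channels
# from this annotation.
annotate_transition <- function(net_x_clean, net_y_clean, sway_x, sway_y,
                                fs, baseline, protocol, tl) {
  sp <- cop_speed(cbind(net_x_clean + sway_x, net_y_clean + sway_y), fs)
  i0 <- sec_to_idx(baseline[1], fs)
  i1 <- min(sec_to_idx(baseline[2], fs), length(sp) + 1L)
  b <- sp[i0:(i1 - 1L)]
  thr <- mean(b) + 3 * stats::sd(b)
  g <- sustained_runs(sp, thr, fs)
  tof <- function(i) (i - 1) / fs
  if (protocol == "locomotor_termination") {
    pre <- g[g$end <= i0, , drop = FALSE]
    end <- if (nrow(pre) > 0) tof(pre$end[nrow(pre)] - 1L) else tl$nominal_end
    list(onset = tl$nominal_onset, end = end)
  } else {
    post <- g[g$start >= i1, , drop = FALSE]
    onset <- if (nrow(post) > 0) tof(post$start[1]) else tl$nominal_onset
    end <- if (nrow(post) > 0) tof(post$end[nrow(post)] - 1L) else tl$nominal_end
    list(onset = onset, end = end)
  }
}

# Gain schedule: standing gain outside the movement, transition gain between
# the transition markers, swing gain while walking with the double-support
# multiplier applied inside double-support intervals.
build_gain_vector <- function(t, tl, cp, protocol) {
  g <- rep(cp$standing_gain, length(t))
  set_seg <- function(g, t0, t1, val) {
    g[t >= t0 & t < t1] <- val
    g
  }
  if (protocol == "posture_shift") {
    g <- set_seg(g, tl$nominal_onset, tl$nominal_end, cp$transition_gain)
    return(g)
  }
  wb <- tl$walk
  walk_end <- wb$hs[length(wb$hs)]
  g <- set_seg(g, tl$nominal_onset, wb$to[1], cp$transition_gain)
  g <- set_seg(g, wb$to[1], walk_end, cp$swing_gain)
  for (ds in tl$double_support)
    g <- set_seg(g, ds[1], ds[2], cp$ds_multiplier * cp$swing_gain)
  if (protocol == "locomotor_termination")
    g <- set_seg(g, tl$nominal_onset, tl$nominal_end, cp$transition_gain)
  g
}
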