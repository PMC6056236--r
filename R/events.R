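#' Estimate body weight from a quiet-standing baseline
#'
#' Mean of the total vertical force over a baseline interval that lies
#' within a standing segment.
#'
#' @param trial A \code{trial_recording}.
#' @param baseline \code{c(start_s, end_s)}, half-open, in seconds.
#' @return Body weight in N.
#' @export
estimate_body_weight <- function(trial, baseline = c(0, 5)) {
  stopifnot(inherits(trial, "trial_recording"))
  n <- length(trial$plates[[1]]$fz_N)
  i0 <- sec_to_idx(baseline[1], trial$fs)
  i1 <- sec_to_idx(baseline[2], trial$fs)
  if (i1 <= i0 || i0 < 1 || i1 > n + 1)
    stop_invalid("baseline [%g, %g) s lies outside the recording",
                 baseline[1], baseline[2])
  tot <- Reduce(`+`, lapply(trial$plates, `[[`, "fz_N"))
  mean(tot[i0:(i1 - 1L)])
}

#' Detect toe-offs and heel-strikes from per-foot vertical force
#'
#' A toe-off is the first sample at which a foot's vertical force drops
#' below 5\% of body weight; a heel-strike is the first sample after a
#' toe-off at which it rises above that threshold again. Threshold
#' crossings that do not persist for at least \code{min_event_s} are
#' treated as chatter and ignored.
#'
#' @param per_foot_fz Numeric matrix (samples x feet) or list of per-foot
#'   vertical-force vectors in N.
#' @param body_weight_N Body weight in N.
#' @param fs Sampling rate in Hz.
#' @param threshold_frac Fraction of body weight defining the contact
#'   threshold (default 0.05).
#' @param min_event_s Minimum duration of a below/above-threshold run, s.
#' @return An object of class \code{gait_events}: per-foot toe-off and
#'   heel-strike sample indices (1-based) plus merged, time-ordered event
#'   tables.
#' @export
detect_gait_events <- function(per_foot_fz, body_weight_N, fs,
                               threshold_frac = 0.05, min_event_s = 0.05) {
  if (body_weight_N <= 0) stop_invalid("body_weight_N must be positive")
  if (is.list(per_foot_fz)) per_foot_fz <- do.call(cbind, per_foot_fz)
  per_foot_fz <- as.matrix(per_foot_fz)
  thr <- threshold_frac * body_weight_N
  min_run <- max(1L, as.integer(round(min_event_s * fs)))
  feet <- colnames(per_foot_fz)
  if (is.null(feet)) feet <- paste0("foot", seq_len(ncol(per_foot_fz)))
  per_foot <- lapply(seq_len(ncol(per_foot_fz)), function(j) {
    foot_threshold_events(per_foot_fz[, j], thr, min_run)
  })
  names(per_foot) <- feet
  to <- do.call(rbind, lapply(feet, function(f) {
    if (length(per_foot[[f]]$toe_offs) == 0) return(NULL)
    data.frame(foot = f, sample = per_foot[[f]]$toe_offs, event = "toe_off")
  }))
  hs <- do.call(rbind, lapply(feet, function(f) {
    if (length(per_foot[[f]]$heel_strikes) == 0) return(NULL)
    data.frame(foot = f, sample = per_foot[[f]]$heel_strikes,
               event = "heel_strike")
  }))
  ev <- rbind(to, hs)
  ev <- if (is.null(ev)) {
    data.frame(foot = character(), sample = integer(), event = character())
  } else {
    ev[order(ev$sample), , drop = FALSE]
  }
  rownames(ev) <- NULL
  structure(
    list(per_foot = per_foot, events = ev, body_weight_N = body_weight_N,
         fs = fs, threshold_N = thr),
    class = "gait_events")
}

# Run-based threshold event extraction for one foot. Runs shorter than
# min_run samples are ignored; alternation (TO, HS, TO, ...) is enforced by
# construction: heel-strikes are only taken after a toe-off.
foot_threshold_events <- function(fz, thr, min_run) {
  below <- fz < thr
  runs <- logical_runs(below)
  runs <- runs[(runs$end - runs$start) >= min_run |
                 runs$end == length(fz) + 1L, , drop = FALSE]
  to <- hs <- integer(0)
  for (i in seq_len(nrow(runs))) {
    if (runs$start[i] == 1L) next       # airborne at record start: no event
    to <- c(to, runs$start[i])
    if (runs$end[i] <= length(fz)) hs <- c(hs, runs$end[i])
  }
  list(toe_offs = to, heel_strikes = hs)
}

#' Net centre of pressure across forceplates
#'
#' Vertical-force-weighted average of the per-plate centre-of-pressure
#' coordinates. Samples where the total vertical force does not exceed
#' \code{min_load_N} are undefined and returned as \code{NA}.
#'
#' @param plates List of per-plate channel lists (\code{fz_N},
#'   \code{cop_x_m}, \code{cop_y_m}), or a \code{trial_recording}.
#' @param min_load_N Minimum total vertical force for the CoP to be defined.
#' @return Matrix (samples x 2) with columns \code{x} and \code{y}, in m.
#' @export
net_cop <- function(plates, min_load_N = 1) {
  if (inherits(plates, "trial_recording")) plates <- plates$plates
  fz <- sapply(plates, `[[`, "fz_N")
  cx <- sapply(plates, `[[`, "cop_x_m")
  cy <- sapply(plates, `[[`, "cop_y_m")
  tot <- rowSums(fz)
  x <- rowSums(cx * fz) / tot
  y <- rowSums(cy * fz) / tot
  bad <- tot <= min_load_N
  x[bad] <- NA_real_
  y[bad] <- NA_real_
  cbind(x = x, y = y)
}

#' Horizontal centre-of-pressure speed
#'
#' Filters each CoP axis with a zero-phase second-order Butterworth low-pass
#' at 20 Hz, differentiates (central differences), and returns the magnitude
#' of the horizontal velocity.
#'
#' @param cop Numeric vector (single axis) or matrix with one column per
#'   axis, in m.
#' @param fs Sampling rate in Hz; must exceed 40 Hz.
#' @param cutoff_hz Low-pass cutoff applied before differentiation.
#' @return Numeric vector of speed in m/s, same length as the input.
#' @export
cop_speed <- function(cop, fs, cutoff_hz = 20) {
  if (fs <= 2 * cutoff_hz)
    stop_invalid("fs must exceed %g Hz for the %g Hz CoP filter",
                 2 * cutoff_hz, cutoff_hz)
  cop <- as.matrix(cop)
  if (nrow(cop) < 12)
    stop_invalid("CoP trajectory too short for the filter (%d samples)",
                 nrow(cop))
  v2 <- 0
  for (j in seq_len(ncol(cop))) {
    f <- lowpass_zerophase(cop[, j], fs, cutoff_hz, order = 2)
    n <- length(f)
    v <- numeric(n)
    v[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) * (fs / 2)
    v[1] <- (f[2] - f[1]) * fs
    v[n] <- (f[n] - f[n - 1]) * fs
    v2 <- v2 + v^2
  }
  sqrt(v2)
}

#' Detect the onset or end of a movement transition from CoP speed
#'
#' The transition marker is the first (\code{mode = "onset"}) or last
#' (\code{mode = "end"}) instant at which the horizontal CoP speed exceeds
#' the baseline mean plus three baseline standard deviations, where the
#' baseline is a five-second quiet-standing stretch. Excursions shorter than
#' \code{min_run_s} are ignored as chatter.
#'
#' @param speed CoP speed in m/s (from \code{\link{cop_speed}}).
#' @param fs Sampling rate in Hz.
#' @param baseline \code{c(start_s, end_s)} of the quiet baseline.
#' @param mode \code{"onset"} or \code{"end"}.
#' @param center \code{"mean"} thresholds at baseline mean + 3 SD (default);
#'   \code{"zero"} at 3 SD about zero.
#' @param min_move_s Minimum continuous above-threshold duration for a run
#'   to count as movement rather than a sway excursion. Postural sway only
#'   crosses the 3-SD level in brief bursts; a genuine transition sustains
#'   it for several tenths of a second.
#' @return Sample index (1-based) of the marker.
#' @export
detect_transition <- function(speed, fs, baseline, mode = c("onset", "end"),
                              center = c("mean", "zero"), min_move_s = 0.3) {
  mode <- match.arg(mode)
  center <- match.arg(center)
  n <- length(speed)
  i0 <- sec_to_idx(baseline[1], fs)
  i1 <- sec_to_idx(baseline[2], fs)
  if (i1 <= i0 || i0 < 1 || i1 > n + 1)
    stop_invalid("baseline [%g, %g) s lies outside the record",
                 baseline[1], baseline[2])
  b <- speed[i0:(i1 - 1L)]
  thr <- if (center == "mean") mean(b) + 3 * stats::sd(b) else 3 * stats::sd(b)
  g <- sustained_runs(speed, thr, fs, min_move_s)
  if (mode == "onset") {
    g <- g[g$start >= i1, , drop = FALSE]
    if (nrow(g) == 0)
      stop("transition onset not found: CoP speed never exceeded ",
           "baseline mean + 3 SD", call. = FALSE)
    g$start[1]
  } else {
    # quiet baseline follows the movement (locomotor termination): last
    # sustained run ending before it; baseline precedes the movement
    # (posture shift): last sustained run after it
    pre <- g[g$end <= i0, , drop = FALSE]
    post <- g[g$start >= i1, , drop = FALSE]
    if (nrow(pre) > 0) return(pre$end[nrow(pre)] - 1L)
    if (nrow(post) > 0) return(post$end[nrow(post)] - 1L)
    stop("transition end not found: CoP speed never exceeded ",
         "baseline mean + 3 SD outside the baseline", call. = FALSE)
  }
}

# Continuous above-threshold runs lasting at least min_move_s.
# Returns data.frame(start, end), half-open 1-based indices.
sustained_runs <- function(speed, thr, fs, min_move_s = 0.3) {
  runs <- logical_runs(speed > thr)
  runs[(runs$end - runs$start) >= as.integer(round(min_move_s * fs)), ,
       drop = FALSE]
}

#' Segment a trial into labeled movement phases
#'
#' Applies the protocol's phase definitions. Locomotor initiation: quiet
#' standing runs to the transition onset, the transition runs to the first
#' toe-off, the first step spans first to second toe-off, and walking
#' follows; D is the time from transition onset to the third toe-off.
#' Locomotor termination: the last step spans the second-to-last to last
#' heel-strike, the transition runs from the last heel-strike to the
#' CoP-speed-defined end, and quiet standing follows; D is the time from the
#' third-to-last heel-strike to the transition end. Posture shift: quiet
#' standing, transition between onset and end, then the shifted posture;
#' D is the transition duration.
#'
#' @param events A \code{gait_events} (may be event-free for the posture
#'   protocol).
#' @param transition List with \code{onset} and/or \code{end} sample
#'   indices, as returned by \code{\link{detect_transition}}.
#' @param protocol Protocol name.
#' @param n_samples Record length in samples.
#' @param fs Sampling rate in Hz.
#' @return An object of class \code{phase_segmentation}: transition onset
#'   and end (sample indices), a named list of half-open phase intervals,
#'   and the normalization duration \code{D} in seconds.
#' @export
segment_phases <- function(events, transition, protocol, n_samples, fs) {
  merged <- if (inherits(events, "gait_events")) events$events else events
  to <- merged$sample[merged$event == "toe_off"]
  hs <- merged$sample[merged$event == "heel_strike"]
  seg_err <- function(what)
    stop(sprintf("segmentation failed: missing %s for protocol %s",
                 what, protocol), call. = FALSE)
  if (protocol == "locomotor_initiation") {
    if (is.null(transition$onset)) seg_err("transition onset")
    if (length(to) < 3) seg_err("three toe-offs")
    on <- as.integer(transition$onset)
    phases <- list(
      quiet_standing = c(1L, on),
      transition = c(on, to[1]),
      first_step = c(to[1], to[2]),
      walking = c(to[2], as.integer(n_samples) + 1L))
    D <- (to[3] - on) / fs
    return(new_segmentation(on, to[1], phases, D, fs))
  }
  if (protocol == "locomotor_termination") {
    if (is.null(transition$end)) seg_err("transition end")
    if (length(hs) < 3) seg_err("three heel-strikes")
    en <- as.integer(transition$end)
    last_hs <- hs[length(hs)]
    phases <- list(
      walking = c(1L, hs[length(hs) - 1]),
      last_step = c(hs[length(hs) - 1], last_hs),
      transition = c(last_hs, en),
      quiet_standing = c(en, as.integer(n_samples) + 1L))
    D <- (en - hs[length(hs) - 2]) / fs
    return(new_segmentation(last_hs, en, phases, D, fs))
  }
  if (protocol == "posture_shift") {
    if (is.null(transition$onset)) seg_err("transition onset")
    if (is.null(transition$end)) seg_err("transition end")
    on <- as.integer(transition$onset)
    en <- as.integer(transition$end)
    phases <- list(
      quiet_standing = c(1L, on),
      transition = c(on, en),
      shifted_posture = c(en, as.integer(n_samples) + 1L))
    D <- (en - on) / fs
    return(new_segmentation(on, en, phases, D, fs))
  }
  stop_invalid("unknown protocol '%s'", protocol)
}

new_segmentation <- function(onset, end, phases, D, fs) {
  if (D <= 0) stop_invalid("normalization duration D must be positive")
  structure(
    list(transition_onset = as.integer(onset), transition_end = as.integer(end),
         phases = phases, D = D, fs = fs),
    class = "phase_segmentation")
}

#' One-call event pipeline for a simulated or recorded trial
#'
#' Estimates body weight from the baseline, detects gait events, computes
#' the net CoP speed, locates the transition markers for the trial's
#' protocol, and segments the phases.
#'
#' @param trial A \code{trial_recording}.
#' @param baseline \code{c(start_s, end_s)} quiet baseline in s; default is
#'   the first five seconds (last five for locomotor termination).
#' @return List with \code{body_weight_N}, \code{events}, \code{speed},
#'   \code{transition} (sample indices) and \code{segmentation}.
#' @export
analyze_trial_events <- function(trial, baseline = NULL) {
  stopifnot(inherits(trial, "trial_recording"))
  fs <- trial$fs
  n <- length(trial$plates[[1]]$fz_N)
  if (is.null(baseline)) {
    baseline <- if (trial$protocol == "locomotor_termination")
      c((n / fs) - 5, n / fs) else c(0, 5)
  }
  bw <- estimate_body_weight(trial, baseline)
  fzmat <- sapply(trial$plates, `[[`, "fz_N")
  colnames(fzmat) <- c("left", "right")[seq_len(ncol(fzmat))]
  ev <- detect_gait_events(fzmat, bw, fs)
  sp <- cop_speed(net_cop(trial), fs)
  tr <- switch(trial$protocol,
    locomotor_initiation = list(
      onset = detect_transition(sp, fs, baseline, "onset")),
    locomotor_termination = list(
      end = detect_transition(sp, fs, baseline, "end")),
    posture_shift = list(
      onset = detect_transition(sp, fs, baseline, "onset"),
      end = detect_transition(sp, fs, baseline, "end")))
  seg <- segment_phases(ev, tr, trial$protocol, n, fs)
  list(body_weight_N = bw, events = ev, speed = sp, transition = tr,
       segmentation = seg)
}
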