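#' Configuration of a full analysis run
#'
#' Bundles the simulation settings and every analysis parameter needed to
#' run the pipeline end to end, so that a run is fully reproducible from
#' its configuration and seed.
#'
#' @param protocol Protocol name.
#' @param n_subjects Number of simulated subjects.
#' @param n_trials Trials per subject (100 in the standard protocols).
#' @param fs Sampling rate in Hz.
#' @param duration_s Trial length (protocol default when \code{NULL}).
#' @param head_orientation \code{"forward"} or \code{"left"}.
#' @param seed Master seed; every trial's seed derives from it.
#' @param alpha Significance level of the coherence confidence limit.
#' @param freqs Analysis frequency grid in Hz.
#' @param lag_ms Stimulus-to-response lag in ms.
#' @param band \code{c(f_lo, f_hi)} for the band-averaged time course.
#' @param window_s Width of the non-normalized analysis window centred on
#'   the transition marker (default 3 s for locomotor protocols, 7 s for
#'   the posture shift).
#' @param normalize Also compute movement-time-normalized coherence
#'   (locomotor protocols only; default \code{TRUE} there).
#' @param search_s Half-width of the null-period search window (default
#'   1.5 s locomotor, 3.5 s posture).
#' @param step_timing,coupling,noise Named lists forwarded to
#'   \code{\link{simulation_config}} (\code{noise} may set
#'   \code{noise_sd_N}, \code{sway_cop_rms_m}, \code{sway_shear_rms_N},
#'   \code{fz_noise_sd_N}).
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(protocol = "locomotor_initiation", n_subjects = 1,
                       n_trials = 100, fs = 250, duration_s = NULL,
                       head_orientation = "forward", seed = 1, alpha = 0.01,
                       freqs = 1:20, lag_ms = 200, band = c(1, 10),
                       window_s = NULL, normalize = NULL, search_s = NULL,
                       step_timing = list(), coupling = list(),
                       noise = list()) {
  locomotor <- protocol != "posture_shift"
  if (is.null(window_s)) window_s <- if (locomotor) 3 else 7
  if (is.null(normalize)) normalize <- locomotor
  if (is.null(search_s)) search_s <- if (locomotor) 1.5 else 3.5
  if (normalize && !locomotor)
    stop_invalid("movement-time normalization applies to locomotor protocols")
  structure(
    list(protocol = protocol, n_subjects = as.integer(n_subjects),
         n_trials = as.integer(n_trials), fs = fs, duration_s = duration_s,
         head_orientation = head_orientation, seed = as.integer(seed),
         alpha = alpha, freqs = freqs, lag_ms = lag_ms, band = band,
         window_s = window_s, normalize = normalize, search_s = search_s,
         step_timing = step_timing, coupling = coupling, noise = noise),
    class = "run_config")
}

config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"))
}

trial_sim_config <- function(config, subject, trial) {
  noise <- config$noise
  args <- list(protocol = config$protocol, duration_s = config$duration_s,
               fs = config$fs, step_timing = config$step_timing,
               coupling = config$coupling,
               head_orientation = config$head_orientation,
               seed = sub_seed(config$seed, (subject - 1L) * 100000L + trial))
  do.call(simulation_config, c(args, noise))
}

# Net shear force on the axis the stimulus couples into: mediolateral (fy)
# for head forward, anteroposterior (fx) for head left.
coupled_shear <- function(trial) {
  ch <- if (trial$head_orientation == "forward") "fy_N" else "fx_N"
  Reduce(`+`, lapply(trial$plates, `[[`, ch))
}

# Marker the analysis windows are centred on: transition onset for
# initiation and posture, transition end for termination.
analysis_marker <- function(transition, protocol, fs) {
  idx <- if (protocol == "locomotor_termination") transition$end
         else transition$onset
  (idx - 1) / fs
}

#' Run the full analysis pipeline
#'
#' Simulates the configured trials, detects events and movement phases on
#' each, computes per-trial Morlet spectra, averages them per subject (and
#' pooled across subjects) in a window centred on the transition marker --
#' plus, for locomotor protocols, in movement-time-normalized form --
#' derives the band-averaged coherence time course, the null period around
#' the transition and per-phase coherence peaks, and (with at least six
#' subjects) the multivariate phase-comparison statistics. All outputs are
#' written under \code{out_dir}; every file embeds a hash of the
#' configuration, and a rerun with the same configuration is byte
#' identical.
#'
#' @param config A \code{run_config}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the summary list (also written as
#'   \code{summary.json}).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fs <- config$fs
  hash <- config_hash(config)
  S <- config$n_subjects
  L <- config$n_trials

  # Pass 1: events, markers, normalization durations.
  ev_summaries <- vector("list", S)
  for (s in seq_len(S)) {
    per_trial <- vector("list", L)
    for (i in seq_len(L)) {
      trial <- simulate_trial(trial_sim_config(config, s, i))
      res <- tryCatch(analyze_trial_events(trial), error = function(e)
        stop(sprintf("events failed for subject %d trial %d: %s",
                     s, i, conditionMessage(e)), call. = FALSE))
      seg <- res$segmentation
      per_trial[[i]] <- list(
        marker_s = analysis_marker(res$transition, config$protocol, fs),
        D = seg$D,
        seg = seg,
        events_s = lapply(split(res$events$events$sample,
                                paste(res$events$events$foot,
                                      res$events$events$event)),
                          function(ix) (ix - 1) / fs))
    }
    ev_summaries[[s]] <- per_trial
  }
  all_D <- unlist(lapply(ev_summaries, function(tt) sapply(tt, `[[`, "D")))
  target_len <- as.integer(round(3 * mean(all_D) * fs))

  # Pass 2: spectra (trials are re-simulated from their seeds).
  acc_win <- lapply(seq_len(S), function(s) coherence_accumulator())
  acc_norm <- lapply(seq_len(S), function(s) coherence_accumulator())
  pool_win <- coherence_accumulator()
  pool_norm <- coherence_accumulator()
  for (s in seq_len(S)) {
    for (i in seq_len(L)) {
      trial <- simulate_trial(trial_sim_config(config, s, i))
      info <- ev_summaries[[s]][[i]]
      sp <- morlet_spectra(trial$stimulus$samples, coupled_shear(trial), fs,
                           freqs = config$freqs, lag_ms = config$lag_ms)
      win <- center_window(sp, info$marker_s, config$window_s)
      acc_win[[s]] <- add_trial_spectra(acc_win[[s]], win)
      pool_win <- add_trial_spectra(pool_win, win)
      if (config$normalize) {
        nrm <- normalize_movement_time(sp, info$seg, target_len,
                                       config$protocol)
        acc_norm[[s]] <- add_trial_spectra(acc_norm[[s]], nrm)
        pool_norm <- add_trial_spectra(pool_norm, nrm)
      }
    }
  }

  per_subject <- vector("list", S)
  samples <- NULL
  for (s in seq_len(S)) {
    map <- accumulated_coherence(acc_win[[s]], config$alpha)
    write_coherence_map(map, file.path(out_dir,
                                       sprintf("coherence_subject%02d.tsv", s)),
                        config_hash = hash)
    b <- band_average(map, config$band[1], config$band[2])
    np <- detect_null_period(b, map$cl, 0, search_s = config$search_s)
    iv <- phase_windows(config, ev_summaries[[s]])
    pk_map <- if (config$normalize) {
      nm <- accumulated_coherence(acc_norm[[s]], config$alpha)
      write_coherence_map(nm, file.path(
        out_dir, sprintf("coherence_subject%02d_norm.tsv", s)),
        config_hash = hash)
      nm
    } else {
      map
    }
    pk <- peak_by_phase(pk_map, iv)
    per_subject[[s]] <- list(subject = s, cl = map$cl,
                             null_period = unclass(np), peaks = pk)
    samples <- rbind(samples,
                     data.frame(subject = s, phase = pk$phase,
                                peak = pk$peak, freq = pk$freq))
  }

  pooled_map <- accumulated_coherence(pool_win, config$alpha)
  write_coherence_map(pooled_map, file.path(out_dir, "coherence_pooled.tsv"),
                      config_hash = hash)
  pooled_band <- band_average(pooled_map, config$band[1], config$band[2])
  pooled_np <- detect_null_period(pooled_band, pooled_map$cl, 0,
                                  search_s = config$search_s)

  stats_out <- NULL
  if (S >= 6) {
    stats_out <- phase_statistics(samples)
    utils::write.table(stats_out$table,
                       file.path(out_dir, "stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  events_json <- list(config_hash = hash,
                      subjects = lapply(seq_len(S), function(s)
                        lapply(ev_summaries[[s]], function(x)
                          list(marker_s = x$marker_s, D = x$D,
                               events_s = x$events_s))))
  jsonlite::write_json(events_json, file.path(out_dir, "events.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  summary <- list(
    config = unclass(config), config_hash = hash,
    confidence_limits = list(
      per_subject = coherence_confidence_limit(L, config$alpha),
      pooled = if (S * L >= 2)
        coherence_confidence_limit(S * L, config$alpha) else NA),
    target_len = target_len,
    per_subject = per_subject,
    pooled = list(L = pooled_map$L, cl = pooled_map$cl,
                  null_period = unclass(pooled_np)),
    stats = if (is.null(stats_out)) NULL else stats_out$summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

# Phase windows on the tau axis used for peak extraction: normalized
# movement-time units for locomotor protocols (marker at 0, D = 1), window
# seconds relative to the marker for the posture protocol. Event positions
# are averaged across the subject's trials.
phase_windows <- function(config, trials) {
  if (config$protocol == "locomotor_initiation") {
    u <- sapply(trials, function(x) {
      on <- (x$seg$transition_onset - 1) / config$fs
      to <- (x$seg$phases$first_step - 1) / config$fs
      (to - on) / x$D
    })
    u1 <- mean(u[1, ]); u2 <- mean(u[2, ])
    list(quiet_standing = c(-2, 0), transition = c(0, u1),
         first_step = c(u1, u2))
  } else if (config$protocol == "locomotor_termination") {
    u <- sapply(trials, function(x) {
      en <- (x$seg$transition_end - 1) / config$fs
      ls <- (x$seg$phases$last_step - 1) / config$fs
      (ls - en) / x$D
    })
    v2 <- mean(u[1, ]); v1 <- mean(u[2, ])
    list(quiet_standing = c(0, 2), transition = c(v1, 0),
         last_step = c(v2, v1))
  } else {
    dur <- mean(sapply(trials, `[[`, "D"))
    half <- config$window_s / 2
    list(quiet_standing = c(-half, 0), transition = c(0, dur),
         shifted_posture = c(dur, half))
  }
}

# Omnibus phase test plus pairwise multivariate post hocs and univariate
# Bonferroni-corrected paired t-tests, Table-1 style.
phase_statistics <- function(samples) {
  phases <- unique(samples$phase)
  omni <- rm_manova_phases(samples)
  pairs <- utils::combn(phases, 2, simplify = FALSE)
  m <- length(pairs)
  rows <- list()
  for (pr in pairs) {
    wide <- function(ph, col) {
      sub <- samples[samples$phase == ph, ]
      sub[order(sub$subject), col]
    }
    a <- cbind(peak = wide(pr[1], "peak"), freq = wide(pr[1], "freq"))
    b <- cbind(peak = wide(pr[2], "peak"), freq = wide(pr[2], "freq"))
    ht <- hotelling_paired(a, b)
    tt <- paired_t_bonferroni(a, b, m = 2 * m)
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = paste(pr, collapse = " vs "),
      T2 = ht$T2, F = ht$F, df1 = ht$df1, df2 = ht$df2,
      p_multivariate = min(1, m * ht$p.value),
      p_peak = tt$p_adj[tt$measure == "peak"],
      p_freq = tt$p_adj[tt$measure == "freq"])
  }
  table <- do.call(rbind, rows)
  list(summary = list(omnibus = omni[c("T2", "F", "df1", "df2", "p.value")],
                      posthoc = table),
       table = table)
}
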