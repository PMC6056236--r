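#' Detect the vestibulo-motor null period around a transition
#'
#' Finds the contiguous stretch of the band-averaged coherence time course
#' that lies at or below the confidence limit and contains the transition
#' marker, or, failing that, the stretch that most recently precedes it.
#' The null period summarizes the suspension of vestibular balance control
#' around a motor-state transition: its start relative to the marker
#' (\code{onset_lead}, positive when the coherence drops before the
#' movement begins) and its duration.
#'
#' @param band \code{data.frame(tau, coherence)} from
#'   \code{\link{band_average}}.
#' @param cl Confidence limit the series is compared against.
#' @param transition_marker Marker position on the \code{tau} axis.
#' @param search_s Half-width of the search window around the marker
#'   (1.5 s for locomotor protocols, 3.5 s for posture, matching the
#'   displayed analysis windows).
#' @return An object of class \code{null_period}: \code{found},
#'   \code{drop_time} (tau at which the series falls below the limit),
#'   \code{onset_lead} (= marker - drop_time), \code{duration} (s) and
#'   \code{return_time}.
#' @export
detect_null_period <- function(band, cl, transition_marker, search_s = 1.5) {
  stopifnot(is.data.frame(band), all(c("tau", "coherence") %in% names(band)))
  tau <- band$tau
  if (transition_marker < tau[1] || transition_marker > tau[length(tau)])
    stop_invalid("transition marker %g lies outside the series [%g, %g]",
                 transition_marker, tau[1], tau[length(tau)])
  sel <- tau >= transition_marker - search_s & tau <= transition_marker + search_s
  tau <- tau[sel]
  co <- band$coherence[sel]
  dt <- stats::median(diff(tau))
  runs <- logical_runs(co <= cl)
  if (nrow(runs) == 0)
    return(structure(list(found = FALSE, drop_time = NA_real_,
                          onset_lead = NA_real_, duration = 0,
                          return_time = NA_real_),
                     class = "null_period"))
  starts <- tau[runs$start]
  ends_excl <- ifelse(runs$end > length(tau), tau[length(tau)] + dt,
                      tau[runs$end])
  containing <- which(starts <= transition_marker &
                        ends_excl > transition_marker)
  pick <- if (length(containing) > 0) {
    containing[1]
  } else {
    before <- which(ends_excl <= transition_marker)
    if (length(before) == 0)
      return(structure(list(found = FALSE, drop_time = NA_real_,
                            onset_lead = NA_real_, duration = 0,
                            return_time = NA_real_),
                       class = "null_period"))
    before[length(before)]
  }
  structure(
    list(found = TRUE, drop_time = starts[pick],
         onset_lead = transition_marker - starts[pick],
         duration = ends_excl[pick] - starts[pick],
         return_time = ends_excl[pick]),
    class = "null_period")
}

#' Peak coherence magnitude and frequency per movement phase
#'
#' For each requested phase, finds the maximum of the coherence map over
#' the phase's time window (all analysis frequencies), with ties broken by
#' the lowest frequency and then the earliest time.
#'
#' @param map A \code{coherence_map}.
#' @param intervals Named list of \code{c(lo, hi)} windows on the map's tau
#'   axis (half-open), or a \code{phase_segmentation} together with
#'   \code{fs} via \code{\link{phase_intervals_tau}}.
#' @param phases Character vector of phase names to evaluate (default: all
#'   names of \code{intervals}).
#' @return \code{data.frame(phase, peak, freq, tau)}.
#' @export
peak_by_phase <- function(map, intervals, phases = names(intervals)) {
  stopifnot(inherits(map, "coherence_map"))
  out <- lapply(phases, function(ph) {
    iv <- intervals[[ph]]
    if (is.null(iv)) stop_invalid("no interval for phase '%s'", ph)
    rows <- which(map$tau_axis >= iv[1] & map$tau_axis < iv[2])
    if (length(rows) == 0)
      stop_invalid("phase '%s' [%g, %g) is empty on the tau axis",
                   ph, iv[1], iv[2])
    sub <- map$c[rows, , drop = FALSE]
    pk <- max(sub)
    # ties: lowest frequency first, then earliest tau
    hits <- which(sub == pk, arr.ind = TRUE)
    hits <- hits[order(hits[, "col"], hits[, "row"]), , drop = FALSE]
    data.frame(phase = ph, peak = pk,
               freq = map$freq_axis[hits[1, "col"]],
               tau = map$tau_axis[rows[hits[1, "row"]]])
  })
  do.call(rbind, out)
}

#' Phase intervals of a segmentation on a spectra tau axis
#'
#' Converts the half-open sample intervals of a \code{phase_segmentation}
#' into windows on a tau axis expressed in force-record seconds (as
#' produced by \code{\link{morlet_spectra}}).
#'
#' @param seg A \code{phase_segmentation}.
#' @return Named list of \code{c(lo_s, hi_s)} windows.
#' @export
phase_intervals_tau <- function(seg) {
  stopifnot(inherits(seg, "phase_segmentation"))
  lapply(seg$phases, function(iv) (iv - 1) / seg$fs)
}

#' Pool spectra across subjects
#'
#' Concatenates per-subject trial spectra and computes the pooled
#' trial-averaged coherence, with the confidence limit for the total
#' segment count (e.g. 0.005 at the 99\% level for 1000 pooled segments,
#' 0.008 for 600).
#'
#' @param subject_spectra List (one element per subject) of lists of
#'   \code{timefreq_spectra}.
#' @param alpha Significance level (default 0.01).
#' @return A \code{coherence_map} with \code{L} equal to the total number
#'   of pooled segments.
#' @export
pool_subjects <- function(subject_spectra, alpha = 0.01) {
  flat <- do.call(c, subject_spectra)
  average_and_cohere(flat, alpha = alpha)
}

#' @export
print.null_period <- function(x, ...) {
  if (!x$found) {
    cat("null period: not found\n")
  } else {
    cat(sprintf(
      "null period: drop %.3f s (lead %.3f s before marker), duration %.3f s\n",
      x$drop_time, x$onset_lead, x$duration))
  }
  invisible(x)
}
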