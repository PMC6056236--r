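#' Write a trial recording to the delimited trial format
#'
#' One text file per trial: `# key=value` header lines (sampling rate, body
#' weight, protocol, head orientation, stimulus parameters), then
#' tab-separated columns `t, evs_mA, p{i}_fx, p{i}_fy, p{i}_fz, p{i}_copx,
#' p{i}_copy` for each plate. Values are written with 17 significant
#' digits, so a read/write round trip reproduces the recording exactly.
#' When the trial carries ground-truth annotations they are written to a
#' JSON sidecar `<path>.truth.json`.
#'
#' @param trial A \code{trial_recording}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  n <- length(trial$plates[[1]]$fz_N)
  hdr <- c(
    sprintf("# fs=%.17g", trial$fs),
    sprintf("# body_weight_N=%.17g", trial$body_weight_N),
    sprintf("# protocol=%s", trial$protocol),
    sprintf("# head_orientation=%s", trial$head_orientation),
    sprintf("# n_plates=%d", length(trial$plates)),
    sprintf("# evs_cutoff_hz=%.17g", trial$stimulus$cutoff_hz),
    sprintf("# evs_filter_order=%d", trial$stimulus$filter_order),
    sprintf("# evs_peak_mA=%.17g", trial$stimulus$peak_mA),
    sprintf("# evs_seed=%d", trial$stimulus$seed))
  cols <- list(t = (seq_len(n) - 1) / trial$fs,
               evs_mA = trial$stimulus$samples)
  for (i in seq_along(trial$plates)) {
    p <- trial$plates[[i]]
    cols[[sprintf("p%d_fx", i)]] <- p$fx_N
    cols[[sprintf("p%d_fy", i)]] <- p$fy_N
    cols[[sprintf("p%d_fz", i)]] <- p$fz_N
    cols[[sprintf("p%d_copx", i)]] <- p$cop_x_m
    cols[[sprintf("p%d_copy", i)]] <- p$cop_y_m
  }
  body <- do.call(paste, c(lapply(cols, function(v) sprintf("%.17g", v)),
                           sep = "\t"))
  writeLines(c(hdr, paste(names(cols), collapse = "\t"), body), path)
  if (!is.null(trial$truth)) {
    truth <- trial$truth
    truth$gain <- NULL                  # per-sample schedule stays in memory
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a trial recording from the delimited trial format
#'
#' Inverse of \code{\link{write_trial}}. Raises a parse error naming the
#' offending field when a required header or plate column is missing or
#' inconsistent. A ground-truth sidecar `<path>.truth.json` is attached if
#' present.
#'
#' @param path Trial file path.
#' @return A \code{trial_recording}.
#' @export
read_trial <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, regmatches(hdr_lines,
                                  regexec("^# ([^=]+)=(.*)$", hdr_lines)))
  if (is.null(kv)) stop_invalid("no '# key=value' header found in %s", path)
  hdr <- stats::setNames(as.list(kv[, 3]), kv[, 2])
  need <- c("fs", "body_weight_N", "protocol", "head_orientation", "n_plates")
  for (k in need) if (is.null(hdr[[k]]))
    stop_invalid("trial header is missing field '%s'", k)
  fs <- as.numeric(hdr$fs)
  if (!is.finite(fs) || fs <= 0) stop_invalid("bad fs in header: %s", hdr$fs)
  n_plates <- as.integer(hdr$n_plates)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  if (!all(c("t", "evs_mA") %in% names(tab)))
    stop_invalid("trial file is missing the t or evs_mA column")
  plates <- vector("list", n_plates)
  for (i in seq_len(n_plates)) {
    want <- sprintf("p%d_%s", i, c("fx", "fy", "fz", "copx", "copy"))
    miss <- setdiff(want, names(tab))
    if (length(miss) > 0)
      stop_invalid("plate %d is missing column(s): %s", i,
                   paste(miss, collapse = ", "))
    plates[[i]] <- list(fx_N = tab[[want[1]]], fy_N = tab[[want[2]]],
                        fz_N = tab[[want[3]]], cop_x_m = tab[[want[4]]],
                        cop_y_m = tab[[want[5]]])
  }
  stim <- structure(
    list(samples = tab$evs_mA, fs = fs,
         cutoff_hz = as.numeric(hdr$evs_cutoff_hz %||% NA),
         filter_order = as.integer(hdr$evs_filter_order %||% NA),
         peak_mA = as.numeric(hdr$evs_peak_mA %||% NA),
         seed = as.integer(hdr$evs_seed %||% NA)),
    class = "evs_stimulus")
  truth_path <- paste0(path, ".truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else {
    NULL
  }
  structure(
    list(stimulus = stim, plates = plates, fs = fs,
         protocol = hdr$protocol, head_orientation = hdr$head_orientation,
         body_weight_N = as.numeric(hdr$body_weight_N), truth = truth,
         config = NULL),
    class = "trial_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a coherence map as a delimited matrix with a JSON header
#'
#' First line: `# ` followed by a one-line JSON object (axes metadata, L,
#' alpha, confidence limit, lag, normalization mode, config hash if
#' given). Then a tab-separated matrix: first column tau, remaining
#' columns the coherence at each analysis frequency.
#'
#' @param map A \code{coherence_map}.
#' @param path Output path.
#' @param config_hash Optional hash string to embed.
#' @return \code{path}, invisibly.
#' @export
write_coherence_map <- function(map, path, config_hash = NULL) {
  stopifnot(inherits(map, "coherence_map"))
  meta <- list(L = map$L, alpha = map$alpha, cl = map$cl,
               lag_ms = map$lag_ms, freq_axis = map$freq_axis,
               norm = map$norm, config_hash = config_hash)
  hdr <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                       null = "null"))
  colnames <- paste(c("tau", sprintf("f%g", map$freq_axis)), collapse = "\t")
  body <- apply(cbind(map$tau_axis, map$c), 1, function(r)
    paste(sprintf("%.10g", r), collapse = "\t"))
  writeLines(c(hdr, colnames, body), path)
  invisible(path)
}

#' Read a coherence map written by \code{\link{write_coherence_map}}
#' @param path File path.
#' @return A \code{coherence_map}.
#' @export
read_coherence_map <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  tab <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t")
  structure(
    list(c = as.matrix(tab[, -1, drop = FALSE]), tau_axis = tab[[1]],
         freq_axis = meta$freq_axis, L = meta$L, alpha = meta$alpha,
         cl = meta$cl %||% NA_real_, lag_ms = meta$lag_ms,
         norm = meta$norm),
    class = "coherence_map")
}

#' Read a run configuration from JSON or YAML
#'
#' The file holds named fields understood by \code{\link{run_config}};
#' unknown fields raise an error. YAML requires the \pkg{yaml} package.
#'
#' @param path Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_invalid("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, vals)
}
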