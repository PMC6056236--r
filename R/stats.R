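#' Paired Hotelling's T-squared test
#'
#' One-sample Hotelling test on the paired differences of two matched
#' multivariate samples (one row per subject). With p-dimensional
#' measurements, \eqn{T^2 = n \bar d' S^{-1} \bar d} and
#' \eqn{F = \frac{n - p}{p (n - 1)} T^2} with \eqn{(p, n - p)} degrees of
#' freedom. In one dimension the F statistic equals the square of the
#' paired t statistic.
#'
#' @param a,b Numeric matrices (subjects x measures) with matching rows, or
#'   vectors for the one-dimensional case.
#' @return List with \code{T2}, \code{F}, \code{df1}, \code{df2},
#'   \code{p.value} and \code{n}.
#' @export
hotelling_paired <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop_invalid("paired samples must have identical dimensions")
  d <- a - b
  n <- nrow(d); p <- ncol(d)
  if (n <= p)
    stop_invalid("need more subjects (n = %d) than measures (p = %d)", n, p)
  hotelling_one_sample(d)
}

# One-sample T^2 that the mean of `d` (n x p) is zero.
hotelling_one_sample <- function(d) {
  n <- nrow(d); p <- ncol(d)
  dbar <- colMeans(d)
  if (all(d == 0)) {                   # exact tie: no evidence of an effect
    return(list(T2 = 0, F = 0, df1 = p, df2 = n - p, p.value = 1, n = n))
  }
  S <- stats::cov(d)
  qr_S <- qr(S)
  if (qr_S$rank < p)
    stop("covariance of the differences is singular; collect more subjects ",
         "or reduce the number of measures", call. = FALSE)
  T2 <- n * drop(crossprod(dbar, solve(qr_S, dbar)))
  Fstat <- (n - p) / (p * (n - 1)) * T2
  list(T2 = T2, F = Fstat, df1 = p, df2 = n - p,
       p.value = stats::pf(Fstat, p, n - p, lower.tail = FALSE), n = n)
}

#' Repeated-measures multivariate test of a phase effect
#'
#' Omnibus test that the (peak coherence, peak frequency) pair is identical
#' across three movement phases, computed as a one-sample Hotelling test on
#' the within-subject contrast vectors (phase 2 - phase 1 and phase 3 -
#' phase 1, for both measures: a 4-dimensional difference per subject).
#' Subjects with incomplete phase data are dropped with a warning.
#'
#' @param samples Data frame with columns \code{subject}, \code{phase},
#'   \code{peak}, \code{freq}; exactly three phase levels.
#' @return List with \code{T2}, \code{F}, \code{df1}, \code{df2},
#'   \code{p.value}, \code{n} and the phase ordering used.
#' @export
rm_manova_phases <- function(samples) {
  stopifnot(all(c("subject", "phase", "peak", "freq") %in% names(samples)))
  phases <- unique(as.character(samples$phase))
  if (length(phases) != 3)
    stop_invalid("expected exactly 3 phases, got %d", length(phases))
  subjects <- unique(samples$subject)
  rows <- lapply(subjects, function(s) {
    sub <- samples[samples$subject == s, ]
    if (!all(phases %in% sub$phase)) return(NULL)
    v <- sapply(phases, function(ph) {
      r <- sub[sub$phase == ph, ][1, ]
      c(r$peak, r$freq)
    })
    # contrasts vs the first phase, stacked over both measures
    c(v[1, 2] - v[1, 1], v[1, 3] - v[1, 1],
      v[2, 2] - v[2, 1], v[2, 3] - v[2, 1])
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (any(!keep))
    warning(sum(!keep), " subject(s) dropped for incomplete phase data")
  d <- do.call(rbind, rows[keep])
  if (is.null(d) || nrow(d) <= ncol(d))
    stop_invalid("too few complete subjects (%d) for a 4-dimensional test",
                 if (is.null(d)) 0L else nrow(d))
  out <- hotelling_one_sample(d)
  out$phases <- phases
  out
}

#' Bonferroni-corrected paired t-tests
#'
#' Two-sided paired t-test per measure with Bonferroni adjustment over
#' \code{m} comparisons (\code{p_adj = min(1, m p)}). Zero-variance
#' differences are reported as an exact tie (t = 0, p = 1) when the
#' measures agree, and as p = 0 when they differ by a nonzero constant.
#'
#' @param a,b Matched numeric matrices (subjects x measures) or vectors.
#' @param m Number of comparisons in the Bonferroni family (default: the
#'   number of measures).
#' @return \code{data.frame(measure, t, df, p, p_adj)}.
#' @export
paired_t_bonferroni <- function(a, b, m = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop_invalid("paired samples must have identical dimensions")
  if (is.null(m)) m <- ncol(a)
  if (m < 1) stop_invalid("m must be >= 1")
  meas <- colnames(a)
  if (is.null(meas)) meas <- paste0("measure", seq_len(ncol(a)))
  out <- lapply(seq_len(ncol(a)), function(j) {
    d <- a[, j] - b[, j]
    n <- length(d)
    if (stats::sd(d) == 0) {
      p <- if (mean(d) == 0) 1 else 0
      tt <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    } else {
      ht <- stats::t.test(d)
      tt <- unname(ht$statistic)
      p <- ht$p.value
    }
    data.frame(measure = meas[j], t = tt, df = n - 1L, p = p,
               p_adj = min(1, m * p))
  })
  do.call(rbind, out)
}
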