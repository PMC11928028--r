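# Peak and latency analysis of ThT traces.

#' Min-max normalize a ThT trace
#'
#' Rescales intensities to [0, 1]. Idempotent; errors on a constant trace
#' (zero dynamic range), because rescaling it is meaningless.
#'
#' @param trace a \code{\link{tht_trace}}.
#' @return normalized \code{\link{tht_trace}}.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "tht_trace"))
  rng <- range(trace$intensity)
  if (diff(rng) <= 0) stopf("normalize_trace(): zero dynamic range (constant trace)")
  # the dynamic range is only meaningful when the producer recorded it on a
  # calibrated scale; it is never synthesized from arbitrary raw units, so
  # peak calling stays invariant under affine rescaling of plain traces
  tht_trace(trace$times, (trace$intensity - rng[1]) / diff(rng),
            label = trace$label, normalized = TRUE,
            dynamic_range = trace$dynamic_range)
}

#' Detect hyperpolarization peaks in a normalized ThT trace
#'
#' Local maxima with prominence at least \code{min_prominence} (in normalized
#' units) and pairwise separation at least \code{min_separation} minutes.
#' Because the second hyperpolarization event is a sustained plateau rather
#' than a transient spike, a terminal plateau -- intensity staying at or above
#' \code{plateau_level} for at least \code{plateau_min_duration} minutes at
#' the end of the trace -- counts as the final peak, placed at the plateau
#' onset.
#'
#' Traces carrying a raw \code{dynamic_range} below \code{1 + min_dynamic}
#' are classified non-responsive and return an empty peak set: min-max
#' normalization of a near-flat trace only amplifies noise. The default
#' requires at least a 50% rise of the raw fluorescence over its minimum --
#' hyperpolarization events are of order a two-fold brightening, while
#' non-responding cells fluctuate by a few percent.
#'
#' @param trace a normalized \code{\link{tht_trace}} (see
#'   \code{\link{normalize_trace}}).
#' @param min_prominence minimum prominence as a fraction of the normalized
#'   range (default 0.15).
#' @param min_separation minimum peak separation (min, default 5).
#' @param plateau_level,plateau_min_duration terminal-plateau rule parameters
#'   (defaults 0.8 and 10 min).
#' @param min_dynamic minimum raw dynamic range (max/min - 1) for a trace to
#'   be considered responsive, when the trace records it (default 0.5).
#' @return object of class \code{peak_set}: \code{peak_times},
#'   \code{peak_heights}, \code{prominences}, \code{prominence_used},
#'   \code{plateau_peak} (is the last peak a terminal plateau?).
#' @export
detect_peaks <- function(trace, min_prominence = 0.15, min_separation = 5,
                         plateau_level = 0.8, plateau_min_duration = 10,
                         min_dynamic = 0.5) {
  stopifnot(inherits(trace, "tht_trace"))
  if (!trace$normalized) stopf("detect_peaks(): trace must be normalized first")
  empty <- structure(list(peak_times = numeric(0), peak_heights = numeric(0),
                          prominences = numeric(0),
                          prominence_used = min_prominence,
                          plateau_peak = FALSE), class = "peak_set")
  if (!is.null(trace$dynamic_range) &&
      trace$dynamic_range - 1 < min_dynamic) {
    return(empty)  # non-responsive cell
  }
  y <- trace$intensity; t <- trace$times; n <- length(y)
  if (n < 3L) return(empty)
  # local maxima (plateau-tolerant: first index of any flat top)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  prom <- vapply(cand, function(i) {
    # walk outward to the nearest higher ground on each side; the prominence
    # is the drop to the higher of the two intervening minima
    lmin <- min(y[seq_len(i)][rev(cumall_leq(rev(y[seq_len(i)]), y[i]))])
    rmin <- min(y[i:n][cumall_leq(y[i:n], y[i])])
    y[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  prom <- prom[prom >= min_prominence]
  # enforce separation, keeping the higher peak
  if (length(keep) > 1L) {
    ord <- order(y[keep], decreasing = TRUE)
    sel <- logical(length(keep))
    for (j in ord) {
      if (!any(sel & abs(t[keep] - t[keep[j]]) < min_separation)) sel[j] <- TRUE
    }
    prom <- prom[sel]; keep <- keep[sel]
    o <- order(keep); keep <- keep[o]; prom <- prom[o]
  }
  peak_times <- t[keep]; peak_heights <- y[keep]
  plateau_peak <- FALSE
  # terminal plateau rule
  t_end <- max(t)
  tail_ok <- y[t >= t_end - plateau_min_duration] >= plateau_level
  if (t_end - min(t) >= plateau_min_duration && length(tail_ok) && all(tail_ok)) {
    runs <- rev(cumall_leq(-rev(y), -plateau_level))  # y >= level, from end
    onset_idx <- min(which(runs))
    onset_t <- t[onset_idx]
    covered <- length(peak_times) && max(peak_times) >= onset_t - min_separation
    if (!covered) {
      peak_times <- c(peak_times, onset_t)
      peak_heights <- c(peak_heights, y[onset_idx])
      prom <- c(prom, NA_real_)
      plateau_peak <- TRUE
    } else if (length(peak_times) && max(peak_times) >= onset_t) {
      plateau_peak <- TRUE
    }
  }
  structure(list(peak_times = peak_times, peak_heights = peak_heights,
                 prominences = prom, prominence_used = min_prominence,
                 plateau_peak = plateau_peak), class = "peak_set")
}

# helper: logical run of elements all <= bound, scanning forward from start
cumall_leq <- function(x, bound) cumsum(x > bound + 1e-12) == 0L

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set: %d peak(s) at [%s] min%s\n", length(x$peak_times),
              paste(sprintf("%.3g", x$peak_times), collapse = ", "),
              if (x$plateau_peak) " (last is a terminal plateau)" else ""))
  invisible(x)
}

#' Number of peaks in a peak set
#' @param peaks a \code{peak_set}.
#' @return integer peak count.
#' @export
n_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  length(peaks$peak_times)
}

#' Time to the first hyperpolarization peak
#'
#' The latency of the first detected peak relative to stimulus onset (time
#' zero of the trace). For the single-rise-to-plateau phenotype the plateau
#' onset time is returned, since the plateau is the (only) detected peak.
#'
#' @param trace a normalized \code{\link{tht_trace}}.
#' @param ... passed to \code{\link{detect_peaks}}.
#' @return latency in minutes.
#' @export
time_to_first_peak <- function(trace, ...) {
  pk <- detect_peaks(trace, ...)
  if (n_peaks(pk) == 0L) {
    dots <- list(...)
    min_dynamic <- dots$min_dynamic %||% 0.5
    if (!is.null(trace$dynamic_range) && trace$dynamic_range - 1 < min_dynamic) {
      stopf("time_to_first_peak(): non-responsive trace (no hyperpolarization event)")
    }
    stopf("time_to_first_peak(): no peaks detected in trace '%s'", trace$label)
  }
  pk$peak_times[1L]
}

#' Latency summary statistics (mean, SD, SE)
#'
#' Sample mean, sample standard deviation (n - 1 denominator) and standard
#' error SD / sqrt(n), the form in which first-peak latencies are reported
#' for sparse cells, microclusters and biofilms. For a single observation the
#' SD is undefined and reported as 0 with a warning.
#'
#' @param latencies numeric vector of latencies (min).
#' @return object of class \code{latency_stats}: \code{n}, \code{mean},
#'   \code{sd}, \code{se}.
#' @export
latency_statistics <- function(latencies) {
  latencies <- as.numeric(latencies)
  if (length(latencies) == 0L) stopf("latency_statistics(): no latencies")
  if (any(!is.finite(latencies))) stopf("latency_statistics(): non-finite latencies")
  n <- length(latencies)
  s <- if (n == 1L) { warnf("latency_statistics(): n = 1, SD undefined, reporting 0"); 0 }
       else stats::sd(latencies)
  structure(list(n = n, mean = mean(latencies), sd = s, se = s / sqrt(n)),
            class = "latency_stats")
}

#' @export
print.latency_stats <- function(x, ...) {
  cat(sprintf("Latency: %.3g +/- %.3g +/- %.3g min (mean +/- SD +/- SE), n = %d\n",
              x$mean, x$sd, x$se, x$n))
  invisible(x)
}
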