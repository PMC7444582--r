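#' Moving-average smoothing with truncated edges
#'
#' Centered moving mean over \code{window} samples (5 in the standard
#' protocol). At the edges the window truncates to the samples available,
#' so the output has the same length as the input and a constant trace is
#' left unchanged.
#'
#' @param x numeric vector.
#' @param window odd window length, \code{<= length(x)}.
#' @return numeric vector, same length as \code{x}.
#' @export
smooth_trace <- function(x, window = 5L) {
  n <- length(x)
  if (window %% 2 == 0) stop("window must be odd (ambiguous center)")
  if (window > n) stop("window longer than trace")
  if (window == 1) return(x)
  h <- (window - 1) %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect peaks by prominence and width
#'
#' Candidate peaks are samples strictly greater than both neighbours; a
#' flat plateau counts once, at its middle sample (left-middle when even).
#' For each candidate, each flanking base is the minimum of the signal
#' between the peak and the nearer of (signal end, next sample exceeding
#' the peak value) on that side; prominence is the peak value minus the
#' higher base. Width is the horizontal extent, by linear interpolation, at
#' the height \code{value - prominence/2}. Peaks with prominence >=
#' \code{min_prominence} and width >= \code{min_width} are kept — the
#' standard analysis uses 0.1 normalized units and 5 samples.
#'
#' Detection is invariant to adding a constant, and prominences scale
#' linearly with the trace.
#'
#' @param x numeric vector (typically a smoothed F/F0 trace), length >= 3.
#' @param min_prominence minimum prominence, in the trace's units.
#' @param min_width minimum width in samples (equal to seconds at 1 frame/s).
#' @param dt seconds per sample, used only to report peak times.
#' @return data frame with columns \code{index} (0-based sample),
#'   \code{time} (s), \code{value}, \code{prominence}, \code{width}
#'   (samples), sorted by index. Zero rows when nothing passes.
#' @export
find_peaks <- function(x, min_prominence = 0.1, min_width = 5, dt = 1.0) {
  n <- length(x)
  if (n < 3) stop("trace must have length >= 3")

  # candidate maxima, plateaus collapsed to their (left-)middle sample
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) cand <- c(cand, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(cand) == 0)
    return(empty_peaks())

  rows <- lapply(cand, function(p) {
    v <- x[p]
    # left interval: back to the sample after the nearest higher sample
    lo <- p
    while (lo > 1L && x[lo - 1L] <= v) lo <- lo - 1L
    left_base <- min(x[lo:p])
    hi <- p
    while (hi < n && x[hi + 1L] <= v) hi <- hi + 1L
    right_base <- min(x[p:hi])
    prom <- v - max(left_base, right_base)
    h <- v - prom / 2
    # crossings of h within [lo, p] and [p, hi]; a sample below h exists
    # on both sides because each base is at most v - prom < h
    k <- p
    while (x[k] >= h) k <- k - 1L
    left_pos <- k + (h - x[k]) / (x[k + 1L] - x[k])
    k <- p
    while (x[k] >= h) k <- k + 1L
    right_pos <- k - (h - x[k]) / (x[k - 1L] - x[k])
    c(index = p - 1L, value = v, prominence = prom,
      width = right_pos - left_pos)
  })
  res <- as.data.frame(do.call(rbind, rows))
  res$time <- res$index * dt
  res <- res[res$prominence >= min_prominence & res$width >= min_width,
             c("index", "time", "value", "prominence", "width")]
  rownames(res) <- NULL
  res
}

empty_peaks <- function() {
  data.frame(index = integer(0), time = numeric(0), value = numeric(0),
             prominence = numeric(0), width = numeric(0))
}

#' Variance of the first derivative of a trace
#'
#' A flatness statistic: the sample variance (n - 1 denominator) of the
#' successive differences of the trace. Flat or linearly ramping traces
#' score 0; pulsing traces score high. Used to quantify how quickly the
#' fluorescence changes with time when comparing conditions.
#'
#' @param x numeric vector or a \code{calcium_trace} (its \code{F_norm}
#'   is used).
#' @return scalar variance, in (trace units / sample)^2.
#' @export
derivative_variance <- function(x) {
  if (inherits(x, "calcium_trace")) x <- x$F_norm
  if (length(x) < 3) stop("trace must have length >= 3")
  var(diff(x))
}

#' Compute pulse metrics for one transit
#'
#' The normalized trace is smoothed, restricted to the transit window
#' (entry to sp-ut valve close, or to the end of the recording when the
#' valve never closes), and peaks are detected by prominence/width. The
#' metrics are: number of peaks; peaks per second over the transit
#' duration; time after entry to the maximum calcium signal (the
#' highest-valued detected peak, earliest on ties); time after entry for
#' the smoothed trace to first reach half that maximum; and the variance
#' of the first derivative of the smoothed transit segment.
#'
#' @param trace a \code{calcium_trace}; either its \code{entry_frame} or an
#'   attached [event_record()] must provide the entry frame.
#' @param smooth_window moving-average window (samples).
#' @param min_prominence,min_width peak filter thresholds.
#' @param half_max_mode \code{"absolute"} takes half of the peak's
#'   normalized value; \code{"baseline_subtracted"} takes the level halfway
#'   between baseline (1.0) and the peak.
#' @return object of class \code{pulse_metrics}: list with \code{n_peaks},
#'   \code{peaks_per_second}, \code{t_half_max}, \code{t_max} (s after
#'   entry, \code{NA} when no peak passes), \code{deriv_variance},
#'   \code{duration} (s), and the peak table.
#' @export
compute_metrics <- function(trace, smooth_window = 5L, min_prominence = 0.1,
                            min_width = 5,
                            half_max_mode = c("absolute",
                                              "baseline_subtracted")) {
  stopifnot(inherits(trace, "calcium_trace"))
  half_max_mode <- match.arg(half_max_mode)
  entry <- trace$entry_frame
  if ((is.null(entry) || is.na(entry)) && !is.null(trace$events))
    entry <- trace$events$entry_start
  if (is.null(entry) || is.na(entry))
    stop("entry annotation missing: cannot anchor transit metrics")
  n <- length(trace$F_norm)
  last <- n - 1L  # 0-based index of the final frame
  vclose <- if (!is.null(trace$events)) trace$events$valve_close else NA
  end <- if (!is.null(vclose) && !is.na(vclose)) vclose else last

  sm <- smooth_trace(trace$F_norm, smooth_window)
  seg <- sm[(entry + 1):(end + 1)]  # 0-based entry..end inclusive
  pk <- if (length(seg) >= 3)
    find_peaks(seg, min_prominence, min_width, dt = trace$dt)
  else empty_peaks()
  if (nrow(pk) > 0) pk$index <- pk$index + entry
  pk$time <- pk$index * trace$dt

  duration <- (end - entry) * trace$dt
  n_peaks <- nrow(pk)
  if (n_peaks > 0) {
    vmax <- max(pk$value)
    imax <- pk$index[which(pk$value == vmax)[1]]  # earliest on ties
    t_max <- (imax - entry) * trace$dt
    half <- if (half_max_mode == "absolute") vmax / 2 else (vmax + 1) / 2
    rel <- which(seg >= half)
    t_half <- if (length(rel) > 0) (rel[1] - 1) * trace$dt else NA_real_
  } else {
    t_max <- NA_real_
    t_half <- NA_real_
  }
  structure(list(n_peaks = n_peaks,
                 peaks_per_second = if (duration > 0) n_peaks / duration
                                    else NA_real_,
                 t_half_max = t_half,
                 t_max = t_max,
                 deriv_variance = var(diff(seg)),
                 duration = duration,
                 entry_frame = entry,
                 end_frame = end,
                 peaks = pk),
            class = "pulse_metrics")
}

#' @export
print.pulse_metrics <- function(x, ...) {
  cat("<pulse_metrics>", x$n_peaks, "peaks over", x$duration, "s (",
      format(x$peaks_per_second, digits = 4), "peaks/s )\n")
  cat("  t_half_max:", format(x$t_half_max, digits = 4),
      "s | t_max:", format(x$t_max, digits = 4),
      "s | deriv var:", format(x$deriv_variance, digits = 4), "\n")
  invisible(x)
}
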