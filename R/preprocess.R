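#' Zero-phase band-pass filter a raw recording
#'
#' Applies a Butterworth band-pass (default 250--7000 Hz) forward and
#' backward (\code{signal::filtfilt}) so that spike times are not shifted
#' -- a requirement for the +/-5 ms correlation analysis downstream.
#'
#' @param raw a \code{"raw_recording"}.
#' @param low_hz,high_hz pass-band corner frequencies, Hz; must satisfy
#'   \code{0 < low < high < sampling_rate/2}.
#' @param order Butterworth order (per pass).
#' @return A \code{"raw_recording"} of the same shape, filtered.
#' @export
bandpass <- function(raw, low_hz = 250, high_hz = 7000, order = 2) {
  stopifnot(inherits(raw, "raw_recording"))
  nyq <- raw$sampling_rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band must satisfy 0 < low < high < Nyquist", call. = FALSE)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- raw
  for (i in seq_len(nrow(raw$samples)))
    out$samples[i, ] <- signal::filtfilt(bf, raw$samples[i, ])
  out$band_hz <- c(low_hz, high_hz)
  out
}

#' Peak-to-peak population burst trace
#'
#' Reduces one channel of raw signal to the peak-to-peak amplitude
#' (max minus min) in consecutive non-overlapping windows (default 45 ms),
#' the standard low-rate envelope used to quantify the population burst
#' pattern.  Trailing samples that do not fill a window are dropped.
#'
#' @param raw a \code{"raw_recording"}.
#' @param channel channel index (row of the sample matrix).
#' @param window_ms window length, ms.
#' @return An object of class \code{"burst_trace"}: \code{values}
#'   (amplitude per window), \code{window_ms}, \code{t0}, and
#'   \code{sampling_rate_hz}.
#' @export
peak_to_peak_trace <- function(raw, channel = 1, window_ms = 45) {
  stopifnot(inherits(raw, "raw_recording"))
  x <- raw$samples[channel, ]
  w <- round(window_ms / 1000 * raw$sampling_rate_hz)
  if (length(x) < w) stop("signal shorter than one window", call. = FALSE)
  n_win <- floor(length(x) / w)
  m <- matrix(x[seq_len(n_win * w)], nrow = w)
  vals <- apply(m, 2, function(col) max(col) - min(col))
  out <- list(values = vals, window_ms = window_ms, t0 = 0,
              window_s = w / raw$sampling_rate_hz)
  class(out) <- "burst_trace"
  out
}

#' Detect population bursts on a burst trace
#'
#' Thresholds the peak-to-peak trace at \code{median + k_sd} scaled median
#' absolute deviations (robust statistics, so the bursts themselves do not
#' inflate the threshold); contiguous supra-threshold runs separated by
#' less than \code{min_gap_ms} are merged into one burst.  Returns
#' time-ordered, non-overlapping bursts.
#'
#' @param trace a [peak_to_peak_trace()] result.
#' @param k_sd threshold in scaled MADs above the trace median.
#' @param min_gap_ms sub-threshold gaps shorter than this are bridged.
#' @param min_duration_ms supra-threshold runs shorter than this are
#'   discarded (single-window blips are not population bursts).
#' @return Data frame with \code{onset_s}, \code{offset_s},
#'   \code{peak_amplitude}; zero rows when nothing crosses threshold.
#' @export
detect_population_bursts <- function(trace, k_sd = 3, min_gap_ms = 200,
                                     min_duration_ms = 90) {
  stopifnot(inherits(trace, "burst_trace"))
  v <- trace$values
  if (length(v) == 0) stop("empty burst trace", call. = FALSE)
  thr <- stats::median(v) + k_sd * stats::mad(v)
  if (!is.finite(thr)) thr <- Inf
  above <- which(v > thr)
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_amplitude = numeric(0))
  if (length(above) == 0) return(empty)
  gap_win <- max(1, round(min_gap_ms / trace$window_ms))
  starts <- above[c(TRUE, diff(above) > gap_win)]
  ends <- above[c(diff(above) > gap_win, TRUE)]
  long_enough <- (ends - starts + 1) * trace$window_ms >= min_duration_ms
  starts <- starts[long_enough]
  ends <- ends[long_enough]
  if (length(starts) == 0) return(empty)
  ws <- trace$window_s
  data.frame(
    onset_s = trace$t0 + (starts - 1) * ws,
    offset_s = trace$t0 + ends * ws,
    peak_amplitude = mapply(function(a, b) max(v[a:b]), starts, ends)
  )
}

#' Average burst-aligned amplitude shape
#'
#' Aligns the burst trace to each burst onset and averages pointwise over
#' bursts, producing the mean population burst waveform (e.g. for
#' comparing eupneic and gasping burst shapes).
#'
#' @param trace a [peak_to_peak_trace()] result.
#' @param bursts data frame from [detect_population_bursts()].
#' @param pre_s,post_s alignment window around each onset, seconds.
#' @return List with \code{time_s} (relative to onset), \code{mean}
#'   (average amplitude), and \code{n_bursts} actually used (bursts whose
#'   window falls outside the trace are dropped).
#' @export
average_burst_shape <- function(trace, bursts, pre_s = 0.5, post_s = 1.5) {
  stopifnot(inherits(trace, "burst_trace"))
  if (nrow(bursts) == 0) stop("no bursts to average", call. = FALSE)
  ws <- trace$window_s
  n_pre <- round(pre_s / ws)
  n_post <- round(post_s / ws)
  idx0 <- round((bursts$onset_s - trace$t0) / ws) + 1
  keep <- idx0 - n_pre >= 1 & idx0 + n_post <= length(trace$values)
  if (!any(keep)) stop("no burst window fits inside the trace", call. = FALSE)
  rows <- lapply(idx0[keep], function(i)
    trace$values[(i - n_pre):(i + n_post)])
  m <- do.call(rbind, rows)
  list(time_s = seq(-n_pre, n_post) * ws,
       mean = colMeans(m),
       n_bursts = sum(keep))
}

# Robust SD of a filtered trace: scaled median absolute deviation, so
# spikes themselves do not inflate the detection threshold.
robust_sd <- function(x) stats::mad(x, center = stats::median(x))

#' Threshold spike detection on a filtered channel
#'
#' Detects negative-going threshold crossings at \code{threshold_sd}
#' robust standard deviations (scaled MAD) of the filtered signal, the
#' convention for dominantly negative extracellular spikes.  After each
#' event, detection is dead for one snippet length; a waveform snippet
#' (default 1 ms before, 2 ms after) is cut around the spike trough (the
#' signal minimum within 0.5 ms of the crossing), which aligns waveforms
#' for feature extraction.  Events whose snippet would overrun the
#' recording are dropped and counted.
#'
#' @param raw a filtered \code{"raw_recording"}.
#' @param channel channel index (row of the sample matrix).
#' @param threshold_sd detection threshold in robust SDs (2.6 for unit
#'   channels, 4.0 for multi-unit channels).
#' @param pre_ms,post_ms snippet extent around the crossing, ms.
#' @return An object of class \code{"detection_result"}:
#'   \code{crossing_times} (event times at the aligned trough, seconds,
#'   sorted), \code{waveforms} (events x samples matrix),
#'   \code{threshold_sd}, \code{threshold} (signal units),
#'   \code{channel}, \code{n_edge_dropped}, \code{sampling_rate_hz}.
#' @export
detect_spikes <- function(raw, channel = 1, threshold_sd = 2.6,
                          pre_ms = 1, post_ms = 2) {
  stopifnot(inherits(raw, "raw_recording"))
  if (threshold_sd <= 0) stop("threshold_sd must be positive", call. = FALSE)
  x <- raw$samples[channel, ]
  fs <- raw$sampling_rate_hz
  thr <- -threshold_sd * robust_sd(x)
  n_pre <- round(pre_ms / 1000 * fs)
  n_post <- round(post_ms / 1000 * fs)
  dead <- n_pre + n_post + 1L

  below <- x < thr
  crossings <- which(below & !c(FALSE, below[-length(below)]))
  # one event per crossing, with a dead time of one snippet
  kept <- integer(0)
  last <- -Inf
  for (i in crossings) {
    if (i - last >= dead) { kept <- c(kept, i); last <- i }
  }
  # align each event at the deepest trough within the snippet post-window
  # of the crossing: a shallow (noise) crossing immediately followed by a
  # true spike then yields one event aligned at the spike, instead of the
  # spike being lost to the dead time
  n_align <- n_post
  troughs <- vapply(kept, function(i) {
    j <- min(i + n_align, length(x))
    i - 1L + which.min(x[i:j])
  }, integer(1))
  in_bounds <- troughs - n_pre >= 1 & troughs + n_post <= length(x)
  dropped <- sum(!in_bounds)
  kept <- kept[in_bounds]
  troughs <- troughs[in_bounds]
  waveforms <- if (length(kept) > 0) {
    t(vapply(troughs, function(i) x[(i - n_pre):(i + n_post)],
             numeric(n_pre + n_post + 1L)))
  } else {
    matrix(numeric(0), nrow = 0, ncol = n_pre + n_post + 1L)
  }
  out <- list(crossing_times = (troughs - 1) / fs,
              waveforms = waveforms,
              threshold_sd = threshold_sd,
              threshold = thr,
              channel = channel,
              n_edge_dropped = dropped,
              pre_ms = pre_ms, post_ms = post_ms,
              sampling_rate_hz = fs)
  class(out) <- "detection_result"
  out
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("Detection: %d events on channel %s at %.1f robust SD",
              length(x$crossing_times), as.character(x$channel),
              x$threshold_sd))
  if (x$n_edge_dropped > 0)
    cat(sprintf(" (%d edge events dropped)", x$n_edge_dropped))
  cat("\n")
  invisible(x)
}
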