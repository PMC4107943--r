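#' Binarize spike trains
#'
#' Converts spike trains to binary occupancy over half-open 1-ms bins
#' \code{[b, b+1)}: a bin is 1 iff the element fired at least once in it
#' (multiple spikes in one bin collapse to a single 1; the number of
#' collapsed spikes is logged).  The representation is sparse: per
#' element, the sorted 0-based indices of occupied bins.
#'
#' @param trains a \code{"spike_train_set"} or a named list of spike-time
#'   vectors (seconds).
#' @param bin_ms bin width, ms.
#' @param t_start,t_end common analysis interval, seconds; spikes outside
#'   \code{[t_start, t_end)} are ignored.  \code{t_end} defaults to the
#'   set's duration (or the latest spike rounded up).
#' @return An object of class \code{"binary_spike_matrix"}: \code{bins}
#'   (named list of occupied-bin indices), \code{n_bins}, \code{bin_ms},
#'   \code{t0}, \code{n_collapsed}.
#' @export
binarize <- function(trains, bin_ms = 1, t_start = 0, t_end = NULL) {
  times <- if (inherits(trains, "spike_train_set")) trains$times else trains
  stopifnot(is.list(times), !is.null(names(times)))
  if (is.null(t_end)) {
    t_end <- if (inherits(trains, "spike_train_set")) trains$duration_s
             else ceiling(max(c(0, unlist(times, use.names = FALSE))))
  }
  if (t_end <= t_start) stop("empty analysis interval", call. = FALSE)
  n_bins <- as.integer(floor((t_end - t_start) * 1000 / bin_ms + 1e-9))
  collapsed <- 0L
  bins <- lapply(times, function(tt) {
    tt <- tt[tt >= t_start & tt < t_start + n_bins * bin_ms / 1000]
    b <- as.integer(floor((tt - t_start) * 1000 / bin_ms))
    ub <- unique(b)
    collapsed <<- collapsed + length(b) - length(ub)
    sort(ub)
  })
  out <- list(bins = bins, n_bins = n_bins, bin_ms = bin_ms,
              t0 = t_start, n_collapsed = collapsed)
  class(out) <- "binary_spike_matrix"
  out
}

#' @export
print.binary_spike_matrix <- function(x, ...) {
  cat(sprintf("Binary spike matrix: %d elements x %d bins (%g ms)\n",
              length(x$bins), x$n_bins, x$bin_ms))
  if (x$n_collapsed > 0)
    cat(sprintf("  %d spikes collapsed into shared bins\n", x$n_collapsed))
  invisible(x)
}

#' @export
as.matrix.binary_spike_matrix <- function(x, ...) {
  m <- matrix(0L, nrow = length(x$bins), ncol = x$n_bins,
              dimnames = list(names(x$bins), NULL))
  for (i in seq_along(x$bins)) m[i, x$bins[[i]] + 1L] <- 1L
  m
}

# Pair counts by signed lag: C(tau) = #{(i,j): b_j - a_i = tau bins},
# tau = -max_lag..max_lag, counted on collapsed (binary) bins.
correlogram_counts <- function(a_bins, b_bins, n_bins, max_lag) {
  occ <- logical(n_bins)
  occ[b_bins + 1L] <- TRUE
  taus <- -max_lag:max_lag
  counts <- integer(length(taus))
  for (i in seq_along(taus)) {
    idx <- a_bins + taus[i]
    idx <- idx[idx >= 0L & idx < n_bins]
    counts[i] <- sum(occ[idx + 1L])
  }
  names(counts) <- taus
  counts
}

new_correlogram <- function(lags_ms, counts, n_a, n_b, n_bins, bin_ms,
                            analysis_lag_ms, noise_lag_ms, significance_sd,
                            kind, pair = c(NA, NA)) {
  values <- as.numeric(counts) * as.numeric(n_bins) / (n_a * n_b)
  names(values) <- names(counts)
  out <- list(lags_ms = lags_ms, counts = counts, values = values,
              n_a = n_a, n_b = n_b, n_bins = n_bins, bin_ms = bin_ms,
              analysis_lag_ms = analysis_lag_ms, noise_lag_ms = noise_lag_ms,
              significance_sd = significance_sd, kind = kind, pair = pair,
              baseline = NA_real_, noise_sd = NA_real_,
              peak_value = NA_real_, peak_lag_ms = NA_real_,
              significant = NA, evaluable = TRUE, shape = NA_character_)
  class(out) <- "correlogram"
  out
}

#' Rate-normalized cross-correlogram of two spike trains
#'
#' Counts spike pairs by signed lag (1-ms bins after binarization) and
#' normalizes each bin by the count expected under independence,
#' \eqn{N_a N_b / n_{bins}}, so the value is dimensionless, ~1 for
#' independent trains, and invariant under proportional rate changes.
#' The correlogram is computed over the full noise window (default
#' +/-50 ms); the peak is taken over the +/-5 ms analysis window, the
#' baseline and correlation-noise SD over the flank lags, and the peak is
#' flagged significant when it exceeds the baseline by more than
#' \code{significance_sd} noise SDs.
#'
#' @param a,b spike-time vectors in seconds.
#' @param duration_s common analysis interval length, seconds.
#' @param t_start interval start, seconds.
#' @param bin_ms bin width, ms.
#' @param analysis_lag_ms peak-search half-window, ms.
#' @param noise_lag_ms full correlogram half-window, ms (flanks
#'   \code{analysis_lag_ms < |tau| <= noise_lag_ms} estimate the noise).
#' @param significance_sd significance threshold in noise SDs.
#' @param min_spikes minimum spikes required of both trains; fewer raises
#'   a condition of class \code{"rhythmnet_too_few_spikes"} so callers can
#'   exclude (not zero) the pair.
#' @param pair optional pair of element ids, recorded in the result.
#' @return An object of class \code{"correlogram"}; see
#'   [assess_significance()] for the peak fields.
#' @export
#' @examples
#' a <- sort(runif(300, 0, 60))
#' b <- a + 0.002   # b echoes a at +2 ms
#' cross_correlogram(a, b, duration_s = 61)$peak_lag_ms
cross_correlogram <- function(a, b, duration_s, t_start = 0, bin_ms = 1,
                              analysis_lag_ms = 5, noise_lag_ms = 50,
                              significance_sd = 5, min_spikes = 50,
                              pair = c(NA, NA)) {
  if (analysis_lag_ms >= noise_lag_ms)
    stop("noise window must be wider than the analysis window", call. = FALSE)
  bsm <- binarize(list(a = a, b = b), bin_ms = bin_ms,
                  t_start = t_start, t_end = t_start + duration_s)
  cross_correlogram_binned(bsm$bins$a, bsm$bins$b, bsm$n_bins, bin_ms,
                           analysis_lag_ms, noise_lag_ms, significance_sd,
                           min_spikes, pair)
}

cross_correlogram_binned <- function(a_bins, b_bins, n_bins, bin_ms = 1,
                                     analysis_lag_ms = 5, noise_lag_ms = 50,
                                     significance_sd = 5, min_spikes = 50,
                                     pair = c(NA, NA)) {
  n_a <- length(a_bins)
  n_b <- length(b_bins)
  if (n_a < min_spikes || n_b < min_spikes) {
    cond <- structure(
      class = c("rhythmnet_too_few_spikes", "error", "condition"),
      list(message = sprintf(
        "too few spikes for pair (%d, %d; need %d)", n_a, n_b, min_spikes),
        call = NULL))
    stop(cond)
  }
  max_lag <- as.integer(round(noise_lag_ms / bin_ms))
  counts <- correlogram_counts(a_bins, b_bins, n_bins, max_lag)
  cg <- new_correlogram(lags_ms = (-max_lag:max_lag) * bin_ms,
                        counts = counts, n_a = n_a, n_b = n_b,
                        n_bins = n_bins, bin_ms = bin_ms,
                        analysis_lag_ms = analysis_lag_ms,
                        noise_lag_ms = noise_lag_ms,
                        significance_sd = significance_sd,
                        kind = "cross", pair = pair)
  assess_significance(cg)
}

#' Auto-correlogram of a spike train
#'
#' Same machinery as [cross_correlogram()] with the train against itself;
#' zero-lag self-pairs are excluded, so a refractory-clean train shows
#' empty bins around lag 0 -- the standard sorting-quality check.
#'
#' @inheritParams cross_correlogram
#' @param train spike times in seconds.
#' @param min_spikes minimum number of spikes.
#' @return A \code{"correlogram"} with \code{kind = "auto"}.
#' @export
autocorrelogram <- function(train, duration_s, t_start = 0, bin_ms = 1,
                            analysis_lag_ms = 5, noise_lag_ms = 50,
                            min_spikes = 2) {
  if (length(train) < min_spikes)
    stop("too few spikes for an auto-correlogram", call. = FALSE)
  bsm <- binarize(list(a = train), bin_ms = bin_ms,
                  t_start = t_start, t_end = t_start + duration_s)
  a <- bsm$bins$a
  max_lag <- as.integer(round(noise_lag_ms / bin_ms))
  counts <- correlogram_counts(a, a, bsm$n_bins, max_lag)
  counts[as.character(0)] <- counts[as.character(0)] - length(a)  # self-pairs
  cg <- new_correlogram(lags_ms = (-max_lag:max_lag) * bin_ms,
                        counts = counts, n_a = length(a), n_b = length(a),
                        n_bins = bsm$n_bins, bin_ms = bin_ms,
                        analysis_lag_ms = analysis_lag_ms,
                        noise_lag_ms = noise_lag_ms,
                        significance_sd = 5, kind = "auto")
  cg$baseline <- estimate_noise_sd(cg)$baseline
  cg$noise_sd <- estimate_noise_sd(cg)$noise_sd
  cg
}

#' Estimate correlation noise from correlogram flanks
#'
#' The correlation noise is the fluctuation of the normalized correlogram
#' attributable to chance coincidences; it is estimated surrogate-free
#' from the flank lags outside the analysis window
#' (\code{analysis_lag_ms < |tau| <= noise_lag_ms}): the baseline is
#' their mean, the noise SD their standard deviation.
#'
#' @param corr a \code{"correlogram"}.
#' @return List with \code{baseline} and \code{noise_sd}.
#' @export
estimate_noise_sd <- function(corr) {
  stopifnot(inherits(corr, "correlogram"))
  flank <- abs(corr$lags_ms) > corr$analysis_lag_ms &
    abs(corr$lags_ms) <= corr$noise_lag_ms
  if (!any(flank))
    stop("noise window must be wider than the analysis window", call. = FALSE)
  v <- corr$values[flank]
  list(baseline = mean(v), noise_sd = stats::sd(v))
}

#' Flag a correlogram peak as significant
#'
#' Locates the peak (maximum normalized value) within the analysis
#' window, ties broken toward smaller \code{|lag|} then toward negative
#' lag, and marks it significant when \code{peak - baseline} exceeds
#' \code{significance_sd} times the flank noise SD.  A flat correlogram
#' (zero noise SD) is marked non-evaluable, never auto-significant.
#'
#' @param corr a \code{"correlogram"}.
#' @return The correlogram with \code{baseline}, \code{noise_sd},
#'   \code{peak_value}, \code{peak_lag_ms}, \code{significant},
#'   \code{evaluable} and (when significant) \code{shape} filled in.
#' @export
assess_significance <- function(corr) {
  stopifnot(inherits(corr, "correlogram"))
  ns <- estimate_noise_sd(corr)
  corr$baseline <- ns$baseline
  # floor the flank SD so that the k-SD rule keeps its nominal
  # confidence for sparse trains: with few coincidences per bin the
  # count distribution is Poisson-skewed and the empirical flank SD
  # underestimates its tail, so the floor is set from the Poisson
  # quantile at the confidence level the k-SD rule implies
  scale <- as.numeric(corr$n_bins) / (corr$n_a * corr$n_b)
  m_flank <- max(ns$baseline / scale, 0)
  q <- stats::qpois(stats::pnorm(corr$significance_sd), m_flank)
  poisson_floor <- (q - m_flank) / corr$significance_sd * scale
  corr$noise_sd_empirical <- ns$noise_sd
  corr$noise_sd <- max(ns$noise_sd, poisson_floor, na.rm = TRUE)
  win <- abs(corr$lags_ms) <= corr$analysis_lag_ms
  lags <- corr$lags_ms[win]
  vals <- corr$values[win]
  ord <- order(abs(lags), lags)   # smaller |lag| first, then negative lag
  peak_i <- ord[which.max(vals[ord])]
  corr$peak_value <- unname(vals[peak_i])
  corr$peak_lag_ms <- unname(lags[peak_i])
  if (!is.finite(corr$noise_sd) || corr$noise_sd <= 0) {
    corr$evaluable <- FALSE
    corr$significant <- FALSE
  } else {
    corr$evaluable <- TRUE
    corr$significant <-
      (corr$peak_value - corr$baseline) > corr$significance_sd * corr$noise_sd
  }
  if (isTRUE(corr$significant)) corr$shape <- classify_peak_shape(corr)
  corr
}

#' Classify the shape of a significant correlogram peak
#'
#' Categories follow the observed peak taxonomy: peaks whose
#' supra-threshold region includes zero lag are \code{"zero_sharp"}
#' (width at most \code{width_sharp} bins) or \code{"zero_broad"};
#' displaced peaks are \code{"lag_short"} (|lag| 0.1--2 ms) or
#' \code{"lag_long"} (|lag| 2.1--5 ms).
#'
#' @param corr a significant \code{"correlogram"}.
#' @param width_sharp maximum width (bins) of a sharp zero-lag peak.
#' @return One of \code{"zero_sharp"}, \code{"zero_broad"},
#'   \code{"lag_short"}, \code{"lag_long"}.
#' @export
classify_peak_shape <- function(corr, width_sharp = 2) {
  stopifnot(inherits(corr, "correlogram"))
  if (!isTRUE(corr$significant) &&
      !((corr$peak_value - corr$baseline) >
          corr$significance_sd * corr$noise_sd))
    stop("peak-shape classification requires a significant correlogram",
         call. = FALSE)
  win_idx <- which(abs(corr$lags_ms) <= corr$analysis_lag_ms)
  lags <- corr$lags_ms[win_idx]
  supra <- (corr$values[win_idx] - corr$baseline) >
    corr$significance_sd * corr$noise_sd
  peak_pos <- match(corr$peak_lag_ms, lags)
  # maximal contiguous supra-threshold run containing the peak
  lo <- peak_pos
  while (lo > 1 && supra[lo - 1]) lo <- lo - 1
  hi <- peak_pos
  while (hi < length(lags) && supra[hi + 1]) hi <- hi + 1
  region <- lags[lo:hi]
  if (any(region == 0)) {
    if (length(region) <= width_sharp) "zero_sharp" else "zero_broad"
  } else if (abs(corr$peak_lag_ms) <= 2) {
    "lag_short"
  } else {
    "lag_long"
  }
}

#' @export
print.correlogram <- function(x, ...) {
  lab <- if (all(is.na(x$pair))) "" else
    sprintf(" %s vs %s", x$pair[1], x$pair[2])
  cat(sprintf("%s-correlogram%s: +/-%g ms analysis, +/-%g ms noise window\n",
              if (x$kind == "auto") "Auto" else "Cross", lab,
              x$analysis_lag_ms, x$noise_lag_ms))
  cat(sprintf("  n = %d x %d spikes over %d bins of %g ms\n",
              x$n_a, x$n_b, x$n_bins, x$bin_ms))
  if (!is.na(x$peak_value))
    cat(sprintf("  peak %.3f at %+g ms; baseline %.3f, noise SD %.4f -> %s%s\n",
                x$peak_value, x$peak_lag_ms, x$baseline, x$noise_sd,
                if (isTRUE(x$significant)) "significant" else "not significant",
                if (!is.na(x$shape)) paste0(" (", x$shape, ")") else ""))
  invisible(x)
}

#' @export
plot.correlogram <- function(x, ...) {
  graphics::plot(x$lags_ms, x$values, type = "h", lwd = 2,
                 xlab = "lag (ms)", ylab = "normalized coincidences",
                 main = sprintf("%s-correlogram",
                                if (x$kind == "auto") "Auto" else "Cross"),
                 ...)
  graphics::abline(h = x$baseline, col = "grey40", lty = 2)
  if (is.finite(x$noise_sd) && x$noise_sd > 0)
    graphics::abline(h = x$baseline + x$significance_sd * x$noise_sd,
                     col = "red", lty = 3)
  graphics::abline(v = c(-x$analysis_lag_ms, x$analysis_lag_ms),
                   col = "grey70", lty = 3)
  invisible(x)
}

#' Build the per-condition linkage matrix
#'
#' Evaluates the cross-correlogram of every unordered element pair over a
#' common analysis window and assembles the symmetric linkage matrix:
#' the normalized peak value where the pair is significant, zero
#' otherwise.  Pairs with too few spikes or a flat (non-evaluable)
#' correlogram are excluded -- recorded separately, not counted as zero.
#'
#' @param trains a \code{"spike_train_set"} or named list of spike-time
#'   vectors (seconds).
#' @param condition condition label stored on the matrix (defaults to the
#'   train set's condition).
#' @param config an [analysis_config()] supplying bin width, lag windows,
#'   significance threshold and \code{min_spikes}.
#' @param t_start,t_end analysis window, seconds (e.g. the last 10 min of
#'   the condition); defaults to the full recording.
#' @return An object of class \code{"linkage_matrix"}: \code{values}
#'   (symmetric, zero diagonal), \code{peak_lags} (ms, of the
#'   source-to-target correlogram), \code{significant} (logical matrix),
#'   \code{pairs} (per-pair summary data frame), \code{excluded},
#'   \code{n_evaluated}, \code{condition}.
#' @export
build_linkage_matrix <- function(trains, condition = NULL,
                                 config = analysis_config(),
                                 t_start = 0, t_end = NULL) {
  validate_config(config)
  if (is.null(condition) && inherits(trains, "spike_train_set"))
    condition <- trains$condition
  bsm <- binarize(trains, bin_ms = config$bin_ms,
                  t_start = t_start, t_end = t_end)
  ids <- names(bsm$bins)
  n <- length(ids)
  if (n < 2) stop("need at least two elements", call. = FALSE)

  values <- matrix(0, n, n, dimnames = list(ids, ids))
  peak_lags <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  signif <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  pair_rows <- vector("list", n * (n - 1L) / 2L)
  excluded <- character(0)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      cg <- tryCatch(
        cross_correlogram_binned(bsm$bins[[i]], bsm$bins[[j]], bsm$n_bins,
                                 bin_ms = config$bin_ms,
                                 analysis_lag_ms = config$analysis_lag_ms,
                                 noise_lag_ms = config$noise_lag_ms,
                                 significance_sd = config$significance_sd,
                                 min_spikes = config$min_spikes,
                                 pair = c(ids[i], ids[j])),
        rhythmnet_too_few_spikes = function(e) NULL)
      if (is.null(cg) || !cg$evaluable) {
        excluded <- c(excluded, paste(ids[i], ids[j], sep = ":"))
        pair_rows[[k]] <- data.frame(
          a = ids[i], b = ids[j], peak_value = NA_real_,
          peak_lag_ms = NA_real_, significant = NA, excluded = TRUE,
          shape = NA_character_, stringsAsFactors = FALSE)
        next
      }
      if (cg$significant) {
        values[i, j] <- values[j, i] <- cg$peak_value
        signif[i, j] <- signif[j, i] <- TRUE
      }
      peak_lags[i, j] <- cg$peak_lag_ms
      peak_lags[j, i] <- -cg$peak_lag_ms
      pair_rows[[k]] <- data.frame(
        a = ids[i], b = ids[j], peak_value = cg$peak_value,
        peak_lag_ms = cg$peak_lag_ms, significant = cg$significant,
        excluded = FALSE, shape = cg$shape, stringsAsFactors = FALSE)
    }
  }
  out <- list(values = values, peak_lags = peak_lags, significant = signif,
              pairs = do.call(rbind, pair_rows), excluded = excluded,
              n_evaluated = k - length(excluded), n_pairs = k,
              condition = condition,
              config = config)
  class(out) <- "linkage_matrix"
  out
}

#' @export
print.linkage_matrix <- function(x, ...) {
  cat(sprintf("Linkage matrix (%s): %d elements, %d/%d pairs evaluated\n",
              x$condition %||% "unlabelled", nrow(x$values),
              x$n_evaluated, x$n_pairs))
  cat(sprintf("  significant links: %d\n", count_links(x)))
  if (length(x$excluded) > 0)
    cat(sprintf("  excluded pairs: %d\n", length(x$excluded)))
  invisible(x)
}

#' Difference of two linkage matrices (delta-correlation)
#'
#' Element-wise \code{condition - reference}, the change-in-correlation
#' measure used to quantify network reconfiguration across conditions.
#' Requires identical element ordering (guaranteed when sorting was
#' performed on condition-merged data).
#'
#' @param cond,ref \code{"linkage_matrix"} objects over the same elements.
#' @return An object of class \code{"delta_matrix"}: \code{values},
#'   \code{considered} (logical matrix: pairs significant in at least one
#'   of the two conditions), \code{condition}, \code{reference}.
#' @export
delta_matrix <- function(cond, ref) {
  stopifnot(inherits(cond, "linkage_matrix"), inherits(ref, "linkage_matrix"))
  if (!identical(rownames(cond$values), rownames(ref$values)))
    stop("element sets/order differ between matrices", call. = FALSE)
  out <- list(values = cond$values - ref$values,
              considered = cond$significant | ref$significant,
              condition = cond$condition,
              reference = ref$condition)
  class(out) <- "delta_matrix"
  out
}

#' @export
print.delta_matrix <- function(x, ...) {
  ut <- upper.tri(x$values)
  cons <- x$considered & ut
  cat(sprintf("Delta-correlation matrix: %s - %s, %d elements\n",
              x$condition %||% "?", x$reference %||% "?", nrow(x$values)))
  if (any(cons))
    cat(sprintf("  considered pairs: %d, mean delta %.3f\n",
                sum(cons), mean(x$values[cons])))
  invisible(x)
}

#' Randomly thin a spike train
#'
#' Keeps each spike independently with probability \code{p} -- the
#' canonical check that the correlogram normalization is invariant to
#' proportional firing-rate changes.
#'
#' @param times_s spike times, seconds.
#' @param p keep probability in (0, 1].
#' @param seed integer seed.
#' @return Thinned spike-time vector.
#' @export
thin_train <- function(times_s, p, seed = 1L) {
  stopifnot(p > 0, p <= 1)
  with_local_seed(seed, times_s[stats::runif(length(times_s)) < p])
}
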