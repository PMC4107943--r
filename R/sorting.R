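#' Merge per-condition detections onto one timeline
#'
#' Concatenates detection results from several conditions (same channel)
#' into a single timeline so that sorting is performed once and element
#' identity persists across conditions.  Segment boundaries are recorded
#' so original times are recoverable with [split_conditions()].
#'
#' @param det_per_condition named list of \code{"detection_result"}
#'   objects, one per condition, in timeline order.
#' @param segment_durations_s optional numeric vector of segment lengths;
#'   defaults to each segment's last event time rounded up to a second.
#' @return A merged \code{"detection_result"} with a \code{segments} data
#'   frame (\code{condition}, \code{start_s}, \code{end_s},
#'   \code{offset_s}).
#' @export
concat_conditions <- function(det_per_condition, segment_durations_s = NULL) {
  stopifnot(is.list(det_per_condition), length(det_per_condition) > 0,
            !is.null(names(det_per_condition)))
  chans <- vapply(det_per_condition, function(d) d$channel, numeric(1))
  if (length(unique(chans)) != 1L)
    stop("all conditions must come from the same channel", call. = FALSE)
  if (is.null(segment_durations_s)) {
    segment_durations_s <- vapply(det_per_condition, function(d)
      ceiling(max(c(0, d$crossing_times))), numeric(1))
  }
  if (length(segment_durations_s) != length(det_per_condition))
    stop("one duration per condition required", call. = FALSE)
  offsets <- cumsum(c(0, utils::head(segment_durations_s, -1)))
  times <- unlist(mapply(function(d, off) d$crossing_times + off,
                         det_per_condition, offsets, SIMPLIFY = FALSE),
                  use.names = FALSE)
  if (is.unsorted(times))
    stop("segments overlap after concatenation", call. = FALSE)
  waveforms <- do.call(rbind, lapply(det_per_condition, function(d) d$waveforms))
  merged <- det_per_condition[[1]]
  merged$crossing_times <- times
  merged$waveforms <- waveforms
  merged$n_edge_dropped <- sum(vapply(det_per_condition,
                                      function(d) d$n_edge_dropped, numeric(1)))
  merged$segments <- data.frame(
    condition = names(det_per_condition),
    start_s = offsets,
    end_s = offsets + segment_durations_s,
    offset_s = offsets,
    stringsAsFactors = FALSE
  )
  merged
}

#' Split a merged detection back into per-condition results
#'
#' Inverse of [concat_conditions()]: events are reassigned to their
#' condition segments and shifted back to segment-local time.
#'
#' @param merged a merged \code{"detection_result"} carrying
#'   \code{segments}.
#' @return Named list of \code{"detection_result"} objects.
#' @export
split_conditions <- function(merged) {
  seg <- merged$segments
  if (is.null(seg)) stop("no segment map present", call. = FALSE)
  out <- vector("list", nrow(seg))
  names(out) <- seg$condition
  for (i in seq_len(nrow(seg))) {
    sel <- merged$crossing_times >= seg$start_s[i] &
      merged$crossing_times < seg$end_s[i]
    d <- merged
    d$segments <- NULL
    d$crossing_times <- merged$crossing_times[sel] - seg$offset_s[i]
    d$waveforms <- merged$waveforms[sel, , drop = FALSE]
    out[[i]] <- d
  }
  out
}

#' Principal-component features of spike waveforms
#'
#' Projects detected waveform snippets onto the eigenvectors of their
#' covariance (PCA), the standard low-dimensional space in which spike
#' clusters are separated.  Degenerate input (all waveforms identical)
#' yields all-zero scores.
#'
#' @param waveforms events x samples matrix.
#' @param n_components number of components to retain (at least 2).
#' @return An object of class \code{"feature_space"}: \code{scores}
#'   (events x components), \code{rotation}, \code{explained_variance}
#'   (fractions, non-increasing), \code{degenerate} flag.
#' @export
pca_features <- function(waveforms, n_components = 3) {
  if (!is.matrix(waveforms) || nrow(waveforms) < 2)
    stop("need at least two waveforms", call. = FALSE)
  n_components <- min(n_components, ncol(waveforms), nrow(waveforms) - 1L)
  if (n_components < 1)
    stop("fewer events than components requested", call. = FALSE)
  total_var <- sum(apply(waveforms, 2, stats::var))
  if (total_var == 0) {
    out <- list(scores = matrix(0, nrow(waveforms), n_components),
                rotation = matrix(0, ncol(waveforms), n_components),
                explained_variance = rep(0, n_components),
                degenerate = TRUE)
    class(out) <- "feature_space"
    return(out)
  }
  p <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  out <- list(scores = p$x[, seq_len(k), drop = FALSE],
              rotation = p$rotation[, seq_len(k), drop = FALSE],
              explained_variance = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)],
              degenerate = FALSE)
  class(out) <- "feature_space"
  out
}

#' Gaussian-mixture (EM) clustering of waveform features
#'
#' Fits Gaussian mixtures by expectation-maximization over a range of
#' cluster counts and selects the model by BIC.  With two or more
#' clusters, a central low-amplitude cluster (centroid close to the
#' feature-space origin) is flagged as the noise class.
#'
#' @param features a [pca_features()] result.
#' @param k_range candidate numbers of clusters.
#' @param seed integer seed (mixture initialization subsamples at large n).
#' @param noise_radius_frac a minimal-norm centroid closer to the origin
#'   than this fraction of the largest centroid norm marks its cluster as
#'   noise.
#' @return An object of class \code{"em_clustering"}: \code{labels},
#'   \code{k}, \code{means}, \code{noise_cluster} (index or \code{NA}),
#'   \code{bic}, \code{converged}.
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_em <- function(features, k_range = 1:6, seed = 1L,
                       noise_radius_frac = 0.35) {
  stopifnot(inherits(features, "feature_space"))
  x <- features$scores
  n <- nrow(x)
  if (n < max(2, min(k_range)))
    stop("too few events to cluster", call. = FALSE)
  if (features$degenerate || all(apply(x, 2, stats::var) == 0)) {
    out <- list(labels = rep(1L, n), k = 1L,
                means = matrix(colMeans(x), ncol = 1),
                noise_cluster = NA_integer_, bic = NA_real_, converged = TRUE)
    class(out) <- "em_clustering"
    return(out)
  }
  fit <- with_local_seed(seed, {
    suppressWarnings(mclust::Mclust(x, G = k_range, verbose = FALSE))
  })
  if (is.null(fit)) {
    out <- list(labels = rep(1L, n), k = 1L,
                means = matrix(colMeans(x), ncol = 1),
                noise_cluster = NA_integer_, bic = NA_real_, converged = FALSE)
    class(out) <- "em_clustering"
    return(out)
  }
  labels <- as.integer(fit$classification)
  k <- fit$G
  means <- fit$parameters$mean
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  noise_cluster <- NA_integer_
  if (k >= 2) {
    norms <- sqrt(colSums(means^2))
    cand <- which.min(norms)
    if (norms[cand] < noise_radius_frac * max(norms))
      noise_cluster <- as.integer(cand)
  }
  out <- list(labels = labels, k = as.integer(k), means = means,
              noise_cluster = noise_cluster, bic = fit$BIC,
              converged = TRUE)
  class(out) <- "em_clustering"
  out
}

#' Enforce the 2-ms refractory period on a spike train
#'
#' Greedy left-to-right rule: a spike is kept iff it falls at least
#' \code{refractory_ms} after the last kept spike.  The discarded
#' fraction is the refractory-violation fraction used for sorting
#' quality control (accepted units must stay below 0.5%).
#'
#' @param times_s sorted spike times, seconds.
#' @param refractory_ms refractory period, ms.
#' @return List with \code{times_s} (kept times),
#'   \code{violation_fraction} (discarded / original; 0 for empty input)
#'   and \code{n_discarded}.
#' @export
#' @examples
#' enforce_refractory(c(0, 0.001, 0.005))  # keeps 0 and 0.005
enforce_refractory <- function(times_s, refractory_ms = 2) {
  if (length(times_s) == 0)
    return(list(times_s = numeric(0), violation_fraction = 0, n_discarded = 0L))
  if (is.unsorted(times_s)) stop("times must be sorted", call. = FALSE)
  refr <- refractory_ms / 1000
  keep <- logical(length(times_s))
  last <- -Inf
  for (i in seq_along(times_s)) {
    if (times_s[i] - last >= refr) { keep[i] <- TRUE; last <- times_s[i] }
  }
  list(times_s = times_s[keep],
       violation_fraction = sum(!keep) / length(times_s),
       n_discarded = sum(!keep))
}

#' Classify clusters as single units or multi-unit activity
#'
#' A cluster counts as a single unit when it is well isolated (minimum
#' Mahalanobis distance to every other non-noise cluster centroid of at
#' least \code{isolation_min}) and its refractory-violation fraction is
#' below \code{max_violation}.  Everything else is multi-unit activity.
#'
#' @param clustering an [cluster_em()] result.
#' @param features the [pca_features()] the clustering was fit on.
#' @param times_s event times (seconds) aligned with the feature rows.
#' @param isolation_min minimum Mahalanobis isolation distance.
#' @param max_violation maximum admissible refractory-violation fraction.
#' @param refractory_ms refractory period, ms.
#' @return Data frame per non-noise cluster: \code{cluster}, \code{kind}
#'   (\code{"unit"}/\code{"multiunit"}), \code{isolation},
#'   \code{violation_fraction}, \code{n_events}.
#' @export
classify_element_kind <- function(clustering, features, times_s,
                                  isolation_min = 3, max_violation = 0.005,
                                  refractory_ms = 2) {
  stopifnot(inherits(clustering, "em_clustering"),
            inherits(features, "feature_space"),
            length(times_s) == nrow(features$scores))
  labs <- clustering$labels
  clusters <- setdiff(sort(unique(labs)), clustering$noise_cluster)
  iso <- function(c1) {
    others <- setdiff(clusters, c1)
    if (length(others) == 0) return(Inf)
    x1 <- features$scores[labs == c1, , drop = FALSE]
    cv <- stats::cov(x1)
    # guard singular covariance of tight clusters
    cv <- cv + diag(1e-9 * max(1, sum(diag(cv))), ncol(cv))
    mu1 <- colMeans(x1)
    min(vapply(others, function(c2) {
      mu2 <- colMeans(features$scores[labs == c2, , drop = FALSE])
      sqrt(stats::mahalanobis(mu2, mu1, cv))
    }, numeric(1)))
  }
  rows <- lapply(clusters, function(cl) {
    tt <- sort(times_s[labs == cl])
    vf <- enforce_refractory(tt, refractory_ms)$violation_fraction
    d <- iso(cl)
    data.frame(cluster = cl,
               kind = if (d >= isolation_min && vf < max_violation)
                 "unit" else "multiunit",
               isolation = d,
               violation_fraction = vf,
               n_events = length(tt),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sort one channel's detected events into elements
#'
#' Convenience wrapper chaining [pca_features()], [cluster_em()],
#' [classify_element_kind()] and refractory enforcement.  Clusters that
#' qualify as units become unit elements; all remaining non-noise events
#' (plus clusters failing isolation) are pooled into one multi-unit
#' element for the channel, re-thresholded at the multi-unit criterion
#' in the sense that only events at least \code{mua_threshold_sd} robust
#' SDs deep are retained.
#'
#' @param det a \code{"detection_result"} (typically condition-merged).
#' @param seed integer seed for clustering.
#' @param n_components,k_range passed to [pca_features()]/[cluster_em()].
#' @param isolation_min,max_violation passed to [classify_element_kind()].
#' @param mua_threshold_sd detection depth (robust SDs) required of events
#'   pooled into the multi-unit element.
#' @param refractory_ms refractory period, ms.
#' @return An object of class \code{"sorted_channel"}: \code{trains}
#'   (named list of spike-time vectors), \code{kinds}, \code{qc} (the
#'   [classify_element_kind()] table), \code{clustering},
#'   \code{features}, \code{segments} (if present on \code{det}).
#' @export
sort_channel <- function(det, seed = 1L, n_components = 3, k_range = 1:6,
                         isolation_min = 3, max_violation = 0.005,
                         mua_threshold_sd = 4.0, refractory_ms = 2) {
  stopifnot(inherits(det, "detection_result"))
  feats <- pca_features(det$waveforms, n_components = n_components)
  clus <- cluster_em(feats, k_range = k_range, seed = seed)
  qc <- classify_element_kind(clus, feats, det$crossing_times,
                              isolation_min = isolation_min,
                              max_violation = max_violation,
                              refractory_ms = refractory_ms)
  trains <- list()
  kinds <- character(0)
  mua_pool <- numeric(0)
  # depth of each event relative to the unit threshold, in robust SDs
  depth_sd <- -apply(det$waveforms, 1, min) /
    (abs(det$threshold) / det$threshold_sd)
  for (i in seq_len(nrow(qc))) {
    cl <- qc$cluster[i]
    tt <- sort(det$crossing_times[clus$labels == cl])
    if (qc$kind[i] == "unit") {
      id <- sprintf("ch%s_u%d", as.character(det$channel), cl)
      trains[[id]] <- enforce_refractory(tt, refractory_ms)$times_s
      kinds[id] <- "unit"
    } else {
      mua_pool <- c(mua_pool, tt)
    }
  }
  if (length(mua_pool) > 0) {
    sel <- depth_sd[clus$labels %in%
                      qc$cluster[qc$kind == "multiunit"]] >= mua_threshold_sd
    mua_pool <- sort(mua_pool[sel])
    if (length(mua_pool) > 0) {
      id <- sprintf("ch%s_mua", as.character(det$channel))
      trains[[id]] <- mua_pool
      kinds[id] <- "multiunit"
    }
  }
  out <- list(trains = trains, kinds = kinds, qc = qc,
              clustering = clus, features = feats,
              segments = det$segments)
  class(out) <- "sorted_channel"
  out
}

#' @export
print.sorted_channel <- function(x, ...) {
  cat(sprintf("Sorted channel: %d element(s) (%d unit, %d multiunit)\n",
              length(x$trains), sum(x$kinds == "unit"),
              sum(x$kinds == "multiunit")))
  for (id in names(x$trains))
    cat(sprintf("  %s [%s]: %d spikes\n", id, x$kinds[id],
                length(x$trains[[id]])))
  invisible(x)
}
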