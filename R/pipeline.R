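#' Write spike trains as tidy CSV with a JSON sidecar
#'
#' The CSV holds one row per spike (\code{element_id}, \code{kind},
#' \code{phase}, \code{time_s}, \code{condition}); the sidecar holds the
#' metadata needed to reconstruct the \code{"spike_train_set"} (duration,
#' burst windows, condition, seed), so the pair round-trips through
#' [read_spike_trains()].
#'
#' @param trains a \code{"spike_train_set"}.
#' @param path CSV output path; the sidecar replaces the extension with
#'   \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_spike_trains <- function(trains, path) {
  stopifnot(inherits(trains, "spike_train_set"))
  el <- trains$elements
  rows <- lapply(names(trains$times), function(id) {
    tt <- trains$times[[id]]
    i <- match(id, el$id)
    if (length(tt) == 0) return(NULL)
    data.frame(element_id = id, kind = el$kind[i], phase = el$phase[i],
               time_s = tt, condition = trains$condition %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(condition = trains$condition,
         duration_s = trains$duration_s,
         seed = trains$seed,
         elements = el,
         bursts = trains$bursts),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read spike trains written by [write_spike_trains()]
#'
#' @param path the CSV path (the JSON sidecar is looked up next to it).
#' @return A \code{"spike_train_set"}.
#' @export
read_spike_trains <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  el <- as.data.frame(meta$elements, stringsAsFactors = FALSE)
  times <- lapply(el$id, function(id)
    sort(df$time_s[df$element_id == id]))
  names(times) <- el$id
  out <- list(times = times,
              elements = el[, c("id", "kind", "phase")],
              bursts = as.data.frame(meta$bursts),
              duration_s = meta$duration_s,
              condition = meta$condition,
              seed = meta$seed)
  class(out) <- "spike_train_set"
  out
}

#' Write a linkage matrix as CSV plus JSON metadata
#'
#' @param matrix a \code{"linkage_matrix"}.
#' @param path CSV output path (element ids as header and first column);
#'   metadata goes to a \code{.json} sidecar.
#' @return \code{path}, invisibly.
#' @export
write_linkage_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "linkage_matrix"))
  utils::write.csv(as.data.frame(matrix$values), path, row.names = TRUE)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(condition = matrix$condition,
         n_evaluated = matrix$n_evaluated,
         n_pairs = matrix$n_pairs,
         excluded = matrix$excluded,
         config = unclass(matrix$config)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a linkage matrix written by [write_linkage_matrix()]
#'
#' @param path the CSV path.
#' @return A \code{"linkage_matrix"} (values and metadata; per-pair
#'   correlogram summaries are not round-tripped).
#' @export
read_linkage_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  values <- as.matrix(df)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  cfg <- do.call(analysis_config, meta$config[names(meta$config) %in%
                                                names(formals(analysis_config))])
  out <- list(values = values, peak_lags = NULL,
              significant = values != 0, pairs = NULL,
              excluded = meta$excluded %||% character(0),
              n_evaluated = meta$n_evaluated, n_pairs = meta$n_pairs,
              condition = meta$condition, config = cfg)
  class(out) <- "linkage_matrix"
  out
}

# Raw-signal route for one condition: synthesize each occupied channel,
# band-pass filter and detect at the unit threshold.
detect_all_channels <- function(trains, net, config, noise_sd, seed) {
  el <- net$elements
  grid <- net$config$grid
  chans <- sort(unique(el$electrode_row * grid[2] + el$electrode_col + 1L))
  dets <- list()
  for (ch in chans) {
    raw <- synthesize_raw_signal(trains, net, noise_sd = noise_sd,
                                 seed = seed + ch, channels = ch)
    filt <- bandpass(raw, config$band_hz[1], config$band_hz[2])
    dets[[as.character(ch)]] <- detect_spikes(
      filt, channel = 1, threshold_sd = config$detect_sd_unit)
    dets[[as.character(ch)]]$channel <- ch
  }
  dets
}

#' Run the full analysis pipeline
#'
#' Ties the stages together: generate a ground-truth network, simulate
#' spike trains per condition, (optionally) synthesize raw signal and
#' re-detect and re-sort spikes on condition-merged channels, build
#' per-condition linkage matrices over the analysis window, subtract the
#' reference (first) condition to obtain delta-correlation matrices, and
#' write spike trains, matrices, graphs and summary tables to
#' \code{out_dir} together with a run manifest.  The master seed fans
#' out deterministically into per-stage seeds, so identical
#' \code{(config, seed)} runs give identical outputs.
#'
#' @param gen_config a [generator_config()].
#' @param config an [analysis_config()].
#' @param conditions character vector of condition labels (the first is
#'   the reference); with a single condition the difference and
#'   comparison stages are skipped with a notice.
#' @param duration_s simulated duration per condition, seconds.
#' @param seed master integer seed.
#' @param out_dir output directory (created if needed); \code{NULL}
#'   keeps everything in memory.
#' @param detect_sort if \code{TRUE}, run the raw-signal route
#'   (synthesis, filtering, threshold detection, condition-merged PCA/EM
#'   sorting) and analyze the re-sorted trains; otherwise analyze the
#'   simulated trains directly.  The raw route is faithful but costs
#'   about three orders of magnitude more samples (25 kHz vs 1 kHz), so
#'   reserve it for short recordings.
#' @param noise_sd raw-signal noise SD (raw route only).
#' @return An object of class \code{"run_manifest"}: seeds, parameters,
#'   per-stage outputs (\code{trains}, \code{linkage}, \code{deltas},
#'   \code{rate_changes}, \code{mean_deltas}, \code{graphs}), link
#'   counts, exclusion logs and written file paths.
#' @export
run_pipeline <- function(gen_config = generator_config(),
                         config = analysis_config(),
                         conditions = c("control", "hypoxia"),
                         duration_s = 600, seed = 1L, out_dir = NULL,
                         detect_sort = FALSE, noise_sd = 0.08) {
  validate_config(config)
  stopifnot(length(conditions) >= 1)
  seeds <- list(network = derive_seed(seed, "network"))
  net <- generate_network(gen_config, seed = seeds$network)

  trains <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    s_prof <- derive_seed(seed, "trains") + 2L * i
    s_sim <- derive_seed(seed, "trains") + 2L * i + 1L
    seeds[[paste0("profile_", cond)]] <- s_prof
    seeds[[paste0("simulate_", cond)]] <- s_sim
    profile <- condition_profile(cond, net, seed = s_prof)
    trains[[cond]] <- simulate_spike_trains(net, profile, duration_s,
                                            seed = s_sim)
  }

  if (detect_sort) {
    seeds$sort <- derive_seed(seed, "sort")
    dets <- lapply(conditions, function(cond)
      detect_all_channels(trains[[cond]], net, config, noise_sd,
                          derive_seed(seed, "detect") +
                            match(cond, conditions)))
    names(dets) <- conditions
    chans <- names(dets[[1]])
    sorted_times <- stats::setNames(
      rep(list(stats::setNames(list(), character(0))), length(conditions)),
      conditions)
    kinds_all <- character(0)
    for (ch in chans) {
      merged <- concat_conditions(
        stats::setNames(lapply(conditions, function(cond) dets[[cond]][[ch]]),
                        conditions),
        segment_durations_s = rep(duration_s, length(conditions)))
      sc <- sort_channel(merged, seed = seeds$sort,
                         mua_threshold_sd = config$detect_sd_mua,
                         refractory_ms = config$refractory_ms)
      for (id in names(sc$trains)) {
        kinds_all[id] <- sc$kinds[[id]]
        for (i in seq_along(conditions)) {
          seg <- sc$segments[i, ]
          tt <- sc$trains[[id]]
          sorted_times[[conditions[i]]][[id]] <-
            tt[tt >= seg$start_s & tt < seg$end_s] - seg$offset_s
        }
      }
    }
    # re-sorted trains replace the simulated ones for analysis
    for (cond in conditions) {
      st <- trains[[cond]]
      st$times <- sorted_times[[cond]]
      st$elements <- data.frame(id = names(kinds_all),
                                kind = unname(kinds_all),
                                phase = NA_character_,
                                stringsAsFactors = FALSE)
      trains[[cond]] <- st
    }
  }

  win <- min(config$analysis_window_min * 60, duration_s)
  t_start <- duration_s - win
  linkage <- lapply(trains, function(st)
    build_linkage_matrix(st, config = config,
                         t_start = t_start, t_end = duration_s))

  reference <- conditions[1]
  deltas <- list()
  rate_changes <- list()
  mean_deltas <- list()
  if (length(conditions) >= 2) {
    kinds <- stats::setNames(trains[[reference]]$elements$kind,
                             trains[[reference]]$elements$id)
    for (cond in conditions[-1]) {
      deltas[[cond]] <- delta_matrix(linkage[[cond]], linkage[[reference]])
      rate_changes[[cond]] <- rate_change(trains[[cond]], trains[[reference]],
                                          t_start = t_start,
                                          t_end = duration_s)
      mean_deltas[[cond]] <- tryCatch(mean_delta(deltas[[cond]], kinds),
                                      error = function(e) NULL)
    }
  } else {
    message("single condition: difference and comparison stages skipped")
  }
  graphs <- lapply(linkage, build_graph)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cond in conditions) {
      p <- file.path(out_dir, sprintf("trains_%s.csv", cond))
      write_spike_trains(trains[[cond]], p)
      files[sprintf("trains_%s", cond)] <- p
      p <- file.path(out_dir, sprintf("linkage_%s.csv", cond))
      write_linkage_matrix(linkage[[cond]], p)
      files[sprintf("linkage_%s", cond)] <- p
      p <- file.path(out_dir, sprintf("network_%s.graphml", cond))
      export_graph(graphs[[cond]], p, "graphml")
      files[sprintf("graph_%s", cond)] <- p
    }
    for (cond in names(deltas)) {
      p <- file.path(out_dir, sprintf("delta_%s_vs_%s.csv", cond, reference))
      utils::write.csv(as.data.frame(deltas[[cond]]$values), p,
                       row.names = TRUE)
      files[sprintf("delta_%s", cond)] <- p
      p <- file.path(out_dir, sprintf("rate_change_%s.csv", cond))
      utils::write.csv(rate_changes[[cond]]$elements, p, row.names = FALSE)
      files[sprintf("rate_change_%s", cond)] <- p
    }
  }

  manifest <- list(
    master_seed = as.integer(seed),
    stage_seeds = seeds,
    conditions = conditions,
    reference = reference,
    duration_s = duration_s,
    detect_sort = detect_sort,
    config = unclass(config),
    generator = unclass(gen_config),
    n_links = vapply(linkage, count_links, numeric(1)),
    excluded_pairs = lapply(linkage, function(l) l$excluded),
    files = as.list(files),
    network = net,
    trains = trains,
    linkage = linkage,
    deltas = deltas,
    rate_changes = rate_changes,
    mean_deltas = mean_deltas,
    graphs = graphs
  )
  class(manifest) <- "run_manifest"
  if (!is.null(out_dir)) {
    slim <- manifest[c("master_seed", "stage_seeds", "conditions",
                       "reference", "duration_s", "detect_sort", "config",
                       "generator", "n_links", "excluded_pairs", "files")]
    jsonlite::write_json(slim, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d): conditions %s, %g s each\n",
              x$master_seed, paste(x$conditions, collapse = ", "),
              x$duration_s))
  cat(sprintf("  route: %s\n",
              if (x$detect_sort) "raw signal (detect + sort)"
              else "spike trains"))
  for (cond in x$conditions)
    cat(sprintf("  %-20s %3d links\n", cond, x$n_links[[cond]]))
  for (cond in names(x$mean_deltas)) {
    md <- x$mean_deltas[[cond]]
    if (!is.null(md)) {
      both <- md[md$group == "both", , drop = FALSE]
      all_mean <- stats::weighted.mean(md$mean_delta, md$n_pairs)
      cat(sprintf("  delta(%s - %s): mean %.3f over %d pairs\n",
                  cond, x$reference, all_mean, sum(md$n_pairs)))
    }
  }
  invisible(x)
}
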