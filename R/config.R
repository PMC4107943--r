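#' Analysis configuration
#'
#' Bundles every numeric constant of the analysis chain into one validated
#' object.  The defaults are the values used throughout the package:
#' a 250--7000 Hz pass band, detection thresholds of 2.6 SD (single units)
#' and 4.0 SD (multi-unit activity), a 2-ms refractory period, 1-ms
#' binarization, a +/-5 ms correlation lag window with noise estimated on
#' +/-50 ms flanks, a 5-SD significance rule, a 45-ms peak-to-peak window
#' for the population burst trace, 10-min analysis windows and alpha = 0.05.
#'
#' @param band_hz numeric length-2, band-pass corner frequencies in Hz.
#' @param detect_sd_unit detection threshold for unit channels, in robust
#'   SDs of the filtered signal.
#' @param detect_sd_mua detection threshold for multi-unit channels.
#' @param refractory_ms minimum admissible inter-spike interval, ms.
#' @param bin_ms binarization bin width, ms.
#' @param analysis_lag_ms half-width of the correlogram analysis window, ms.
#' @param noise_lag_ms half-width of the window used to estimate the
#'   correlation noise; must exceed \code{analysis_lag_ms}.
#' @param significance_sd significance threshold in noise SDs.
#' @param p2p_window_ms window for the peak-to-peak burst trace, ms.
#' @param analysis_window_min length of the per-condition analysis window,
#'   minutes.
#' @param alpha significance level for condition comparisons.
#' @param min_spikes minimum spikes per element for a pair to be evaluated.
#' @param seed default random seed recorded in the configuration.
#'
#' @return An object of class \code{"analysis_config"} (a named list).
#' @seealso [load_config()], [save_config()]
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$significance_sd
analysis_config <- function(band_hz = c(250, 7000),
                            detect_sd_unit = 2.6,
                            detect_sd_mua = 4.0,
                            refractory_ms = 2,
                            bin_ms = 1,
                            analysis_lag_ms = 5,
                            noise_lag_ms = 50,
                            significance_sd = 5,
                            p2p_window_ms = 45,
                            analysis_window_min = 10,
                            alpha = 0.05,
                            min_spikes = 50,
                            seed = 1L) {
  cfg <- list(
    band_hz = as.numeric(band_hz),
    detect_sd_unit = as.numeric(detect_sd_unit),
    detect_sd_mua = as.numeric(detect_sd_mua),
    refractory_ms = as.numeric(refractory_ms),
    bin_ms = as.numeric(bin_ms),
    analysis_lag_ms = as.numeric(analysis_lag_ms),
    noise_lag_ms = as.numeric(noise_lag_ms),
    significance_sd = as.numeric(significance_sd),
    p2p_window_ms = as.numeric(p2p_window_ms),
    analysis_window_min = as.numeric(analysis_window_min),
    alpha = as.numeric(alpha),
    min_spikes = as.numeric(min_spikes),
    seed = as.integer(seed)
  )
  class(cfg) <- "analysis_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  fail <- function(field, msg) {
    stop(sprintf("analysis_config$%s: %s", field, msg), call. = FALSE)
  }
  if (length(cfg$band_hz) != 2L || any(!is.finite(cfg$band_hz)))
    fail("band_hz", "must be two finite numbers")
  if (cfg$band_hz[1] <= 0 || cfg$band_hz[1] >= cfg$band_hz[2])
    fail("band_hz", "must satisfy 0 < low < high")
  scalar_pos <- c("detect_sd_unit", "detect_sd_mua", "refractory_ms",
                  "bin_ms", "analysis_lag_ms", "noise_lag_ms",
                  "significance_sd", "p2p_window_ms", "analysis_window_min",
                  "min_spikes")
  for (f in scalar_pos) {
    v <- cfg[[f]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      fail(f, "must be a single positive finite number")
  }
  if (cfg$analysis_lag_ms >= cfg$noise_lag_ms)
    fail("noise_lag_ms", "must be strictly greater than analysis_lag_ms")
  if (length(cfg$alpha) != 1L || cfg$alpha <= 0 || cfg$alpha >= 1)
    fail("alpha", "must lie in (0, 1)")
  invisible(cfg)
}

#' Load an analysis configuration from JSON
#'
#' Fields missing from the file take the package defaults; unknown fields
#' and out-of-range values are rejected with a field-level message.
#'
#' @param path path to a JSON file (an empty object \code{{}} yields the
#'   full default configuration).
#' @return An \code{"analysis_config"} object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a JSON object", call. = FALSE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_config, raw)
}

#' Save an analysis configuration as JSON
#'
#' @param cfg an \code{"analysis_config"} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  band-pass:        %g-%g Hz\n", x$band_hz[1], x$band_hz[2]))
  cat(sprintf("  detection:        %.1f SD (unit), %.1f SD (MUA)\n",
              x$detect_sd_unit, x$detect_sd_mua))
  cat(sprintf("  refractory:       %g ms\n", x$refractory_ms))
  cat(sprintf("  correlogram:      %g-ms bins, lag +/-%g ms, noise +/-%g ms\n",
              x$bin_ms, x$analysis_lag_ms, x$noise_lag_ms))
  cat(sprintf("  significance:     peak - baseline > %g noise SD\n",
              x$significance_sd))
  cat(sprintf("  burst trace:      %g-ms peak-to-peak windows\n",
              x$p2p_window_ms))
  cat(sprintf("  analysis window:  %g min per condition, alpha = %g\n",
              x$analysis_window_min, x$alpha))
  invisible(x)
}

# Run code under a local RNG state; the caller's state is untouched.
# All stochastic operations in the package funnel through this.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic fan-out of one master seed into per-stage seeds (< 2^31).
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master))
  idx <- match(stage, c("network", "trains", "signal", "detect", "sort",
                        "connect", "report"), nomatch = 0L)
  as.integer((abs(as.numeric(master)) * 48271 + idx * 2246822519) %% 2147483647)
}

#' One-sided Gaussian confidence level of a k-SD peak rule
#'
#' For a correlogram peak tested against \code{k} standard deviations of
#' Gaussian correlation noise, returns the one-sided confidence level
#' \eqn{\Phi(k)} in percent.  At the default \code{k = 5} this exceeds
#' 99.9%, the level quoted for the significance rule.
#'
#' @param k_sd threshold in noise standard deviations.
#' @return Confidence level in percent.
#' @export
#' @examples
#' significance_confidence(5)   # > 99.9
significance_confidence <- function(k_sd = 5) {
  stopifnot(is.finite(k_sd), k_sd > 0)
  100 * stats::pnorm(k_sd)
}
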