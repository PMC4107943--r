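#' Generator configuration for synthetic rhythmic-network recordings
#'
#' Describes the population to be simulated: a grid of electrodes carrying
#' unitary and multi-unitary elements, a slow population rhythm
#' (fictive-eupnea-like bursts), and a set of planted pairwise couplings.
#' Defaults emulate a single slice on a 6 x 10 array: a few tens of
#' elements, ~87% of them inspiratory, a ~5-s rhythm with ~0.5-s bursts,
#' and couplings with lags inside the +/-5 ms detection window.
#'
#' @param n_units number of single-unit elements.
#' @param n_multiunits number of multi-unit elements (each the
#'   superposition of 2--4 latent neurons).
#' @param inspiratory_fraction probability that an element is inspiratory.
#' @param rhythm_period_s mean population burst period, seconds.
#' @param period_jitter_s SD of the Gaussian cycle-to-cycle period jitter.
#' @param burst_duration_s population burst duration, seconds.
#' @param n_couplings number of planted strong couplings (detectable
#'   functional links).
#' @param n_weak_couplings number of planted weak ("latent") couplings:
#'   connections below the significance floor in control that can be
#'   recruited into detectability when a condition potentiates coupling,
#'   as silent or weak synapses are.
#' @param n_driver_pool optional size of a source ("driver") pool
#'   couplings are drawn from; by default sources are any element with
#'   an appreciable firing rate.
#' @param strength_range range of per-spike copy probabilities for planted
#'   couplings; \code{NULL} (the default) instead calibrates each
#'   coupling's probability to a detection margin drawn from
#'   \code{margin_range} (strong) or \code{weak_margin_range} (weak).
#' @param margin_range range of target detection margins for strong
#'   couplings (correlogram peak excess over the flank-noise SD, in SDs,
#'   at a 600-s window) used when \code{strength_range} is \code{NULL}.
#'   The default keeps every strong link comfortably above the 5-SD
#'   significance threshold -- and still above it when a condition halves
#'   coupling strength.
#' @param weak_margin_range target detection margins for weak couplings;
#'   the default keeps them below the significance threshold in control.
#' @param lag_range_ms range of coupling lags, ms (within the +/-5 ms
#'   analysis window).
#' @param jitter_ms SD of the Gaussian jitter added to each copied spike,
#'   ms; a length-2 vector draws one value per coupling uniformly from
#'   that range (synaptic jitter varies across connections).
#' @param baseline_rate_range_hz tonic (outside-burst) rate range for
#'   inspiratory elements, Hz.
#' @param intraburst_rate_meanlog,intraburst_rate_sdlog log-normal
#'   parameters of the within-burst rate of inspiratory elements, Hz.
#'   The defaults put the reciprocal of the median inter-spike interval
#'   near 5 Hz, the scale observed for inspiratory elements in control.
#' @param expiratory_rate_meanlog,expiratory_rate_sdlog log-normal
#'   parameters of the outside-burst rate of expiratory elements, Hz.
#' @param expiratory_suppression multiplicative rate drop of expiratory
#'   elements inside bursts.
#' @param grid electrode grid as \code{c(rows, cols)}.
#' @param pitch_um inter-electrode spacing, micrometres.
#' @param sampling_rate_hz digitization rate for raw-signal synthesis.
#'
#' @return An object of class \code{"generator_config"}.
#' @export
generator_config <- function(n_units = 20,
                             n_multiunits = 10,
                             inspiratory_fraction = 0.87,
                             rhythm_period_s = 5,
                             period_jitter_s = 0.3,
                             burst_duration_s = 0.5,
                             n_couplings = 10,
                             n_weak_couplings = 6,
                             n_driver_pool = NULL,
                             strength_range = NULL,
                             margin_range = c(10, 14),
                             weak_margin_range = c(0.2, 0.5),
                             lag_range_ms = c(0.5, 5),
                             jitter_ms = 0.3,
                             baseline_rate_range_hz = c(0.1, 1),
                             intraburst_rate_meanlog = log(3.6),
                             intraburst_rate_sdlog = 0.8,
                             expiratory_rate_meanlog = log(2),
                             expiratory_rate_sdlog = 0.5,
                             expiratory_suppression = 0.2,
                             grid = c(6, 10),
                             pitch_um = 100,
                             sampling_rate_hz = 25000) {
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  if (cfg$n_units + cfg$n_multiunits <= 0)
    stop("at least one element is required", call. = FALSE)
  if (cfg$n_units < 0 || cfg$n_multiunits < 0)
    stop("element counts must be non-negative", call. = FALSE)
  if (cfg$inspiratory_fraction < 0 || cfg$inspiratory_fraction > 1)
    stop("inspiratory_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$rhythm_period_s <= cfg$burst_duration_s || cfg$burst_duration_s <= 0)
    stop("need rhythm_period_s > burst_duration_s > 0", call. = FALSE)
  if (!is.null(cfg$strength_range) &&
      (any(cfg$strength_range < 0) || any(cfg$strength_range > 1)))
    stop("strength_range must lie in [0, 1]", call. = FALSE)
  if (is.null(cfg$strength_range) && any(cfg$margin_range <= 0))
    stop("margin_range must be positive", call. = FALSE)
  if (any(cfg$lag_range_ms < 0) || any(cfg$lag_range_ms > 5))
    stop("lag_range_ms must lie in [0, 5]", call. = FALSE)
  if (2 * cfg$n_couplings + cfg$n_weak_couplings >
        cfg$n_units + cfg$n_multiunits)
    stop("population too small: strong couplings are disjoint and all
  couplings are target-unique", call. = FALSE)
  cfg
}

#' Generate a ground-truth network
#'
#' Draws a population of unitary and multi-unitary elements on the
#' electrode grid, assigns inspiratory/expiratory phase and firing-rate
#' parameters, and plants pairwise couplings (directed spike-copy links
#' with fixed lag and jitter).  Identical \code{(config, seed)} pairs give
#' identical networks.
#'
#' @param config a [generator_config()].
#' @param seed integer random seed.
#' @return An object of class \code{"gt_network"} with components
#'   \code{elements} (data frame: id, kind, phase, rates, electrode,
#'   n_latent), \code{couplings} (data frame: source, target, lag_ms,
#'   strength, jitter_ms), the rhythm parameters, and the seed.
#' @export
#' @examples
#' net <- generate_network(generator_config(n_units = 6, n_multiunits = 2,
#'                                          n_couplings = 3,
#'                                          n_weak_couplings = 0), seed = 1)
#' net
generate_network <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  pick <- function(x, k) x[sample.int(length(x), k)]   # scalar-safe sample
  n <- config$n_units + config$n_multiunits
  with_local_seed(seed, {
    kind <- c(rep("unit", config$n_units), rep("multiunit", config$n_multiunits))
    phase <- ifelse(stats::runif(n) < config$inspiratory_fraction,
                    "inspiratory", "expiratory")
    # multi-unit activity is inspiratory in this preparation
    phase[kind == "multiunit"] <- "inspiratory"
    n_latent <- ifelse(kind == "unit", 1L, sample(2:4, n, replace = TRUE))

    baseline <- numeric(n)
    intraburst <- numeric(n)
    insp <- phase == "inspiratory"
    baseline[insp] <- stats::runif(sum(insp),
                                   config$baseline_rate_range_hz[1],
                                   config$baseline_rate_range_hz[2])
    intraburst[insp] <- pmin(40, stats::rlnorm(sum(insp),
                                               config$intraburst_rate_meanlog,
                                               config$intraburst_rate_sdlog))
    intraburst[insp] <- pmax(intraburst[insp], baseline[insp])
    # an inspiratory element is burst-modulated by construction: its
    # tonic rate stays well below its intraburst rate
    baseline[insp] <- pmin(baseline[insp], intraburst[insp] / 3)
    if (any(!insp)) {
      baseline[!insp] <- stats::rlnorm(sum(!insp),
                                       config$expiratory_rate_meanlog,
                                       config$expiratory_rate_sdlog)
      intraburst[!insp] <- baseline[!insp] * config$expiratory_suppression
    }

    n_sites <- prod(config$grid)
    sites <- if (n <= n_sites) sample.int(n_sites, n)
             else sample.int(n_sites, n, replace = TRUE)
    elements <- data.frame(
      id = sprintf("e%02d", seq_len(n)),
      kind = kind,
      phase = phase,
      baseline_rate_hz = baseline,
      intraburst_rate_hz = intraburst,
      electrode_row = (sites - 1L) %/% config$grid[2],
      electrode_col = (sites - 1L) %% config$grid[2],
      n_latent = n_latent,
      stringsAsFactors = FALSE
    )

    n_cp <- config$n_couplings + config$n_weak_couplings
    couplings <- data.frame(source = character(), target = character(),
                            lag_ms = numeric(), strength = numeric(),
                            jitter_ms = numeric(), class = character(),
                            margin = numeric(), stringsAsFactors = FALSE)
    if (n_cp > 0) {
      bf <- config$burst_duration_s / config$rhythm_period_s
      rate <- (bf * intraburst + (1 - bf) * baseline) * n_latent
      # strong couplings follow a core-follower architecture: disjoint
      # links (unique sources AND unique targets, so no common-source
      # coincidences confound per-link ground truth) from high-rate
      # "core" elements onto lower-rate followers
      by_rate <- order(rate, decreasing = TRUE)
      n_strong <- config$n_couplings
      n_weak <- config$n_weak_couplings
      if (2 * n_strong + n_weak > n)
        stop("population too small for the requested couplings",
             call. = FALSE)
      pool_n <- max(n_strong, min(n - n_strong, sum(rate >= 1.5)))
      if (!is.null(config$n_driver_pool))
        pool_n <- min(pool_n, max(n_strong, config$n_driver_pool))
      src_pool <- by_rate[seq_len(pool_n)]
      src_s <- if (length(src_pool) == n_strong) src_pool else
        pick(src_pool, n_strong)
      # targets come from the most active non-source elements: links
      # between rate-matched elements keep correlogram statistics
      # comparable across condition-induced rate changes
      tgt_cand <- setdiff(by_rate, src_s)   # descending rate
      tgt_s <- pick(tgt_cand[seq_len(max(n_strong,
                                         length(tgt_cand) %/% 2))],
                    n_strong)
      # weak ("latent") couplings take remaining targets; sources may
      # repeat (their coincidences sit below the significance floor)
      remaining <- setdiff(seq_len(n), c(tgt_s, src_s))
      if (length(remaining) < n_weak) remaining <- setdiff(seq_len(n), tgt_s)
      tgt_w <- if (n_weak > 0) pick(remaining, n_weak) else integer(0)
      src_w <- vapply(tgt_w, function(t)
        pick(setdiff(src_s, t), 1L), integer(1))
      src <- c(src_s, src_w)
      tgt <- c(tgt_s, tgt_w)
      cp_class <- c(rep("strong", config$n_couplings),
                    rep("weak", config$n_weak_couplings))
      if (!is.null(config$strength_range)) {
        strength <- stats::runif(n_cp, config$strength_range[1],
                                 config$strength_range[2])
        margins <- rep(NA_real_, n_cp)
      } else {
        # calibrate per-link copy probability to a target detection
        # margin (peak excess over flank noise, in noise SDs) at the
        # reference 600-s analysis window: strong links stay uniformly
        # recoverable across heterogeneous firing rates -- and above
        # threshold when a condition halves coupling strength -- while
        # weak ("latent") links sit below the significance floor until
        # coupling is potentiated
        margins <- ifelse(cp_class == "strong",
                          stats::runif(n_cp, config$margin_range[1],
                                       config$margin_range[2]),
                          stats::runif(n_cp, config$weak_margin_range[1],
                                       config$weak_margin_range[2]))
        t_ref <- 600
        p0 <- 0.6   # fraction of copies landing in the modal 1-ms bin
        comod <- (bf * intraburst[src] * intraburst[tgt] * n_latent[src] *
                    n_latent[tgt] +
                  (1 - bf) * baseline[src] * baseline[tgt] * n_latent[src] *
                    n_latent[tgt]) / (rate[src] * rate[tgt])
        flank_counts <- pmax(rate[src] * rate[tgt] * comod * t_ref / 1000,
                             0.05)
        # same floored noise estimate the significance rule applies
        sd_counts <- pmax(sqrt(flank_counts),
                          (stats::qpois(stats::pnorm(5), flank_counts) -
                             flank_counts) / 5)
        s_cal <- margins * 5 * sd_counts / (rate[src] * t_ref * p0)
        strength <- pmin(0.9, pmax(0.001, s_cal))
      }
      couplings <- data.frame(
        source = elements$id[src],
        target = elements$id[tgt],
        lag_ms = round(stats::runif(n_cp, config$lag_range_ms[1],
                                    config$lag_range_ms[2]), 1),
        strength = strength,
        jitter_ms = if (length(config$jitter_ms) == 2)
          stats::runif(n_cp, config$jitter_ms[1],
                       config$jitter_ms[2]) else config$jitter_ms,
        class = cp_class,
        margin = margins,
        stringsAsFactors = FALSE
      )
    }

    net <- list(elements = elements, couplings = couplings,
                rhythm_period_s = config$rhythm_period_s,
                period_jitter_s = config$period_jitter_s,
                burst_duration_s = config$burst_duration_s,
                config = config, seed = as.integer(seed))
    class(net) <- "gt_network"
    validate_network(net)
    net
  })
}

validate_network <- function(net) {
  stopifnot(inherits(net, "gt_network"))
  el <- net$elements
  if (anyDuplicated(el$id)) stop("element ids must be unique", call. = FALSE)
  if (nrow(net$couplings) > 0) {
    if (any(net$couplings$source == net$couplings$target))
      stop("couplings must join two distinct elements", call. = FALSE)
    if (!all(c(net$couplings$source, net$couplings$target) %in% el$id))
      stop("coupling references unknown element", call. = FALSE)
    if (any(net$couplings$lag_ms < 0 | net$couplings$lag_ms > 5))
      stop("coupling lag must lie in [0, 5] ms", call. = FALSE)
    if (any(net$couplings$strength < 0 | net$couplings$strength > 1))
      stop("coupling strength must lie in [0, 1]", call. = FALSE)
  }
  insp <- el$phase == "inspiratory"
  if (any(el$intraburst_rate_hz[insp] < el$baseline_rate_hz[insp]))
    stop("inspiratory elements need intraburst rate >= baseline", call. = FALSE)
  if (net$rhythm_period_s <= net$burst_duration_s)
    stop("rhythm period must exceed burst duration", call. = FALSE)
  invisible(net)
}

#' @export
print.gt_network <- function(x, ...) {
  el <- x$elements
  cat(sprintf("Ground-truth network: %d elements (%d units, %d multiunits)\n",
              nrow(el), sum(el$kind == "unit"), sum(el$kind == "multiunit")))
  cat(sprintf("  inspiratory: %d (%.0f%%), expiratory: %d\n",
              sum(el$phase == "inspiratory"),
              100 * mean(el$phase == "inspiratory"),
              sum(el$phase == "expiratory")))
  cat(sprintf("  rhythm: period %.1f s (jitter %.2f s), burst %.2f s\n",
              x$rhythm_period_s, x$period_jitter_s, x$burst_duration_s))
  cat(sprintf("  planted couplings: %d (lags %.1f-%.1f ms)\n",
              nrow(x$couplings),
              if (nrow(x$couplings)) min(x$couplings$lag_ms) else NA,
              if (nrow(x$couplings)) max(x$couplings$lag_ms) else NA))
  invisible(x)
}

#' Condition effect profile
#'
#' Per-element rate multipliers, a global coupling-strength multiplier and
#' a silencing fraction describing how an experimental condition reshapes
#' the network relative to control.  Defaults reproduce the reported
#' population effects: in hypoxia a minority subpopulation rises to
#' 135 +/- 6% of control while the majority falls to 64 +/- 2% (global
#' mean ~88%), with 0.4% of elements silenced and weakened coupling;
#' under isocitrate 84% of elements rise to 463 +/- 45% with strongly
#' potentiated coupling; isocitrate + hypoxia returns rates to control
#' levels while coupling stays potentiated.
#'
#' @param condition one of \code{"control"}, \code{"hypoxia"},
#'   \code{"isocitrate"}, \code{"isocitrate_hypoxia"}.
#' @param net the [generate_network()] output the profile applies to.
#' @param seed integer seed for the per-element draws.
#' @param up_fraction fraction of elements in the rate-increasing
#'   subpopulation.
#' @param up_mean,up_sd mean and SD of the multiplier in the up subset.
#' @param down_mean,down_sd mean and SD of the multiplier in the down subset.
#' @param coupling_strength_multiplier median factor on coupling copy
#'   probabilities (capped at 1 per spike).
#' @param coupling_strength_sdlog log-scale SD of the per-coupling
#'   multiplier: condition effects on synaptic efficacy are heterogeneous
#'   across connections (most links weaken in hypoxia, but some
#'   strengthen, and conversely under isocitrate), so each coupling draws
#'   its own multiplier from a log-normal centred on
#'   \code{coupling_strength_multiplier}.
#' @param silencing_fraction probability that an element stops firing
#'   entirely.
#' @return An object of class \code{"condition_profile"}.
#' @export
condition_profile <- function(condition = c("control", "hypoxia",
                                            "isocitrate",
                                            "isocitrate_hypoxia"),
                              net, seed = 1L,
                              up_fraction = NULL, up_mean = NULL,
                              up_sd = NULL, down_mean = NULL, down_sd = NULL,
                              coupling_strength_multiplier = NULL,
                              coupling_strength_sdlog = NULL,
                              silencing_fraction = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(net, "gt_network"))
  defaults <- switch(condition,
    control = list(up_fraction = 0, up_mean = 1, up_sd = 0,
                   down_mean = 1, down_sd = 0,
                   coupling_strength_multiplier = 1,
                   coupling_strength_sdlog = 0, silencing_fraction = 0),
    hypoxia = list(up_fraction = 0.34, up_mean = 1.35, up_sd = 0.06,
                   down_mean = 0.64, down_sd = 0.02,
                   coupling_strength_multiplier = 0.5,
                   coupling_strength_sdlog = 0,
                   silencing_fraction = 0.004),
    isocitrate = list(up_fraction = 0.84, up_mean = 4.63, up_sd = 0.45,
                      down_mean = 0.58, down_sd = 0.38,
                      coupling_strength_multiplier = 12,
                      coupling_strength_sdlog = 0,
                      silencing_fraction = 0),
    isocitrate_hypoxia = list(up_fraction = 1, up_mean = 1.0, up_sd = 0.1,
                              down_mean = 1.0, down_sd = 0.1,
                              coupling_strength_multiplier = 3,
                              coupling_strength_sdlog = 0,
                              silencing_fraction = 0.004)
  )
  take <- function(x, d) if (is.null(x)) d else x
  up_fraction <- take(up_fraction, defaults$up_fraction)
  up_mean <- take(up_mean, defaults$up_mean)
  up_sd <- take(up_sd, defaults$up_sd)
  down_mean <- take(down_mean, defaults$down_mean)
  down_sd <- take(down_sd, defaults$down_sd)
  coupling_strength_multiplier <-
    take(coupling_strength_multiplier, defaults$coupling_strength_multiplier)
  coupling_strength_sdlog <-
    take(coupling_strength_sdlog, defaults$coupling_strength_sdlog)
  silencing_fraction <- take(silencing_fraction, defaults$silencing_fraction)
  stopifnot(up_fraction >= 0, up_fraction <= 1,
            silencing_fraction >= 0, silencing_fraction <= 1,
            coupling_strength_multiplier > 0)

  ids <- net$elements$id
  n <- length(ids)
  n_cp <- nrow(net$couplings)
  # the rate-increasing subpopulation is the most active one: the
  # rhythmogenic core keeps driving (gasping persists in hypoxia, and
  # excitatory metabolic support recruits active cells first), so up/down
  # membership follows activity rank rather than a uniform draw
  el <- net$elements
  bf <- net$burst_duration_s / net$rhythm_period_s
  exp_rate <- (bf * el$intraburst_rate_hz +
                 (1 - bf) * el$baseline_rate_hz) * el$n_latent
  profile <- with_local_seed(seed, {
    if (condition == "control") {
      mult <- rep(1, n)
      silenced <- rep(FALSE, n)
      cp_mult <- rep(1, n_cp)
    } else {
      n_up <- round(up_fraction * n)
      up <- rank(-exp_rate, ties.method = "first") <= n_up
      mult <- ifelse(up,
                     stats::rnorm(n, up_mean, up_sd),
                     stats::rnorm(n, down_mean, down_sd))
      mult <- pmax(mult, 0.05)
      silenced <- stats::runif(n) < silencing_fraction
      cp_mult <- coupling_strength_multiplier *
        stats::rlnorm(n_cp, 0, coupling_strength_sdlog)
    }
    list(condition = condition,
         rate_multipliers = stats::setNames(mult, ids),
         coupling_strength_multiplier = coupling_strength_multiplier,
         coupling_multipliers = cp_mult,
         silenced = stats::setNames(silenced, ids),
         seed = as.integer(seed))
  })
  class(profile) <- "condition_profile"
  profile
}

#' @export
print.condition_profile <- function(x, ...) {
  cat(sprintf("Condition profile '%s': %d elements\n",
              x$condition, length(x$rate_multipliers)))
  cat(sprintf("  rate multiplier: mean %.2f (range %.2f-%.2f)\n",
              mean(x$rate_multipliers), min(x$rate_multipliers),
              max(x$rate_multipliers)))
  cat(sprintf("  coupling strength x%.2f, %d element(s) silenced\n",
              x$coupling_strength_multiplier, sum(x$silenced)))
  invisible(x)
}

# Poisson spike times on piecewise-constant rate segments.
piecewise_poisson <- function(breaks, rates) {
  out <- vector("list", length(rates))
  for (i in seq_along(rates)) {
    len <- breaks[i + 1] - breaks[i]
    if (rates[i] <= 0 || len <= 0) next
    k <- stats::rpois(1, rates[i] * len)
    if (k > 0) out[[i]] <- breaks[i] + sort(stats::runif(k, 0, len))
  }
  unlist(out, use.names = FALSE) %||% numeric(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate spike trains for a network under a condition
#'
#' Draws population burst windows (periodic with Gaussian period jitter),
#' then per-element inhomogeneous Poisson spiking with a boxcar rate
#' envelope: inspiratory elements fire at their intraburst rate inside
#' bursts and at baseline outside; expiratory elements are suppressed
#' inside bursts.  Multi-unit elements superpose 2--4 latent neurons.
#' Each planted coupling then copies source spikes into the target at
#' \code{lag_ms} plus Gaussian jitter with per-spike probability
#' \code{strength} (times the condition's coupling multiplier, capped at
#' 1); coupling is rate-preserving -- each copied spike replaces one of
#' the target's own spikes, so the driven element phase-locks to its
#' driver without changing its firing rate.  Every latent neuron finally
#' passes through 2-ms refractory enforcement.
#'
#' @param net a [generate_network()] result.
#' @param profile a [condition_profile()] for the same network.
#' @param duration_s recording length, seconds (at least three rhythm
#'   periods).
#' @param seed integer seed.
#' @return An object of class \code{"spike_train_set"}: \code{times} (named
#'   list of sorted spike-time vectors, seconds), \code{elements} (metadata
#'   data frame), \code{bursts} (data frame of burst windows),
#'   \code{duration_s}, \code{condition}.
#' @export
simulate_spike_trains <- function(net, profile, duration_s, seed = 1L) {
  stopifnot(inherits(net, "gt_network"), inherits(profile, "condition_profile"))
  if (!setequal(names(profile$rate_multipliers), net$elements$id))
    stop("profile does not match network elements", call. = FALSE)
  if (duration_s < 3 * net$rhythm_period_s)
    stop("duration_s must cover at least three rhythm periods", call. = FALSE)

  with_local_seed(seed, {
    # population burst windows
    onsets <- numeric(0)
    t <- stats::runif(1, 0, net$rhythm_period_s)
    while (t < duration_s) {
      onsets <- c(onsets, t)
      step <- stats::rnorm(1, net$rhythm_period_s, net$period_jitter_s)
      t <- t + max(step, net$burst_duration_s + 0.1)
    }
    offsets <- pmin(onsets + net$burst_duration_s, duration_s)
    bursts <- data.frame(onset_s = onsets, offset_s = offsets)

    breaks <- sort(unique(c(0, onsets[onsets < duration_s],
                            offsets[offsets < duration_s], duration_s)))
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    in_burst <- vapply(mids, function(m)
      any(m >= onsets & m < offsets), logical(1))

    el <- net$elements
    mult <- profile$rate_multipliers[el$id]
    silenced <- profile$silenced[el$id]

    # latent trains per element (multiunits superpose several)
    latent <- vector("list", nrow(el))
    names(latent) <- el$id
    for (i in seq_len(nrow(el))) {
      if (silenced[i]) { latent[[i]] <- list(numeric(0)); next }
      rate_in <- el$intraburst_rate_hz[i] * mult[i]
      rate_out <- el$baseline_rate_hz[i] * mult[i]
      seg_rates <- ifelse(in_burst, rate_in, rate_out)
      latent[[i]] <- lapply(seq_len(el$n_latent[i]), function(j)
        piecewise_poisson(breaks, seg_rates))
    }

    # planted couplings: rate-preserving synchronization.  Each source
    # spike, with probability strength, phase-locks the target: a copy
    # appears at lag + jitter and one of the target's own spikes (the
    # nearest unaligned one) is removed, so coupling reshapes spike
    # timing without changing firing rates -- the driven neuron fires on
    # the driver's clock rather than its own.
    source_trains <- lapply(latent, function(l) sort(unlist(l, use.names = FALSE)))
    cp <- net$couplings
    if (nrow(cp) > 0) {
      cpm <- profile$coupling_multipliers %||%
        rep(profile$coupling_strength_multiplier, nrow(cp))
      for (k in seq_len(nrow(cp))) {
        if (silenced[cp$target[k]] || silenced[cp$source[k]]) next
        s_eff <- min(1, cp$strength[k] * cpm[k])
        src <- source_trains[[cp$source[k]]]
        if (length(src) == 0 || s_eff <= 0) next
        keep <- stats::runif(length(src)) < s_eff
        copies <- src[keep] + cp$lag_ms[k] / 1000
        if (cp$jitter_ms[k] > 0)
          copies <- copies + stats::rnorm(sum(keep), 0, cp$jitter_ms[k] / 1000)
        copies <- copies[copies >= 0 & copies < duration_s]
        own <- latent[[cp$target[k]]][[1]]
        if (length(copies) > 0 && length(own) > 0) {
          # one own spike removed per copy (random draw), so the
          # element's firing rate is exactly rate-multiplier-controlled
          n_del <- min(length(own), length(copies))
          own <- own[-sample.int(length(own), n_del)]
        }
        latent[[cp$target[k]]][[1]] <- sort(c(own, copies))
      }
    }

    refr_s <- 0.002
    times <- lapply(latent, function(l) {
      cleaned <- lapply(l, function(tt)
        enforce_refractory(sort(tt), refractory_ms = 1000 * refr_s)$times_s)
      sort(unlist(cleaned, use.names = FALSE))
    })

    out <- list(times = times,
                elements = el[, c("id", "kind", "phase")],
                bursts = bursts,
                duration_s = duration_s,
                condition = profile$condition,
                seed = as.integer(seed))
    class(out) <- "spike_train_set"
    out
  })
}

#' @export
print.spike_train_set <- function(x, ...) {
  n_sp <- vapply(x$times, length, integer(1))
  cat(sprintf("Spike train set: %d elements, %.0f s, condition '%s'\n",
              length(x$times), x$duration_s, x$condition))
  cat(sprintf("  spikes: %d total (median %.0f per element); %d bursts\n",
              sum(n_sp), stats::median(n_sp), nrow(x$bursts)))
  invisible(x)
}

#' Extracellular spike waveform template
#'
#' A stereotyped biphasic (negative trough, small positive overshoot) or
#' triphasic extracellular action-potential shape, sampled at the
#' digitization rate.  Used by [synthesize_raw_signal()].
#'
#' @param sampling_rate_hz digitization rate, Hz.
#' @param duration_ms template support, ms (must not exceed the 2-ms
#'   refractory period).
#' @param amplitude trough depth in signal units.
#' @param shape \code{"biphasic"} or \code{"triphasic"}.
#' @return Numeric vector of samples.
#' @export
spike_template <- function(sampling_rate_hz = 25000, duration_ms = 1.2,
                           amplitude = 1, shape = c("biphasic", "triphasic")) {
  shape <- match.arg(shape)
  if (duration_ms > 2)
    stop("template must not outlast the 2-ms refractory period", call. = FALSE)
  n <- max(3L, round(duration_ms / 1000 * sampling_rate_hz))
  t <- seq(0, duration_ms, length.out = n)
  t0 <- duration_ms * 0.3
  w1 <- duration_ms * 0.08
  t1 <- duration_ms * 0.6
  w2 <- duration_ms * 0.18
  w <- -exp(-(t - t0)^2 / (2 * w1^2)) + 0.35 * exp(-(t - t1)^2 / (2 * w2^2))
  if (shape == "triphasic")
    w <- w + 0.25 * exp(-(t - duration_ms * 0.12)^2 / (2 * (duration_ms * 0.06)^2))
  amplitude * w / max(abs(w))
}

#' Synthesize a raw multi-channel recording from spike trains
#'
#' Places each element's waveform template at its spike times on the
#' element's electrode channel (waveforms superpose linearly) and adds
#' stationary Gaussian noise.  Ground-truth spike times are retained in
#' the result.
#'
#' @param trains a [simulate_spike_trains()] result.
#' @param net the originating [generate_network()] (supplies electrode
#'   geometry).
#' @param templates a single numeric template (recycled for all elements)
#'   or a named list of templates per element id; see [spike_template()].
#' @param noise_sd SD of the additive stationary Gaussian noise, signal
#'   units.
#' @param noise_correlation_ms temporal correlation scale of the noise
#'   (Gaussian autocorrelation).  Extracellular background noise is
#'   band-limited -- dominated by distant multi-unit activity and
#'   electrode/tissue filtering -- not white at the 25-kHz digitization
#'   rate; the 0.2-ms default reproduces realistic threshold-crossing
#'   statistics.  Set to 0 for white noise.
#' @param seed integer seed for the noise.
#' @param channels integer vector of channel indices (1-based, row-major
#'   over the grid) to synthesize; default: every grid channel.
#' @return An object of class \code{"raw_recording"}: \code{samples}
#'   (channels x time matrix), \code{sampling_rate_hz}, \code{geometry},
#'   \code{channel_ids}, \code{duration_s}, and \code{ground_truth}
#'   (element-to-channel map plus true spike times).
#' @export
synthesize_raw_signal <- function(trains, net, templates = spike_template(),
                                  noise_sd = 0.1, noise_correlation_ms = 0.2,
                                  seed = 1L, channels = NULL) {
  stopifnot(inherits(trains, "spike_train_set"), inherits(net, "gt_network"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  fs <- net$config$sampling_rate_hz
  refr_samples <- 0.002 * fs
  el <- net$elements
  if (is.numeric(templates)) {
    templates <- stats::setNames(rep(list(templates), nrow(el)), el$id)
  }
  if (!all(el$id %in% names(templates)))
    stop("templates must cover every element id", call. = FALSE)
  if (any(vapply(templates, length, integer(1)) > refr_samples))
    stop("template longer than the refractory period", call. = FALSE)

  grid <- net$config$grid
  chan_of <- el$electrode_row * grid[2] + el$electrode_col + 1L
  names(chan_of) <- el$id
  if (is.null(channels)) channels <- seq_len(prod(grid))
  n_samp <- round(trains$duration_s * fs)

  # Gaussian smoothing kernel imposing the noise correlation scale;
  # renormalized so the output SD equals noise_sd exactly.
  kernel <- NULL
  if (noise_sd > 0 && noise_correlation_ms > 0) {
    sig <- noise_correlation_ms / 1000 * fs
    half <- ceiling(4 * sig)
    kernel <- stats::dnorm(seq(-half, half), sd = sig)
    kernel <- kernel / sqrt(sum(kernel^2))
  }
  with_local_seed(seed, {
    samples <- if (noise_sd > 0) {
      m <- matrix(stats::rnorm(length(channels) * n_samp, 0, noise_sd),
                  nrow = length(channels))
      if (!is.null(kernel)) {
        for (r in seq_len(nrow(m))) {
          padded <- c(rev(m[r, seq_along(kernel)]), m[r, ],
                      rev(m[r, n_samp - seq_along(kernel) + 1L]))
          sm <- stats::filter(padded, kernel, sides = 2)
          m[r, ] <- sm[length(kernel) + seq_len(n_samp)]
        }
      }
      m
    } else {
      matrix(0, nrow = length(channels), ncol = n_samp)
    }
    rownames(samples) <- as.character(channels)
    for (id in el$id) {
      ch <- chan_of[[id]]
      row <- match(ch, channels)
      if (is.na(row)) next
      tpl <- templates[[id]]
      for (t in trains$times[[id]]) {
        i0 <- round(t * fs) + 1L
        i1 <- min(i0 + length(tpl) - 1L, n_samp)
        if (i0 > n_samp) next
        k <- i1 - i0 + 1L
        samples[row, i0:i1] <- samples[row, i0:i1] + tpl[seq_len(k)]
      }
    }
    out <- list(samples = samples,
                sampling_rate_hz = fs,
                geometry = grid,
                pitch_um = net$config$pitch_um,
                channel_ids = as.integer(channels),
                duration_s = trains$duration_s,
                ground_truth = list(channel_of_element = chan_of,
                                    times = trains$times))
    class(out) <- "raw_recording"
    out
  })
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("Raw recording: %d channel(s) x %d samples (%.1f s at %g kHz)\n",
              nrow(x$samples), ncol(x$samples), x$duration_s,
              x$sampling_rate_hz / 1000))
  cat(sprintf("  grid %d x %d, %g um pitch\n",
              x$geometry[1], x$geometry[2], x$pitch_um))
  invisible(x)
}
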