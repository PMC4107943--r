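# Shared fixtures, built in code at test time.

# A small network with explicit coupling parameters.
tiny_network <- function(n_units = 4, n_multiunits = 0, n_couplings = 0,
                         seed = 1, ...) {
  generate_network(
    generator_config(n_units = n_units, n_multiunits = n_multiunits,
                     n_couplings = n_couplings, n_weak_couplings = 0, ...),
    seed = seed)
}

# Homogeneous Poisson spike train on [0, duration).
poisson_train <- function(rate_hz, duration_s, seed) {
  with_seed_local(seed, sort(stats::runif(stats::rpois(1, rate_hz * duration_s),
                                          0, duration_s)))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# A deliberately coupled pair: b echoes a at lag_ms with probability
# strength, plus independent background in b.
coupled_pair <- function(rate_a = 5, rate_b_own = 3, strength = 0.5,
                         lag_ms = 2, jitter_ms = 0, duration_s = 300,
                         seed = 1) {
  with_seed_local(seed, {
    a <- sort(stats::runif(stats::rpois(1, rate_a * duration_s), 0, duration_s))
    copies <- a[stats::runif(length(a)) < strength] + lag_ms / 1000
    if (jitter_ms > 0)
      copies <- copies + stats::rnorm(length(copies), 0, jitter_ms / 1000)
    own <- sort(stats::runif(stats::rpois(1, rate_b_own * duration_s),
                             0, duration_s))
    b <- sort(c(own, copies))
    list(a = a, b = b[b >= 0 & b < duration_s])
  })
}

# Independent nested-loop pair counter: the brute-force oracle for
# correlogram counts, on binarized (collapsed) 1-ms bins.
brute_force_counts <- function(a, b, duration_s, max_lag = 50) {
  ab <- sort(unique(floor(a[a >= 0 & a < duration_s] * 1000)))
  bb <- sort(unique(floor(b[b >= 0 & b < duration_s] * 1000)))
  n_bins <- floor(duration_s * 1000)
  counts <- stats::setNames(integer(2 * max_lag + 1),
                            as.character(-max_lag:max_lag))
  for (i in ab) {
    for (j in bb) {
      tau <- j - i
      if (abs(tau) <= max_lag && i >= 0 && i < n_bins && j >= 0 && j < n_bins)
        counts[as.character(tau)] <- counts[as.character(tau)] + 1L
    }
  }
  counts
}
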