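test_that("degenerate generator configurations are rejected", {
  expect_error(generator_config(n_units = 0, n_multiunits = 0),
               "at least one element")
  expect_error(generator_config(inspiratory_fraction = 1.3), "inspiratory")
  expect_error(generator_config(n_units = 2, n_multiunits = 0,
                                n_couplings = 3, n_weak_couplings = 0),
               "population too small")
  expect_error(generator_config(burst_duration_s = 6), "rhythm_period_s")
})

test_that("identical (config, seed) pairs give identical networks and trains", {
  cfg <- generator_config(n_units = 8, n_multiunits = 2, n_couplings = 3,
                          n_weak_couplings = 1)
  n1 <- generate_network(cfg, seed = 11)
  n2 <- generate_network(cfg, seed = 11)
  expect_identical(n1, n2)
  p1 <- condition_profile("hypoxia", n1, seed = 5)
  t1 <- simulate_spike_trains(n1, p1, 60, seed = 9)
  t2 <- simulate_spike_trains(n2, condition_profile("hypoxia", n2, seed = 5),
                              60, seed = 9)
  expect_identical(t1, t2)
  expect_false(identical(n1, generate_network(cfg, seed = 12)))
})

test_that("network invariants hold across random seeds", {
  cfg <- generator_config(n_units = 10, n_multiunits = 5, n_couplings = 6,
                          n_weak_couplings = 3)
  for (seed in 1:10) {
    net <- generate_network(cfg, seed = seed)
    el <- net$elements
    expect_false(anyDuplicated(el$id) > 0)
    expect_true(all(net$couplings$source != net$couplings$target))
    expect_true(all(net$couplings$lag_ms >= 0 & net$couplings$lag_ms <= 5))
    expect_true(all(net$couplings$strength >= 0 & net$couplings$strength <= 1))
    insp <- el$phase == "inspiratory"
    expect_true(all(el$intraburst_rate_hz[insp] >= el$baseline_rate_hz[insp]))
    expect_true(all(el$electrode_row %in% 0:5 & el$electrode_col %in% 0:9))
    # target-unique couplings
    expect_false(anyDuplicated(net$couplings$target) > 0)
  }
})

test_that("inspiratory count matches the binomial expectation at large n", {
  # oracle: 99% binomial interval for n = 1000, p = 0.87 over units;
  # multiunits are always inspiratory so they are excluded from the check
  net <- generate_network(generator_config(n_units = 1000, n_multiunits = 0,
                                           n_couplings = 0,
                                           n_weak_couplings = 0), seed = 3)
  n_insp <- sum(net$elements$phase == "inspiratory")
  expect_gte(n_insp, qbinom(0.005, 1000, 0.87))
  expect_lte(n_insp, qbinom(0.995, 1000, 0.87))
})

test_that("a full-strength zero-jitter coupling copies every source spike", {
  net <- tiny_network(n_units = 2, seed = 2)
  net$couplings <- data.frame(source = "e01", target = "e02", lag_ms = 2,
                              strength = 1, jitter_ms = 0, class = "strong",
                              margin = NA_real_, stringsAsFactors = FALSE)
  prof <- condition_profile("control", net, seed = 1)
  tr <- simulate_spike_trains(net, prof, 60, seed = 4)
  src <- tr$times$e01
  tgt <- tr$times$e02
  # every source spike has a target spike 2 ms later, unless the copy was
  # refractory-blocked by a neighbouring copy
  matched <- vapply(src, function(t) any(abs(tgt - (t + 0.002)) < 1e-9),
                    logical(1))
  blocked <- c(FALSE, diff(src) < 0.002)
  expect_true(all(matched | blocked))
})

test_that("rate multipliers scale measured rates proportionally", {
  net <- tiny_network(n_units = 6, seed = 5)
  ctrl <- condition_profile("control", net, seed = 1)
  half <- ctrl
  half$rate_multipliers[] <- 0.5
  t1 <- simulate_spike_trains(net, ctrl, 600, seed = 7)
  t2 <- simulate_spike_trains(net, half, 600, seed = 8)
  n1 <- sum(lengths(t1$times))
  n2 <- sum(lengths(t2$times))
  expect_gt(n1, 1000)
  # ratio ~ 0.5 within Poisson error (a few SD of the count ratio)
  se <- 0.5 * sqrt(1 / n1 + 1 / n2)
  expect_lt(abs(n2 / n1 - 0.5), 4 * se + 0.02)
})

test_that("trains respect the refractory period and burst structure", {
  net <- tiny_network(n_units = 5, seed = 6)
  prof <- condition_profile("control", net, seed = 1)
  tr <- simulate_spike_trains(net, prof, 120, seed = 2)
  for (id in names(tr$times)) {
    tt <- tr$times[[id]]
    expect_false(is.unsorted(tt))
    if (net$elements$kind[net$elements$id == id] == "unit" && length(tt) > 1)
      expect_gte(min(diff(tt)), 0.002 - 1e-12)
  }
  # inspiratory elements fire faster inside bursts
  insp <- net$elements$id[net$elements$phase == "inspiratory"]
  bursts <- tr$bursts
  t_in <- sum(bursts$offset_s - bursts$onset_s)
  for (id in insp) {
    tt <- tr$times[[id]]
    if (length(tt) < 30) next
    in_burst <- vapply(tt, function(t)
      any(t >= bursts$onset_s & t < bursts$offset_s), logical(1))
    rate_in <- sum(in_burst) / t_in
    rate_out <- sum(!in_burst) / (tr$duration_s - t_in)
    expect_gt(rate_in, rate_out)
  }
})

test_that("total spike count equals the sum of per-element counts", {
  net <- tiny_network(n_units = 4, n_multiunits = 2, seed = 8)
  tr <- simulate_spike_trains(net, condition_profile("control", net, seed = 1),
                              60, seed = 3)
  df_counts <- lengths(tr$times)
  expect_identical(sum(df_counts), length(unlist(tr$times)))
  expect_error(simulate_spike_trains(net,
                                     condition_profile("control", net, 1), 8),
               "three rhythm periods")
})

test_that("condition profile defaults encode the reported population effects", {
  net <- generate_network(generator_config(n_units = 500, n_multiunits = 0,
                                           n_couplings = 0,
                                           n_weak_couplings = 0), seed = 1)
  ctrl <- condition_profile("control", net, seed = 1)
  expect_true(all(ctrl$rate_multipliers == 1))
  expect_equal(ctrl$coupling_strength_multiplier, 1)
  expect_true(all(!ctrl$silenced))
  hyp <- condition_profile("hypoxia", net, seed = 2)
  expect_lt(hyp$coupling_strength_multiplier, 1)
  # global mean rate multiplier near 88% of control
  expect_lt(abs(mean(hyp$rate_multipliers) - 0.88), 0.05)
  iso <- condition_profile("isocitrate", net, seed = 3)
  expect_gt(mean(iso$rate_multipliers), 3)
  expect_gt(iso$coupling_strength_multiplier, 1)
})

test_that("raw synthesis places templates at spike times over noise", {
  net <- tiny_network(n_units = 1, n_couplings = 0, seed = 9,
                      grid = c(1, 1), sampling_rate_hz = 25000)
  net$elements$electrode_row <- 0
  net$elements$electrode_col <- 0
  tr <- simulate_spike_trains(net, condition_profile("control", net, 1),
                              20, seed = 2)
  tr$times$e01 <- 0.5   # a single spike
  tpl <- spike_template()
  raw <- synthesize_raw_signal(tr, net, templates = tpl, noise_sd = 0,
                               seed = 1, channels = 1)
  nz <- which(raw$samples[1, ] != 0)
  i0 <- round(0.5 * 25000) + 1
  expect_equal(min(nz), i0)
  expect_equal(max(nz), i0 + length(tpl) - 1)

  # linear superposition of overlapping spikes
  tr$times$e01 <- c(0.5, 0.501)
  raw2 <- synthesize_raw_signal(tr, net, templates = tpl, noise_sd = 0,
                                seed = 1, channels = 1)
  manual <- numeric(ncol(raw2$samples))
  for (t in c(0.5, 0.501)) {
    j <- round(t * 25000) + 1
    manual[j:(j + length(tpl) - 1)] <- manual[j:(j + length(tpl) - 1)] + tpl
  }
  expect_equal(raw2$samples[1, ], manual)
})

test_that("noise SD is reproduced and long templates are rejected", {
  net <- tiny_network(n_units = 1, seed = 10, grid = c(1, 1))
  net$elements$electrode_row <- 0
  net$elements$electrode_col <- 0
  tr <- simulate_spike_trains(net, condition_profile("control", net, 1),
                              40, seed = 2)
  tr$times$e01 <- numeric(0)  # empty: pure noise
  raw <- synthesize_raw_signal(tr, net, noise_sd = 1, seed = 3, channels = 1)
  expect_gt(ncol(raw$samples), 1e6 - 1)
  expect_lt(abs(sd(raw$samples[1, ]) - 1), 0.02)
  expect_error(spike_template(duration_ms = 3), "refractory")
  long_tpl <- rep(-1, 0.003 * 25000)
  expect_error(synthesize_raw_signal(tr, net, templates = long_tpl,
                                     noise_sd = 0, seed = 1, channels = 1),
               "refractory")
})
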