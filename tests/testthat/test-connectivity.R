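test_that("binarization collapses within-bin spikes and round-trips times", {
  b <- binarize(list(x = c(0.0002, 0.0007)), t_end = 1)
  expect_equal(b$bins$x, 0L)
  expect_equal(b$n_collapsed, 1L)
  expect_equal(binarize(list(x = numeric(0)), t_end = 1)$bins$x, integer(0))
  tt <- sort(with_seed_local(1, runif(50, 0, 10)))
  bb <- binarize(list(x = tt), t_end = 10)
  recovered <- bb$bins$x / 1000
  expect_true(all(abs(tt - recovered[findInterval(tt, recovered)]) < 0.001))
  m <- as.matrix(binarize(list(x = c(0.0005, 0.5)), t_end = 1))
  expect_equal(sum(m), 2L)
  expect_true(all(m %in% c(0L, 1L)))
})

test_that("a shifted train gives a dominant peak at its lag", {
  a <- sort(with_seed_local(2, runif(400, 0, 60)))
  cg <- cross_correlogram(a, a + 0.002, 61)
  expect_equal(cg$peak_lag_ms, 2)
  expect_true(isTRUE(cg$significant))
  expect_gt(cg$peak_value, 10 * sort(cg$values, decreasing = TRUE)[2])
})

test_that("fast counting equals the brute-force nested-loop oracle exactly", {
  for (seed in 1:10) {
    pair <- with_seed_local(seed, list(a = sort(runif(100, 0, 20)),
                                       b = sort(runif(100, 0, 20))))
    cg <- cross_correlogram(pair$a, pair$b, 20, min_spikes = 2)
    oracle <- brute_force_counts(pair$a, pair$b, 20)
    expect_identical(unname(cg$counts), unname(oracle))
  }
})

test_that("the mirror identity holds exactly", {
  for (seed in 1:5) {
    pair <- with_seed_local(seed + 20, list(a = sort(runif(300, 0, 60)),
                                            b = sort(runif(250, 0, 60))))
    ab <- cross_correlogram(pair$a, pair$b, 60)
    ba <- cross_correlogram(pair$b, pair$a, 60)
    expect_identical(unname(ab$counts), unname(rev(ba$counts)))
    expect_equal(ab$peak_value, ba$peak_value)
  }
})

test_that("independent Poisson pairs hover near 1 and are not flagged", {
  n_sig <- 0
  for (seed in 1:20) {
    pair <- with_seed_local(seed + 40, list(
      a = sort(runif(rpois(1, 5 * 600), 0, 600)),
      b = sort(runif(rpois(1, 5 * 600), 0, 600))))
    cg <- cross_correlogram(pair$a, pair$b, 600)
    expect_lt(abs(cg$baseline - 1), 0.1)
    expect_true(all(abs(cg$values - 1) < 6 * max(cg$noise_sd, 0.01) + 0.5))
    if (isTRUE(cg$significant)) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 1)
})

test_that("flank noise estimation matches its inputs", {
  cg <- cross_correlogram(sort(with_seed_local(3, runif(300, 0, 60))),
                          sort(with_seed_local(4, runif(300, 0, 60))), 60)
  # flat flanks give zero empirical SD
  flat <- cg
  flat$values[] <- 1
  ns <- estimate_noise_sd(flat)
  expect_equal(ns$baseline, 1)
  expect_equal(ns$noise_sd, 0)
  # known-Gaussian flanks are recovered within 10% at 90 flank bins
  set.seed(5)
  g <- cg
  g$values[abs(g$lags_ms) > 5] <- rnorm(90, 2, 0.4)
  ns2 <- estimate_noise_sd(g)
  expect_lt(abs(ns2$baseline - 2), 0.2)
  expect_lt(abs(ns2$noise_sd - 0.4), 0.1)
  # symmetric correlogram gives the same estimate as its mirror
  m <- g
  m$values <- rev(g$values)
  expect_equal(estimate_noise_sd(m), estimate_noise_sd(g))
})

test_that("significance flagging follows the 5-SD rule with tie-breaking", {
  base <- cross_correlogram(sort(with_seed_local(6, runif(3000, 0, 600))),
                            sort(with_seed_local(7, runif(3000, 0, 600))),
                            600)
  stub <- base
  stub$counts[] <- 200L
  stub$values[] <- stub$counts[1] * stub$n_bins / (stub$n_a * stub$n_b)
  mkpeak <- function(cg, lag, excess_sd) {
    i <- match(lag, cg$lags_ms)
    ns <- estimate_noise_sd(cg)
    cg$values[i] <- cg$values[i] + excess_sd * max(ns$noise_sd, 1e-6)
    cg
  }
  # with constant flanks the empirical SD is 0; use realistic flanks
  set.seed(8)
  noisy <- base
  noisy$values[abs(noisy$lags_ms) > 5] <- rnorm(90, 1, 0.05)
  noisy$values[abs(noisy$lags_ms) <= 5] <- 1
  ns <- estimate_noise_sd(noisy)
  eff_sd <- max(ns$noise_sd,
                sqrt(ns$baseline * noisy$n_a * noisy$n_b / noisy$n_bins) *
                  noisy$n_bins / (noisy$n_a * noisy$n_b))
  hi <- noisy
  hi$values[match(3, hi$lags_ms)] <- ns$baseline + 20 * eff_sd
  expect_true(assess_significance(hi)$significant)
  lo <- noisy
  lo$values[match(3, lo$lags_ms)] <- ns$baseline + 4.9 * ns$noise_sd
  expect_false(assess_significance(lo)$significant)

  # ties broken toward smaller |lag|, then negative lag
  tie <- noisy
  tie$values[match(c(-4, 2, -2), tie$lags_ms)] <- ns$baseline + 20 * eff_sd
  expect_equal(assess_significance(tie)$peak_lag_ms, -2)
})

test_that("peak shapes follow the zero/sharp/broad/lag taxonomy", {
  base <- cross_correlogram(sort(with_seed_local(9, runif(3000, 0, 600))),
                            sort(with_seed_local(10, runif(3000, 0, 600))),
                            600)
  set.seed(11)
  base$values[abs(base$lags_ms) > 5] <- rnorm(90, 1, 0.02)
  base$values[abs(base$lags_ms) <= 5] <- 1
  ns <- estimate_noise_sd(base)
  eff_sd <- max(ns$noise_sd,
                sqrt(ns$baseline * base$n_a * base$n_b / base$n_bins) *
                  base$n_bins / (base$n_a * base$n_b))
  spike_at <- function(lags) {
    cg <- base
    cg$values[match(lags, cg$lags_ms)] <- ns$baseline + 30 * eff_sd
    assess_significance(cg)
  }
  expect_equal(spike_at(0)$shape, "zero_sharp")
  expect_equal(spike_at(c(-1, 0, 1, 2))$shape, "zero_broad")
  expect_equal(spike_at(3)$shape, "lag_long")
  expect_equal(spike_at(c(1))$shape, "lag_short")
  ns_only <- base
  expect_error(classify_peak_shape(assess_significance(ns_only)),
               "significant")
})

test_that("linkage matrices are symmetric with zeros off the significant set", {
  set.seed(12)
  trains <- list(
    a = sort(runif(1500, 0, 300)),
    b = numeric(0),
    c = sort(runif(1200, 0, 300)),
    d = sort(runif(900, 0, 300)))
  trains$b <- sort(c(trains$a + 0.002,
                     runif(300, 0, 300)))  # strong a->b coupling
  lm <- build_linkage_matrix(trains, condition = "test",
                             t_start = 0, t_end = 300)
  expect_equal(lm$n_pairs, 6)
  expect_true(isSymmetric(lm$values))
  expect_true(all(diag(lm$values) == 0))
  expect_gt(lm$values["a", "b"], 0)
  expect_equal(lm$values["a", "b"], lm$values["b", "a"])
  expect_equal(lm$peak_lags["a", "b"], -lm$peak_lags["b", "a"])
  # independent pairs zero
  expect_equal(lm$values["c", "d"], 0)
  expect_equal(count_links(lm), sum(lm$values[upper.tri(lm$values)] != 0))
})

test_that("pairs with too few spikes are excluded, not zeroed", {
  trains <- list(a = sort(with_seed_local(13, runif(500, 0, 100))),
                 b = c(1, 2, 3),   # below min_spikes
                 c = sort(with_seed_local(14, runif(400, 0, 100))))
  lm <- build_linkage_matrix(trains, t_start = 0, t_end = 100)
  expect_equal(length(lm$excluded), 2)
  expect_equal(lm$n_evaluated, 1)
  expect_true(all(c("a:b", "b:c") %in% lm$excluded))
  expect_error(cross_correlogram(c(1, 2), c(3, 4), 10),
               class = "rhythmnet_too_few_spikes")
})

test_that("delta matrices subtract element-wise and are antisymmetric", {
  set.seed(15)
  trains1 <- list(a = sort(runif(800, 0, 200)), b = sort(runif(700, 0, 200)),
                  c = sort(runif(600, 0, 200)))
  trains1$b <- sort(c(trains1$b, trains1$a + 0.001))
  trains2 <- lapply(trains1, function(tt) thin_train(tt, 0.8, seed = 1))
  l1 <- build_linkage_matrix(trains1, "x", t_start = 0, t_end = 200)
  l2 <- build_linkage_matrix(trains2, "y", t_start = 0, t_end = 200)
  expect_true(all(delta_matrix(l1, l1)$values == 0))
  d12 <- delta_matrix(l1, l2)
  d21 <- delta_matrix(l2, l1)
  expect_equal(d12$values, -d21$values)
  expect_equal(d12$considered, d21$considered)
  l3 <- l2
  rownames(l3$values)[1] <- colnames(l3$values)[1] <- "zz"
  expect_error(delta_matrix(l1, l3), "element")
})

test_that("normalization is invariant to proportional thinning", {
  # expected normalized peak unchanged when both trains are thinned,
  # within 2 empirical standard errors (the normalization's purpose)
  peak_of <- function(p, seed) {
    pair <- coupled_pair(rate_a = 6, rate_b_own = 4, strength = 0.4,
                         duration_s = 300, seed = seed)
    a <- if (p < 1) thin_train(pair$a, p, seed = seed + 1000) else pair$a
    b <- if (p < 1) thin_train(pair$b, p, seed = seed + 2000) else pair$b
    cross_correlogram(a, b, 300)$peak_value
  }
  for (p in c(0.5, 0.8)) {
    full <- vapply(1:12, function(s) peak_of(1, s), numeric(1))
    thin <- vapply(1:12, function(s) peak_of(p, s), numeric(1))
    sem <- sqrt(var(full) / 12 + var(thin) / 12)
    expect_lt(abs(mean(full) - mean(thin)), 2 * sem + 0.02 * mean(full))
  }
})
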