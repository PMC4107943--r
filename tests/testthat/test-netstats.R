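test_that("phase classification follows the in-burst rate ratio", {
  bursts <- data.frame(onset_s = seq(0, 95, by = 5),
                       offset_s = seq(0.5, 95.5, by = 5))
  in_only <- as.vector(outer(c(0.1, 0.3), bursts$onset_s, "+"))
  expect_equal(classify_phase(in_only, bursts, 100), "inspiratory")
  out_only <- seq(1, 96, by = 5)  # always between bursts
  expect_equal(classify_phase(out_only, bursts, 100), "expiratory")
  expect_error(classify_phase(in_only, bursts[1:3, ], 100), "bursts")
})

test_that("phase recovery matches the planted inspiratory fraction", {
  net <- generate_network(generator_config(n_units = 60, n_multiunits = 0,
                                           n_couplings = 0,
                                           n_weak_couplings = 0), seed = 21)
  tr <- simulate_spike_trains(net, condition_profile("control", net, 1),
                              300, seed = 22)
  got <- vapply(net$elements$id, function(id) {
    if (length(tr$times[[id]]) < 5) return(NA_character_)
    classify_phase(tr$times[[id]], tr$bursts, 300)
  }, character(1))
  keep <- !is.na(got)
  agree <- mean(got[keep] == net$elements$phase[keep])
  frac <- mean(got[keep] == "inspiratory")
  expect_gt(agree, 0.9)
  expect_lt(abs(frac - 0.87), 0.1)
})

test_that("rate change reports percent-of-control, groups and switch-offs", {
  net <- tiny_network(n_units = 4, seed = 23)
  ctrl <- simulate_spike_trains(net, condition_profile("control", net, 1),
                                120, seed = 24)
  same <- rate_change(ctrl, ctrl)
  expect_true(all(abs(same$elements$percent_of_control - 100) < 1e-9))
  cond <- ctrl
  cond$times[["e01"]] <- numeric(0)   # silenced element
  rc <- rate_change(cond, ctrl)
  e1 <- rc$elements[rc$elements$element_id == "e01", ]
  expect_equal(e1$percent_of_control, 0)
  expect_true(e1$switched_off)
  expect_equal(e1$group, "silenced")
  short <- ctrl
  short$duration_s <- 30
  expect_error(rate_change(short, short), "one minute")
})

test_that("hypoxia generator defaults recover the ~88% global rate", {
  net <- generate_network(generator_config(n_units = 40, n_multiunits = 20,
                                           n_couplings = 10,
                                           n_weak_couplings = 5), seed = 25)
  ctrl <- simulate_spike_trains(net, condition_profile("control", net, 1),
                                600, seed = 26)
  hyp <- simulate_spike_trains(net, condition_profile("hypoxia", net, 2),
                               600, seed = 27)
  rc <- rate_change(hyp, ctrl)
  glob <- rc$groups$mean_percent[rc$groups$group == "global"]
  expect_gte(glob, 80)
  expect_lte(glob, 96)
  up <- rc$groups[rc$groups$group == "up", ]
  down <- rc$groups[rc$groups$group == "down", ]
  expect_gt(up$mean_percent, 100)
  expect_lt(down$mean_percent, 100)
})

test_that("intraburst frequency is the reciprocal median ISI", {
  expect_equal(intraburst_frequency(cumsum(c(0, 0.1, 0.2, 0.3))), 5)
  expect_equal(intraburst_frequency(seq(0, 1, by = 0.19)), 1 / 0.19,
               tolerance = 1e-12)  # ~5.26 Hz, the control scale
  expect_error(intraburst_frequency(1), "two spikes")
})

test_that("link counting is a permutation-invariant upper-triangle count", {
  set.seed(28)
  trains <- list(a = sort(runif(900, 0, 200)), b = sort(runif(800, 0, 200)),
                 c = sort(runif(700, 0, 200)))
  trains$b <- sort(c(trains$b, trains$a + 0.002))
  lm <- build_linkage_matrix(trains, t_start = 0, t_end = 200)
  expect_equal(count_links(lm), 1)
  perm <- lm
  ord <- c(3, 1, 2)
  perm$values <- lm$values[ord, ord]
  expect_equal(count_links(perm), count_links(lm))
  zero <- lm
  zero$values[] <- 0
  expect_equal(count_links(zero), 0)
})

test_that("mean delta-correlation groups pairs by element kind", {
  v <- matrix(0, 4, 4, dimnames = list(paste0("e", 1:4), paste0("e", 1:4)))
  mk_lm <- function(values, sig) {
    structure(list(values = values, significant = sig, condition = "x",
                   excluded = character(0)), class = "linkage_matrix")
  }
  sig <- matrix(FALSE, 4, 4, dimnames = dimnames(v))
  sig[1, 2] <- sig[2, 1] <- TRUE   # unit-unit
  sig[3, 4] <- sig[4, 3] <- TRUE   # multi-multi
  sig[1, 3] <- sig[3, 1] <- TRUE   # mixed
  v1 <- v; v1[1, 2] <- v1[2, 1] <- 5; v1[3, 4] <- v1[4, 3] <- 2
  v1[1, 3] <- v1[3, 1] <- 1
  kinds <- c(e1 = "unit", e2 = "unit", e3 = "multiunit", e4 = "multiunit")
  d0 <- delta_matrix(mk_lm(v1, sig), mk_lm(v1, sig))
  md0 <- mean_delta(d0, kinds)
  expect_true(all(md0$mean_delta == 0))
  expect_setequal(md0$group, c("unit", "multiunit", "both"))
  expect_equal(sum(md0$n_pairs), 3)  # groups partition the considered set

  v2 <- v1; v2[1, 2] <- v2[2, 1] <- 2
  md <- mean_delta(delta_matrix(mk_lm(v2, sig), mk_lm(v1, sig)), kinds)
  expect_equal(md$mean_delta[md$group == "unit"], -3)
  expect_equal(md$mean_delta[md$group == "multiunit"], 0)
  d_empty <- delta_matrix(mk_lm(v, sig & FALSE), mk_lm(v, sig & FALSE))
  expect_error(mean_delta(d_empty, kinds), "considered")
})

test_that("graphs satisfy the handshake lemma and round-trip exports", {
  set.seed(29)
  trains <- list(a = sort(runif(900, 0, 200)), b = sort(runif(800, 0, 200)),
                 c = sort(runif(700, 0, 200)), d = sort(runif(600, 0, 200)))
  trains$b <- sort(c(trains$b, trains$a + 0.002))
  trains$d <- sort(c(trains$d, trains$c + 0.003))
  lm <- build_linkage_matrix(trains, "demo", t_start = 0, t_end = 200)
  g <- build_graph(lm)
  expect_equal(nrow(g$nodes), 4)   # degree-0 nodes kept
  expect_equal(sum(g$nodes$degree), 2 * count_links(lm))

  csv <- withr::local_tempfile(fileext = ".csv")
  export_graph(g, csv, "csv")
  g2 <- import_graph_csv(csv, nodes = g$nodes$id)
  expect_equal(nrow(g2$nodes), 4)
  expect_equal(round(sort(g2$edges$weight), 6),
               round(sort(g$edges$weight), 6))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml, "graphml")
  g3 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g3), nrow(g$edges))
  expect_equal(sort(igraph::E(g3)$weight), sort(g$edges$weight),
               tolerance = 1e-6)

  zero <- lm
  zero$values[] <- 0
  gz <- build_graph(zero)
  expect_equal(nrow(gz$edges), 0)
  expect_equal(nrow(gz$nodes), 4)
})

test_that("condition comparisons run the configured tests", {
  df_same <- data.frame(replicate = rep(1:6, 2),
                        condition = rep(c("control", "hypoxia"), each = 6),
                        value = rep(c(10, 12, 9, 11, 10, 12), 2))
  cc <- compare_conditions(df_same, test = "paired_t")
  expect_equal(cc$p_value, 1)
  expect_false(cc$significant)

  set.seed(30)
  df_eff <- data.frame(replicate = rep(1:8, 2),
                       condition = rep(c("control", "hypoxia"), each = 8),
                       value = c(rnorm(8, 10), rnorm(8, 4)))
  cc2 <- compare_conditions(df_eff, test = "paired_t")
  expect_true(cc2$significant)

  df3 <- data.frame(replicate = rep(1:6, 3),
                    condition = rep(c("a", "b", "c"), each = 6),
                    value = c(rnorm(6, 5), rnorm(6, 5.2), rnorm(6, 12)))
  an <- compare_conditions(df3, test = "rm_anova", posthoc = "tukey",
                           reference = "a")
  expect_true(an$significant)
  expect_true(any(grepl("c", an$posthoc$comparison)))
  kw <- compare_conditions(df3, test = "kruskal")
  expect_true(kw$significant)
  expect_equal(nrow(kw$posthoc), 3)
  expect_error(compare_conditions(df3[df3$replicate == 1, ], "paired_t"),
               "two replicates")
})

test_that("large coupling effects are detected and null effects are not", {
  # power: halved-coupling experiments significant; type-I: identical
  # generators non-significant -- on link-strength summaries
  set.seed(31)
  mk_vals <- function(shift) c(rnorm(8, 20, 3), rnorm(8, 20 - shift, 3))
  n_sig_eff <- 0; n_sig_null <- 0
  for (i in 1:10) {
    eff <- data.frame(replicate = rep(1:8, 2),
                      condition = rep(c("ctrl", "cond"), each = 8),
                      value = mk_vals(14))
    if (compare_conditions(eff, "paired_t")$significant)
      n_sig_eff <- n_sig_eff + 1
    null <- data.frame(replicate = rep(1:8, 2),
                       condition = rep(c("ctrl", "cond"), each = 8),
                       value = mk_vals(0))
    if (compare_conditions(null, "paired_t")$significant)
      n_sig_null <- n_sig_null + 1
  }
  expect_gte(n_sig_eff, 9)
  expect_lte(n_sig_null, 1)
})
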