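#' Classify an element as inspiratory or expiratory
#'
#' Peri-event criterion: an element is inspiratory when its firing rate
#' inside population burst windows exceeds \code{ratio_threshold} times
#' its rate outside them; otherwise it is expiratory (non-inspiratory).
#'
#' @param times_s spike times, seconds.
#' @param bursts data frame of burst windows (\code{onset_s},
#'   \code{offset_s}), e.g. from [detect_population_bursts()] or the
#'   generator's ground truth.
#' @param duration_s total observation length, seconds.
#' @param ratio_threshold in-burst / out-of-burst rate ratio required for
#'   the inspiratory label.
#' @param min_bursts minimum number of bursts required.
#' @return \code{"inspiratory"} or \code{"expiratory"}.
#' @export
classify_phase <- function(times_s, bursts, duration_s,
                           ratio_threshold = 2, min_bursts = 10) {
  if (nrow(bursts) < min_bursts)
    stop(sprintf("need at least %d bursts to classify phase", min_bursts),
         call. = FALSE)
  t_in <- sum(pmin(bursts$offset_s, duration_s) -
                pmin(bursts$onset_s, duration_s))
  t_out <- duration_s - t_in
  if (t_in <= 0 || t_out <= 0)
    stop("burst windows must cover part but not all of the recording",
         call. = FALSE)
  in_burst <- vapply(times_s, function(t)
    any(t >= bursts$onset_s & t < bursts$offset_s), logical(1))
  rate_in <- sum(in_burst) / t_in
  rate_out <- sum(!in_burst) / t_out
  if (rate_out == 0) {
    if (rate_in > 0) "inspiratory" else "expiratory"
  } else if (rate_in > ratio_threshold * rate_out) {
    "inspiratory"
  } else {
    "expiratory"
  }
}

#' Per-element firing-rate change between conditions
#'
#' Expresses each element's rate in the condition window as a percentage
#' of its control rate (control set to 100%), flags elements that
#' switched off (no spikes in the last minute of the condition window),
#' and summarizes the rate-increasing and rate-decreasing subpopulations
#' as mean +/- s.e.m.
#'
#' @param cond,control \code{"spike_train_set"} objects over the same
#'   elements.
#' @param t_start,t_end analysis window applied to both conditions,
#'   seconds; defaults to the full (common) duration, which must be at
#'   least one minute.
#' @return List of class \code{"rate_change"}: \code{elements} (per
#'   element: rates, \code{percent_of_control}, \code{switched_off},
#'   \code{group}) and \code{groups} (mean +/- s.e.m. per up/down
#'   subset plus the global mean).
#' @export
rate_change <- function(cond, control, t_start = 0, t_end = NULL) {
  stopifnot(inherits(cond, "spike_train_set"),
            inherits(control, "spike_train_set"))
  ids <- names(control$times)
  if (!setequal(ids, names(cond$times)))
    stop("element sets differ between conditions", call. = FALSE)
  if (is.null(t_end)) t_end <- min(cond$duration_s, control$duration_s)
  win <- t_end - t_start
  if (win < 60) stop("analysis window must be at least one minute",
                     call. = FALSE)
  rate_in <- function(tt) sum(tt >= t_start & tt < t_end) / win
  r_ctrl <- vapply(control$times[ids], rate_in, numeric(1))
  r_cond <- vapply(cond$times[ids], rate_in, numeric(1))
  off <- vapply(cond$times[ids], function(tt)
    sum(tt >= t_end - 60 & tt < t_end) == 0, logical(1))
  pct <- ifelse(r_ctrl > 0, 100 * r_cond / r_ctrl, NA_real_)
  grp <- ifelse(off, "silenced",
                ifelse(is.na(pct), "undefined",
                       ifelse(pct > 100, "up", "down")))
  el <- data.frame(element_id = ids,
                   kind = control$elements$kind[match(ids, control$elements$id)],
                   phase = control$elements$phase[match(ids, control$elements$id)],
                   rate_control_hz = r_ctrl,
                   rate_cond_hz = r_cond,
                   percent_of_control = pct,
                   switched_off = off,
                   group = grp,
                   stringsAsFactors = FALSE)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  grows <- lapply(c("up", "down"), function(g) {
    x <- el$percent_of_control[el$group == g]
    if (length(x) == 0) return(NULL)
    data.frame(group = g, n = length(x), mean_percent = mean(x),
               sem_percent = if (length(x) > 1) sem(x) else NA_real_)
  })
  all_pct <- el$percent_of_control[!is.na(el$percent_of_control)]
  grows <- c(grows, list(data.frame(
    group = "global", n = length(all_pct), mean_percent = mean(all_pct),
    sem_percent = sem(all_pct))))
  out <- list(elements = el, groups = do.call(rbind, grows),
              condition = cond$condition, reference = control$condition)
  class(out) <- "rate_change"
  out
}

#' @export
print.rate_change <- function(x, ...) {
  cat(sprintf("Rate change: %s vs %s (%d elements)\n",
              x$condition %||% "?", x$reference %||% "?", nrow(x$elements)))
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %-7s n=%3d  %.1f +/- %.1f %% of control\n",
                x$groups$group[i], x$groups$n[i], x$groups$mean_percent[i],
                x$groups$sem_percent[i]))
  if (any(x$elements$switched_off))
    cat(sprintf("  switched off: %d element(s)\n",
                sum(x$elements$switched_off)))
  invisible(x)
}

#' Intraburst frequency from the median inter-spike interval
#'
#' Approximates the intraburst firing frequency of a rhythmic element as
#' the reciprocal of the median inter-spike interval.
#'
#' @param times_s sorted spike times, seconds (at least two spikes).
#' @return Frequency in Hz.
#' @export
#' @examples
#' intraburst_frequency(c(0, 0.1, 0.3, 0.6))  # median ISI 0.2 s -> 5 Hz
intraburst_frequency <- function(times_s) {
  if (length(times_s) < 2)
    stop("need at least two spikes", call. = FALSE)
  1 / stats::median(diff(times_s))
}

#' Number of functional links in a linkage matrix
#'
#' @param matrix a \code{"linkage_matrix"}.
#' @return Count of nonzero upper-triangle entries.
#' @export
count_links <- function(matrix) {
  stopifnot(inherits(matrix, "linkage_matrix"))
  sum(matrix$values[upper.tri(matrix$values)] != 0)
}

#' Mean delta-correlation by element-kind grouping
#'
#' Averages the change in correlation over considered pairs (pairs
#' significant in at least one of the two conditions), grouped by the
#' kinds of the pair's members: \code{"unit"} (both single units),
#' \code{"multiunit"} (both multi-unit), \code{"both"} (mixed pairs).
#' Empty groups are absent from the result.
#'
#' @param delta a [delta_matrix()].
#' @param kinds named character vector mapping element id to
#'   \code{"unit"}/\code{"multiunit"}.
#' @return Data frame: \code{group}, \code{n_pairs}, \code{mean_delta},
#'   \code{sem_delta}.
#' @export
mean_delta <- function(delta, kinds) {
  stopifnot(inherits(delta, "delta_matrix"))
  ids <- rownames(delta$values)
  if (!all(ids %in% names(kinds)))
    stop("kinds must cover every element", call. = FALSE)
  ut <- which(upper.tri(delta$values) & delta$considered, arr.ind = TRUE)
  if (nrow(ut) == 0)
    stop("no considered pairs (nothing significant in either condition)",
         call. = FALSE)
  ka <- kinds[ids[ut[, 1]]]
  kb <- kinds[ids[ut[, 2]]]
  grp <- ifelse(ka == "unit" & kb == "unit", "unit",
                ifelse(ka == "multiunit" & kb == "multiunit",
                       "multiunit", "both"))
  dv <- delta$values[ut]
  rows <- lapply(c("unit", "multiunit", "both"), function(g) {
    x <- dv[grp == g]
    if (length(x) == 0) return(NULL)
    data.frame(group = g, n_pairs = length(x), mean_delta = mean(x),
               sem_delta = if (length(x) > 1)
                 stats::sd(x) / sqrt(length(x)) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Build a weighted functional-connectivity graph
#'
#' Converts a linkage matrix into an undirected weighted graph: a node
#' for every element (including degree-0 elements) and an edge for every
#' nonzero upper-triangle entry, with the correlation value as weight.
#' The conventional display scales node size with degree and edge width
#' with weight.
#'
#' @param matrix a \code{"linkage_matrix"}.
#' @param kinds optional named element-kind vector stored as a node
#'   attribute.
#' @return An object of class \code{"network_graph"}: \code{graph} (an
#'   \code{igraph} object), \code{nodes} (id, degree), \code{edges}
#'   (source, target, weight), \code{condition}.
#' @export
build_graph <- function(matrix, kinds = NULL) {
  stopifnot(inherits(matrix, "linkage_matrix"))
  g <- igraph::graph_from_adjacency_matrix(matrix$values, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  deg <- igraph::degree(g)
  if (!is.null(kinds))
    igraph::V(g)$kind <- unname(kinds[igraph::V(g)$name])
  el <- igraph::as_edgelist(g)
  edges <- data.frame(source = el[, 1], target = el[, 2],
                      weight = igraph::E(g)$weight %||% numeric(0),
                      stringsAsFactors = FALSE)
  out <- list(graph = g,
              nodes = data.frame(id = igraph::V(g)$name, degree = unname(deg),
                                 stringsAsFactors = FALSE),
              edges = edges,
              condition = matrix$condition)
  class(out) <- "network_graph"
  out
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("Functional network (%s): %d nodes, %d links\n",
              x$condition %||% "unlabelled", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
plot.network_graph <- function(x, ...) {
  deg <- x$nodes$degree
  w <- if (nrow(x$edges)) x$edges$weight else numeric(0)
  igraph::plot.igraph(
    x$graph,
    vertex.size = 5 + 10 * deg / max(1, max(deg)),
    edge.width = if (length(w)) 0.5 + 3 * w / max(w) else 1,
    ...)
  invisible(x)
}

#' Export a network graph
#'
#' Writes the graph as GraphML (importable by Cytoscape and igraph) or as
#' an edge-list CSV (\code{source,target,weight}).
#'
#' @param graph a [build_graph()] result.
#' @param path output file path.
#' @param format \code{"graphml"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "csv")) {
  stopifnot(inherits(graph, "network_graph"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph$graph, path, format = "graphml")
  } else {
    utils::write.csv(graph$edges, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read an edge-list CSV back into a network graph
#'
#' @param path an edge-list CSV written by [export_graph()].
#' @param nodes optional character vector of node ids (to preserve
#'   degree-0 elements).
#' @return A \code{"network_graph"}.
#' @export
import_graph_csv <- function(path, nodes = NULL) {
  edges <- utils::read.csv(path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::E(g)$weight <- edges$weight
  out <- list(graph = g,
              nodes = data.frame(id = igraph::V(g)$name,
                                 degree = unname(igraph::degree(g)),
                                 stringsAsFactors = FALSE),
              edges = edges, condition = NULL)
  class(out) <- "network_graph"
  out
}

# Dunn's rank-based post-hoc test after Kruskal-Wallis.
dunn_test <- function(value, group) {
  group <- factor(group)
  n <- length(value)
  r <- rank(value)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_corr
  lev <- levels(group)
  combs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    g1 <- combs[1, k]; g2 <- combs[2, k]
    n1 <- sum(group == g1); n2 <- sum(group == g2)
    z <- (mean(r[group == g1]) - mean(r[group == g2])) /
      sqrt(s2 * (1 / n1 + 1 / n2))
    data.frame(comparison = paste(g1, g2, sep = " - "), z = z,
               p_value = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  out
}

#' Compare a metric across experimental conditions
#'
#' Applies the configured test to replicate-level values of one metric
#' (link counts, mean delta-correlation, firing rates, ...) across
#' conditions: a paired t-test for two paired conditions, a
#' repeated-measures ANOVA (replicate as block) with Tukey or Dunnett
#' post-hoc contrasts for more, or a Kruskal-Wallis test with Dunn's
#' post-hoc for medians.  Significance is accepted at \code{alpha}.
#'
#' @param data data frame with columns \code{replicate},
#'   \code{condition}, \code{value}.
#' @param test \code{"paired_t"}, \code{"rm_anova"} or \code{"kruskal"}.
#' @param posthoc post-hoc family for \code{rm_anova}: \code{"tukey"} or
#'   \code{"dunnett"}.
#' @param reference reference condition (first level; used by Dunnett).
#' @param alpha significance level.
#' @return An object of class \code{"condition_comparison"}: \code{test},
#'   \code{p_value}, \code{significant}, \code{means} (per condition),
#'   \code{posthoc} (data frame or NULL).
#' @export
compare_conditions <- function(data, test = c("paired_t", "rm_anova",
                                              "kruskal"),
                               posthoc = c("tukey", "dunnett"),
                               reference = NULL, alpha = 0.05) {
  test <- match.arg(test)
  posthoc <- match.arg(posthoc)
  stopifnot(all(c("replicate", "condition", "value") %in% names(data)))
  conds <- unique(data$condition)
  if (!is.null(reference))
    conds <- c(reference, setdiff(conds, reference))
  data$condition <- factor(data$condition, levels = conds)
  tab <- table(data$condition)
  if (any(tab < 2))
    stop("need at least two replicates per condition", call. = FALSE)
  means <- stats::aggregate(value ~ condition, data, function(x)
    c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x))))
  means <- data.frame(condition = means$condition,
                      mean = means$value[, "mean"],
                      sem = means$value[, "sem"])
  ph <- NULL
  if (test == "paired_t") {
    if (length(conds) != 2)
      stop("paired t-test requires exactly two conditions", call. = FALSE)
    wide <- stats::reshape(data, idvar = "replicate", timevar = "condition",
                           direction = "wide")
    v1 <- wide[[paste0("value.", conds[1])]]
    v2 <- wide[[paste0("value.", conds[2])]]
    if (anyNA(v1) || anyNA(v2))
      stop("paired test requires every replicate in both conditions",
           call. = FALSE)
    p <- if (stats::sd(v2 - v1) == 0) {
      # no variation in the paired differences: identical replicates
      # give p = 1, a constant nonzero shift p = 0
      if (all(v2 - v1 == 0)) 1 else 0
    } else {
      stats::t.test(v2, v1, paired = TRUE)$p.value
    }
  } else if (test == "rm_anova") {
    data$replicate <- factor(data$replicate)
    fit <- stats::aov(value ~ condition + replicate, data = data)
    p <- summary(fit)[[1]]["condition", "Pr(>F)"]
    mc <- if (posthoc == "tukey") multcomp::mcp(condition = "Tukey")
          else multcomp::mcp(condition = "Dunnett")
    gl <- summary(multcomp::glht(fit, linfct = mc))
    ph <- data.frame(comparison = names(gl$test$coefficients),
                     estimate = unname(gl$test$coefficients),
                     p_adjusted = unname(gl$test$pvalues),
                     stringsAsFactors = FALSE)
  } else {
    ht <- stats::kruskal.test(value ~ condition, data = data)
    p <- ht$p.value
    if (length(conds) > 2) ph <- dunn_test(data$value, data$condition)
  }
  out <- list(test = test, p_value = p, significant = p < alpha,
              alpha = alpha, means = means, posthoc = ph)
  class(out) <- "condition_comparison"
  out
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("Condition comparison (%s): p = %.4g -> %s at alpha = %g\n",
              x$test, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  for (i in seq_len(nrow(x$means)))
    cat(sprintf("  %-20s %.3f +/- %.3f\n", as.character(x$means$condition[i]),
                x$means$mean[i], x$means$sem[i]))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
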