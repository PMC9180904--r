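#' Tie-corrected Mann-Whitney U test
#'
#' Rank-sum test with the normal approximation used for the between-network
#' topology comparison. U is computed from mid-ranks,
#' \eqn{U = R_x - n_x(n_x+1)/2}, standardized as
#' \eqn{Z = (U - n_x n_y/2)/\sigma_U} with the tie-corrected
#' \deqn{\sigma_U = \sqrt{\frac{n_x n_y}{12}\Big[(n+1) -
#'   \frac{\sum_j (t_j^3 - t_j)}{n(n-1)}\Big]}}
#' where \eqn{t_j} are the tie-group sizes over the pooled sample of size
#' \eqn{n = n_x + n_y}. The two-sided p-value comes from the normal
#' approximation without continuity correction. Sign convention: the first
#' sample is the reference, so Z is negative when it is stochastically
#' smaller than the second.
#'
#' @param x,y Numeric samples (NAs dropped); `x` is the reference group.
#' @return A list with `U`, `Z`, `p_value`, `n_x`, `n_y`.
#' @examples
#' mann_whitney(1:3, 4:6)  # U = 0, Z ~ -1.964
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx < 1 || ny < 1 || n < 3) {
    stop("need n_x >= 1, n_y >= 1 and n_x + n_y >= 3", call. = FALSE)
  }
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  var_U <- (nx * ny / 12) * ((n + 1) - tie_term)
  if (var_U <= 0) {
    warning("all values tied across both samples; Z undefined, reported as 0",
            call. = FALSE)
    return(list(U = U, Z = 0, p_value = 1, n_x = nx, n_y = ny))
  }
  Z <- (U - nx * ny / 2) / sqrt(var_U)
  list(U = U, Z = Z, p_value = min(1, 2 * stats::pnorm(-abs(Z))),
       n_x = nx, n_y = ny)
}

#' Effect size r from a standardized statistic
#'
#' \eqn{r = Z/\sqrt{N}}, with N the total number of compared values (e.g.
#' 60 when comparing a node metric across two full 30-node networks, or the
#' pooled subject count for a subject-level comparison). Reported to 2
#' decimals in summaries.
#'
#' @param z Standardized (Z) statistic.
#' @param n_total Total number of observations entering the comparison.
#' @return The effect size (unrounded).
#' @examples
#' round(effect_size_r(2.63, 49), 2)   # 0.38
#' round(effect_size_r(-2.81, 60), 2)  # -0.36
#' @export
effect_size_r <- function(z, n_total) {
  if (any(n_total < 1)) stop("n_total must be at least 1", call. = FALSE)
  z / sqrt(n_total)
}

#' Compare the topology of two correlation networks
#'
#' The dyshomeostasis test: each node metric (degree, neighbourhood
#' connectivity, stress, betweenness, closeness) and the per-edge edge
#' betweenness are compared between the two networks with the tie-corrected
#' Mann-Whitney U test, treating the per-node (per-edge) values of each
#' network as the two samples. Network A is the reference (normotensive)
#' group: negative Z means the metric is larger in network B. The effect
#' size r = Z/sqrt(N) uses N = number of compared values and accompanies
#' significant comparisons only. Nodes with undefined neighbourhood
#' connectivity (isolated nodes) are excluded from that metric's samples.
#'
#' @param net_a Reference `corr_network` (e.g. the normotensive group).
#' @param net_b Comparison `corr_network` (e.g. the hypertensive group).
#' @param metrics Character vector of node metrics to compare; default all
#'   five plus `edge_betweenness`.
#' @param alpha Significance level used for reporting effect sizes.
#' @return An object of class `network_comparison`; see [tidy()] /
#'   [glance()] methods and [render_summary()].
#' @export
compare_networks <- function(net_a, net_b,
                             metrics = c("degree", "neighbourhood_connectivity",
                                         "stress", "betweenness", "closeness",
                                         "edge_betweenness"),
                             alpha = 0.05) {
  if (!identical(sort(net_a$nodes$name), sort(net_b$nodes$name))) {
    stop("networks must share an identical node panel", call. = FALSE)
  }
  node_metric_names <- intersect(
    c("degree", "neighbourhood_connectivity", "stress", "betweenness",
      "closeness"), metrics)
  ma <- mb <- NULL
  if (length(node_metric_names) > 0) {
    ma <- node_metrics_subset(net_a, node_metric_names)
    mb <- node_metrics_subset(net_b, node_metric_names)
  }
  samples <- lapply(node_metric_names, function(m) {
    list(metric = m, a = ma[[m]][!is.na(ma[[m]])], b = mb[[m]][!is.na(mb[[m]])])
  })
  if ("edge_betweenness" %in% metrics) {
    samples <- c(samples, list(list(
      metric = "edge_betweenness",
      a = edge_betweenness_table(net_a)$edge_betweenness,
      b = edge_betweenness_table(net_b)$edge_betweenness
    )))
  }
  rows <- lapply(samples, function(s) {
    if (length(s$a) == 0 || length(s$b) == 0) {
      warning("metric '", s$metric,
              "' undefined for all nodes in a network; skipped", call. = FALSE)
      return(NULL)
    }
    mw <- mann_whitney(s$a, s$b)
    n_tot <- mw$n_x + mw$n_y
    tibble::tibble(
      metric = s$metric,
      mean_a = mean(s$a), sd_a = stats::sd(s$a),
      mean_b = mean(s$b), sd_b = stats::sd(s$b),
      n_a = mw$n_x, n_b = mw$n_y,
      U = mw$U, Z = mw$Z, p_value = mw$p_value,
      r = ifelse(mw$p_value < alpha, effect_size_r(mw$Z, n_tot), NA_real_)
    )
  })
  comparison <- dplyr::bind_rows(rows)
  globals <- dplyr::bind_rows(
    dplyr::mutate(glance.corr_network(net_a), network = "a", .before = 1),
    dplyr::mutate(glance.corr_network(net_b), network = "b", .before = 1)
  )
  structure(list(comparison = comparison,
                 differential_edges = differential_edges(net_a, net_b),
                 globals = globals,
                 alpha = alpha,
                 note = paste("Nodes are treated as independent observations",
                              "within each network; within-network dependence",
                              "is not modelled by the Mann-Whitney comparison.")),
            class = "network_comparison")
}

node_metrics_subset <- function(net, which_metrics) {
  cheap <- c("degree", "neighbourhood_connectivity")
  if (all(which_metrics %in% cheap)) {
    # avoid the all-pairs shortest-path work when only local metrics are
    # needed (the replicated power simulations compare degree and NC only)
    g <- to_igraph(net)
    deg <- igraph::degree(g)
    nc <- if (igraph::ecount(g) > 0) {
      suppressWarnings(igraph::knn(g, weights = NA)$knn)
    } else rep(NaN, igraph::vcount(g))
    nc[deg == 0 | is.nan(nc)] <- NA_real_
    out <- tibble::tibble(node = igraph::V(g)$name,
                          degree = as.integer(deg),
                          neighbourhood_connectivity = unname(nc))
    return(out[, c("node", which_metrics), drop = FALSE])
  }
  nm <- node_metrics(net)
  nm[, intersect(c("node", which_metrics), names(nm)), drop = FALSE]
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}

#' Tidy method for network comparisons
#'
#' @param x A `network_comparison`.
#' @param ... Unused.
#' @return One row per compared metric with means, SDs, U, Z, p and r.
#' @method tidy network_comparison
#' @export
tidy.network_comparison <- function(x, ...) x$comparison

#' Glance method for network comparisons
#'
#' @param x A `network_comparison`.
#' @param ... Unused.
#' @return One row per network: node count, edge count, density, isolated
#'   node count, plus differential-edge counts.
#' @method glance network_comparison
#' @export
glance.network_comparison <- function(x, ...) {
  de <- x$differential_edges
  dplyr::mutate(x$globals,
                n_only_here = c(sum(de$status == "only_a"),
                                sum(de$status == "only_b")),
                n_shared = sum(de$status == "shared"))
}

#' Render a comparison report as text
#'
#' One row per metric in the reporting style "mean +/- SD (A) vs mean +/-
#' SD (B), Z, p, r", with r shown to 2 decimals for significant rows only.
#'
#' @param x A `network_comparison`.
#' @param digits Digits for means/SDs.
#' @return Character vector of report lines.
#' @export
render_summary <- function(x, digits = 2) {
  stopifnot(inherits(x, "network_comparison"))
  comp <- x$comparison
  header <- sprintf("Network topology comparison (A = reference): %d metrics, alpha = %s",
                    nrow(comp), format(x$alpha))
  if (nrow(comp) == 0) return(header)
  fmt <- function(m, s) paste0(round(m, digits), " ± ", round(s, digits))
  lines <- vapply(seq_len(nrow(comp)), function(i) {
    row <- comp[i, ]
    base <- sprintf("%-27s %s vs %s, Z = %.2f, p = %.3g",
                    row$metric, fmt(row$mean_a, row$sd_a),
                    fmt(row$mean_b, row$sd_b), row$Z, row$p_value)
    if (!is.na(row$r)) base <- sprintf("%s, r = %.2f", base, row$r)
    base
  }, "")
  de <- x$differential_edges
  c(header, lines,
    sprintf("Edges: %d only in A, %d only in B, %d shared",
            sum(de$status == "only_a"), sum(de$status == "only_b"),
            sum(de$status == "shared")))
}
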