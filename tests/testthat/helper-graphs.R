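# Small graph fixtures and oracle-based metric counters, built in code.

# corr_network from an edge list over named nodes (dummy correlation attrs)
test_network <- function(nodes, edges_from = character(), edges_to = character(),
                         rho = NULL) {
  n_e <- length(edges_from)
  if (is.null(rho)) rho <- rep(0.5, n_e)
  edges <- tibble::tibble(
    from = edges_from, to = edges_to, rho = rho,
    p = rep(0.01, n_e),
    sign = ifelse(rho >= 0, "positive", "negative"),
    weight = abs(rho)
  )
  diffcornet:::new_corr_network(
    tibble::tibble(name = nodes, category = NA_character_), edges, alpha = 0.05)
}

path_net <- function() test_network(c("A", "B", "C"), c("A", "B"), c("B", "C"))
star_net <- function() test_network(c("c", "l1", "l2", "l3"),
                                    rep("c", 3), c("l1", "l2", "l3"))
cycle4_net <- function() test_network(c("a", "b", "c", "d"),
                                      c("a", "b", "c", "d"),
                                      c("b", "c", "d", "a"))
complete_net <- function(n) {
  nodes <- paste0("v", seq_len(n))
  pr <- t(utils::combn(nodes, 2))
  test_network(nodes, pr[, 1], pr[, 2])
}

random_er_network <- function(n, p_edge) {
  nodes <- paste0("n", seq_len(n))
  pr <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pr)) < p_edge
  test_network(nodes, pr[keep, 1], pr[keep, 2])
}

# Metric values recomputed from the exhaustive geodesic list, fully
# independent of the accumulation algorithms under test.
oracle_metrics <- function(net) {
  paths <- geodesic_oracle(net)
  nodes <- net$nodes$name
  stress <- stats::setNames(numeric(length(nodes)), nodes)
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  eb_count <- list()
  eb_frac <- list()
  if (length(paths) > 0) {
    pair_of <- vapply(paths, function(p) paste(p[1], p[length(p)]), "")
    for (pair in unique(pair_of)) {
      pp <- paths[pair_of == pair]
      npaths <- length(pp)
      for (p in pp) {
        interior <- p[-c(1, length(p))]
        stress[interior] <- stress[interior] + 1
        btw[interior] <- btw[interior] + 1 / npaths
        for (i in seq_len(length(p) - 1)) {
          k <- ekey(p[i], p[i + 1])
          eb_count[[k]] <- (eb_count[[k]] %||% 0) + 1
          eb_frac[[k]] <- (eb_frac[[k]] %||% 0) + 1 / npaths
        }
      }
    }
  }
  list(stress = stress, betweenness = btw,
       edge_count = unlist(eb_count), edge_frac = unlist(eb_frac))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-variable panel for copula calibration checks
two_var_structure <- function(rho_s) {
  panel <- default_panel()[c(27, 13), ]  # age (truncated-normal), BMI
  correlation_structure(panel, matrix(c(1, rho_s, rho_s, 1), 2))
}
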