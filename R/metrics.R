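#' Node topology metrics
#'
#' Computes, per node of the correlation network, the metrics used in the
#' between-network topology comparison. All shortest-path quantities are
#' computed on the unweighted graph (edge weights |rho| are carried for
#' export/layout only), matching the NetworkAnalyzer-style conventions:
#'
#' * `degree` — number of incident edges;
#' * `neighbourhood_connectivity` — mean degree of the node's neighbours,
#'   undefined (`NA`) for isolated nodes;
#' * `stress` — number of distinct geodesics, over all unordered vertex
#'   pairs, that pass through the node as an interior vertex (an integer
#'   path count, not a fraction);
#' * `betweenness` — standard shortest-path betweenness (sum of geodesic
#'   fractions), unnormalized by default;
#' * `closeness` — (number of other nodes reachable) / (sum of distances to
#'   them), i.e. reciprocal mean distance within the node's connected
#'   component, in \[0, 1\]; 0 for isolated nodes.
#'
#' @param net A `corr_network` or igraph graph.
#' @param normalized_betweenness Divide betweenness by (n-1)(n-2)/2.
#' @return Tibble with one row per node: `node`, `category` (if available),
#'   and the five metrics above.
#' @examples
#' cs <- correlation_structure(default_panel(), diag(30))
#' net <- build_network(correlation_matrix(sample_group(cs, 30, seed = 1)))
#' node_metrics(net)
#' @export
node_metrics <- function(net, normalized_betweenness = FALSE) {
  g <- to_igraph(net)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  nc <- if (igraph::ecount(g) > 0) {
    suppressWarnings(igraph::knn(g, weights = NA)$knn)
  } else {
    rep(NaN, n)
  }
  nc[deg == 0] <- NA_real_
  nc[is.nan(nc)] <- NA_real_
  btw <- igraph::betweenness(g, weights = NA,
                             normalized = normalized_betweenness)
  d <- igraph::distances(g, weights = NA)
  cls <- apply(d, 1, function(row) {
    reach <- is.finite(row) & row > 0
    if (!any(reach)) 0 else sum(reach) / sum(row[reach])
  })
  out <- tibble::tibble(
    node = igraph::V(g)$name,
    degree = as.integer(deg),
    neighbourhood_connectivity = unname(nc),
    stress = unname(stress_centrality(g)),
    betweenness = unname(btw),
    closeness = unname(cls)
  )
  if (!is.null(igraph::vertex_attr(g, "category"))) {
    out <- tibble::add_column(out, category = igraph::V(g)$category,
                              .after = "node")
  }
  out
}

#' Stress centrality by geodesic path counting
#'
#' For each node v, counts every distinct shortest path — over all unordered
#' vertex pairs \{s, t\} with s != v != t — that contains v as an interior
#' vertex. Each geodesic is counted once (not a fraction of geodesics as in
#' betweenness). Path counts are accumulated from powers of the adjacency
#' matrix: the number of geodesics between s and t at distance k equals the
#' (s, t) entry of A^k, since every walk whose length equals the graph
#' distance is necessarily a simple shortest path; a geodesic from s to t
#' passes through v iff d(s, v) + d(v, t) = d(s, t), contributing
#' sigma(s, v) * sigma(v, t) paths.
#'
#' @param net A `corr_network` or igraph graph.
#' @return Integer vector of stress values, named by node.
#' @export
stress_centrality <- function(net) {
  g <- to_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0) return(integer(0))
  cnt <- geodesic_counts(g)
  sigma <- cnt$sigma
  d <- cnt$d
  stress <- integer(n)
  for (v in seq_len(n)) {
    dv <- d[, v]
    through <- outer(dv, dv, "+") == d & is.finite(d) & d > 0
    through[v, ] <- FALSE
    through[, v] <- FALSE
    paths <- sigma[, v] %o% sigma[v, ]
    stress[v] <- sum(paths[through]) / 2  # unordered pairs
  }
  stats::setNames(as.integer(stress), igraph::V(g)$name)
}

# All-pairs geodesic counts sigma and distance matrix d (unweighted).
geodesic_counts <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g, weights = NA)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  sigma <- diag(1, n)
  dimnames(sigma) <- dimnames(d)
  finite <- d[is.finite(d)]
  maxd <- if (length(finite)) max(finite) else 0
  Ak <- diag(1, n)
  for (k in seq_len(maxd)) {
    Ak <- Ak %*% A
    at_k <- which(d == k)
    sigma[at_k] <- Ak[at_k]
  }
  list(sigma = sigma, d = d)
}

#' Edge betweenness
#'
#' Shortest-path load on each edge. The default (`variant = "fraction"`)
#' is the standard definition: the sum over vertex pairs of the fraction of
#' their geodesics that use the edge. `variant = "count"` instead counts
#' every geodesic crossing the edge once — the literal "number of shortest
#' paths between vertices that contain the edge".
#'
#' @param net A `corr_network` or igraph graph.
#' @param variant `"fraction"` (default) or `"count"`.
#' @return Tibble with columns `from`, `to`, `edge_betweenness`.
#' @export
edge_betweenness_table <- function(net, variant = c("fraction", "count")) {
  variant <- match.arg(variant)
  g <- to_igraph(net)
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          edge_betweenness = numeric()))
  }
  if (variant == "fraction") {
    eb <- igraph::edge_betweenness(g, weights = NA, directed = FALSE)
  } else {
    cnt <- geodesic_counts(g)
    sigma <- cnt$sigma; d <- cnt$d
    u <- match(el[, 1], rownames(d)); v <- match(el[, 2], rownames(d))
    eb <- vapply(seq_len(nrow(el)), function(e) {
      uu <- u[e]; vv <- v[e]
      # geodesics s..t using edge (uu, vv) in either orientation
      use <- outer(d[, uu], d[vv, ], "+") + 1 == d & is.finite(d)
      paths <- sigma[, uu] %o% sigma[vv, ]
      tot <- sum(paths[use])
      use2 <- outer(d[, vv], d[uu, ], "+") + 1 == d & is.finite(d)
      paths2 <- sigma[, vv] %o% sigma[uu, ]
      (tot + sum(paths2[use2])) / 2
    }, 0)
  }
  tibble::tibble(from = el[, 1], to = el[, 2], edge_betweenness = unname(eb))
}

to_igraph <- function(net) {
  if (inherits(net, "igraph")) {
    g <- net
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
    g
  } else if (inherits(net, "corr_network")) {
    as_igraph(net)
  } else {
    stop("expected a corr_network or igraph object", call. = FALSE)
  }
}

#' Exhaustively enumerate all geodesics of a small graph
#'
#' Test oracle: lists every shortest path between every unordered pair of
#' connected vertices, by depth-first expansion of the BFS distance field.
#' Refuses graphs above 12 nodes (the enumeration is exponential and only
#' meant to verify the accumulation algorithms on small cases).
#'
#' @param net A `corr_network` or igraph graph with at most 12 nodes.
#' @return A list of character vectors, each a node sequence of one
#'   geodesic (paths of length >= 1 edge; each unordered pair listed once,
#'   from the lexicographically smaller endpoint).
#' @export
geodesic_oracle <- function(net) {
  g <- to_igraph(net)
  n <- igraph::vcount(g)
  if (n > 12) stop("geodesic_oracle is capped at 12 nodes", call. = FALSE)
  d <- igraph::distances(g, weights = NA)
  nms <- igraph::V(g)$name
  adj <- lapply(seq_len(n), function(v) {
    as.integer(igraph::neighbors(g, v))
  })
  paths <- list()
  extend <- function(path, target) {
    last <- path[length(path)]
    if (last == target) {
      paths[[length(paths) + 1]] <<- nms[path]
      return(invisible(NULL))
    }
    for (w in adj[[last]]) {
      if (is.finite(d[w, target]) && d[last, target] == d[w, target] + 1) {
        extend(c(path, w), target)
      }
    }
  }
  ord <- order(nms)
  for (si in seq_len(n)) {
    for (ti in seq_len(n)) {
      s <- ord[si]; t <- ord[ti]
      if (si < ti && is.finite(d[s, t]) && d[s, t] >= 1) extend(s, t)
    }
  }
  paths
}
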