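#' Export a correlation network
#'
#' Writers for the formats Cytoscape and other network tools consume:
#'
#' * `write_network_graphml()` — GraphML with node attributes `name` and
#'   `category` and edge attributes `rho`, `p`, `sign`, `weight` (weight =
#'   |rho|, the layout input for force-directed algorithms);
#' * `write_network_sif()` — simple interaction format, interaction type
#'   `pos_corr` / `neg_corr`, isolated nodes listed on their own line;
#' * `write_edge_csv()` — flat edge-list CSV.
#'
#' `read_network_graphml()` reloads a GraphML export into a `corr_network`
#' equal (nodes, edges, attributes) to the exported object.
#'
#' @param net A `corr_network`.
#' @param path Output file path.
#' @return The path, invisibly (readers return a `corr_network`).
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "corr_network"))
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble::tibble(
    name = igraph::V(g)$name,
    category = if (!is.null(igraph::vertex_attr(g, "category"))) {
      igraph::V(g)$category
    } else NA_character_
  )
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(
    from = el[, 1], to = el[, 2],
    rho = igraph::E(g)$rho, p = igraph::E(g)$p,
    sign = igraph::E(g)$sign, weight = igraph::E(g)$weight
  )
  new_corr_network(nodes, edges)
}

#' @rdname write_network_graphml
#' @export
write_network_sif <- function(net, path) {
  stopifnot(inherits(net, "corr_network"))
  interaction <- ifelse(net$edges$sign == "positive", "pos_corr", "neg_corr")
  lines <- paste(net$edges$from, interaction, net$edges$to, sep = "\t")
  isolated <- setdiff(net$nodes$name, c(net$edges$from, net$edges$to))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_edge_csv <- function(net, path) {
  stopifnot(inherits(net, "corr_network"))
  utils::write.csv(net$edges, path, row.names = FALSE)
  invisible(path)
}

#' Write node metrics as CSV
#'
#' @param metrics Tibble from [node_metrics()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_node_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a scenario to / from YAML
#'
#' The scenario file stores both groups (name, size, panel with marginals,
#' target Spearman matrix), the missingness rate and the master seed, so a
#' synthetic study is fully reproducible from its config.
#'
#' @param config A `scenario_config`.
#' @param path YAML file path.
#' @return `write_scenario_yaml()` the path invisibly;
#'   `read_scenario_yaml()` a `scenario_config`.
#' @export
write_scenario_yaml <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  ser_group <- function(g) {
    pnl <- g$structure$panel
    list(
      name = g$name, n = g$n,
      panel = lapply(seq_len(nrow(pnl)), function(i) {
        c(list(name = pnl$name[i], label = pnl$label[i],
               category = pnl$category[i], units = pnl$units[i]),
          list(marginal = pnl$marginal[[i]]))
      }),
      target_spearman = apply(g$structure$target_spearman, 1, as.numeric,
                              simplify = FALSE)
    )
  }
  yaml::write_yaml(list(group_a = ser_group(config$group_a),
                        group_b = ser_group(config$group_b),
                        missing_rate = config$missing_rate,
                        seed = config$seed),
                   path, precision = 17)  # 17 sig. digits: exact double round-trip
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  de_group <- function(g) {
    panel <- tibble::tibble(
      name = vapply(g$panel, `[[`, "", "name"),
      label = vapply(g$panel, `[[`, "", "label"),
      category = vapply(g$panel, `[[`, "", "category"),
      units = vapply(g$panel, `[[`, "", "units"),
      marginal = lapply(g$panel, `[[`, "marginal")
    )
    m <- do.call(rbind, lapply(g$target_spearman, as.numeric))
    list(name = g$name, n = as.integer(g$n),
         structure = correlation_structure(panel, m))
  }
  scenario_config(de_group(raw$group_a), de_group(raw$group_b),
                  missing_rate = raw$missing_rate, seed = raw$seed)
}
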