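#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of mid-ranks (average ranks for ties) after
#' pairwise-complete filtering. A constant vector has no defined rank
#' correlation and yields `NA` (no edge can be formed from it).
#'
#' @param x,y Paired numeric vectors.
#' @return Coefficient in \[-1, 1\], or `NA` if fewer than 4 complete pairs
#'   or either vector is constant.
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(rank(x), rank(y), method = "pearson")
}

#' Two-sided p-value for a Spearman coefficient
#'
#' Uses the t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on
#' \eqn{n - 2} degrees of freedom; \eqn{|\rho| = 1} gives p = 0.
#'
#' @param rho Spearman coefficient in \[-1, 1\] (NA gives NA).
#' @param n Number of complete pairs (>= 4).
#' @return Two-sided p-value.
#' @examples
#' spearman_pvalue(0.8, 5)  # ~0.104
#' @export
spearman_pvalue <- function(rho, n) {
  if (any(n < 4, na.rm = TRUE)) stop("n must be at least 4", call. = FALSE)
  out <- rep(NA_real_, length(rho))
  n <- rep(n, length.out = length(rho))
  exact <- !is.na(rho) & abs(rho) >= 1 - 1e-12
  out[exact] <- 0
  mid <- !is.na(rho) & !exact
  tval <- rho[mid] * sqrt((n[mid] - 2) / (1 - rho[mid]^2))
  out[mid] <- 2 * stats::pt(-abs(tval), df = n[mid] - 2)
  out
}

#' All pairwise Spearman correlations of a cohort
#'
#' Computes the symmetric matrices of Spearman coefficients, two-sided
#' p-values and pairwise-complete observation counts over every non-grouping
#' numeric column. Pairs with fewer than 4 complete observations, and any
#' pair involving a constant column, are flagged missing (`NA`) with a
#' message.
#'
#' @param table Cohort tibble (a `group` column is ignored).
#' @return An object of class `correlation_result` with elements `rho`, `p`
#'   and `n` (named symmetric matrices; unit diagonal for `rho`, zero for
#'   `p`).
#' @export
correlation_matrix <- function(table) {
  m <- as.matrix(dplyr::select(tibble::as_tibble(table),
                               -dplyr::any_of("group")))
  storage.mode(m) <- "double"
  p <- ncol(m)
  if (p < 2) stop("need at least two variables", call. = FALSE)
  npairs <- crossprod(!is.na(m))
  constant <- apply(m, 2, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                      all(is.na(v)))
  rho <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  rho[npairs < 4] <- NA
  rho[constant, ] <- NA
  rho[, constant] <- NA
  diag(rho) <- ifelse(constant, NA, 1)
  if (any(constant)) {
    message("constant column(s) flagged missing: ",
            paste(colnames(m)[constant], collapse = ", "))
  }
  if (any(npairs[upper.tri(npairs)] < 4)) {
    message(sum(npairs[upper.tri(npairs)] < 4),
            " pair(s) with fewer than 4 complete observations flagged missing")
  }
  pv <- matrix(NA_real_, p, p, dimnames = dimnames(rho))
  ut <- upper.tri(rho)
  ok <- ut & !is.na(rho) & npairs >= 4
  pv[ok] <- spearman_pvalue(rho[ok], pmax(npairs[ok], 4))
  pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
  diag(pv) <- ifelse(constant, NA, 0)
  structure(list(rho = rho, p = pv, n = npairs), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  p <- ncol(x$rho)
  cat("<correlation_result> ", p, " variables, ", p * (p - 1) / 2,
      " pairs\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a correlation result into one row per variable pair
#'
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @return Tibble with columns `var1`, `var2`, `rho`, `p_value`, `n`.
#' @method tidy correlation_result
#' @export
tidy.correlation_result <- function(x, ...) {
  ut <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    var1 = rownames(x$rho)[ut[, 1]],
    var2 = colnames(x$rho)[ut[, 2]],
    rho = x$rho[ut],
    p_value = x$p[ut],
    n = as.integer(x$n[ut])
  )
}

#' Build the significance-thresholded correlation network
#'
#' Nodes are the full variable panel — variables without any significant
#' correlation stay in the network as isolated nodes, so both group
#' networks always have the same node count. An undirected edge joins two
#' variables iff the two-sided p-value of their Spearman correlation is
#' strictly below `alpha`; each edge carries the coefficient, its p-value,
#' a sign (`positive`/`negative`) and weight = |rho|. Optionally p-values
#' are Benjamini-Hochberg adjusted across all pairs before thresholding.
#'
#' @param corr A `correlation_result`.
#' @param alpha Edge significance threshold in (0, 1), default 0.05.
#' @param panel Optional panel tibble supplying node categories (matched by
#'   name; defaults to [default_panel()] categories where names match).
#' @param adjust `"none"` (default: raw p thresholding) or `"BH"`.
#' @return An object of class `corr_network`: a list with tibbles `nodes`
#'   (`name`, `category`) and `edges` (`from`, `to`, `rho`, `p`, `sign`,
#'   `weight`).
#' @export
build_network <- function(corr, alpha = 0.05, panel = NULL, adjust = c("none", "BH")) {
  stopifnot(inherits(corr, "correlation_result"))
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  vars <- colnames(corr$rho)
  if (is.null(panel)) panel <- default_panel()
  cat_lookup <- stats::setNames(panel$category, panel$name)
  nodes <- tibble::tibble(
    name = vars,
    category = unname(cat_lookup[vars])
  )
  ut <- which(upper.tri(corr$rho), arr.ind = TRUE)
  pv <- corr$p[ut]
  if (adjust == "BH") pv <- stats::p.adjust(pv, method = "BH")
  keep <- !is.na(pv) & pv < alpha
  edges <- tibble::tibble(
    from = vars[ut[keep, 1]],
    to = vars[ut[keep, 2]],
    rho = corr$rho[ut][keep],
    p = pv[keep],
    sign = ifelse(corr$rho[ut][keep] >= 0, "positive", "negative"),
    weight = abs(corr$rho[ut][keep])
  )
  new_corr_network(nodes, edges, alpha = alpha)
}

new_corr_network <- function(nodes, edges, alpha = NA_real_) {
  stopifnot(!anyDuplicated(nodes$name), all(edges$from != edges$to))
  structure(list(nodes = nodes, edges = edges, alpha = alpha),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat("<corr_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (alpha=", format(x$alpha), ")\n", sep = "")
  invisible(x)
}

#' Convert a correlation network to an igraph object
#'
#' @param net A `corr_network`.
#' @return An undirected igraph graph with node attributes `name`,
#'   `category` and edge attributes `rho`, `p`, `sign`, `weight`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "corr_network"))
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges),
    directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
}

#' @method tidy corr_network
#' @export
tidy.corr_network <- function(x, ...) x$edges

#' @method glance corr_network
#' @export
glance.corr_network <- function(x, ...) {
  n <- nrow(x$nodes)
  tibble::tibble(
    n_nodes = n,
    n_edges = nrow(x$edges),
    density = if (n > 1) nrow(x$edges) / (n * (n - 1) / 2) else NA_real_,
    n_isolated = n - length(unique(c(x$edges$from, x$edges$to))),
    alpha = x$alpha
  )
}

#' Partition the edges of two networks over the same panel
#'
#' Classifies the union of the two edge sets into edges present only in
#' network A, only in network B, and shared — the basis of the qualitative
#' between-network comparison (e.g. a pulse-pressure-vaspin link present in
#' the hypertensive network only).
#'
#' @param net_a,net_b `corr_network` objects over identical node panels.
#' @return Tibble with columns `from`, `to`, `status`
#'   (`only_a`/`only_b`/`shared`), `rho_a`, `rho_b`; the three statuses are
#'   disjoint and cover the edge union.
#' @export
differential_edges <- function(net_a, net_b) {
  if (!identical(sort(net_a$nodes$name), sort(net_b$nodes$name))) {
    stop("networks must share an identical node panel", call. = FALSE)
  }
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "\r")
  ea <- net_a$edges; eb <- net_b$edges
  ka <- key(ea); kb <- key(eb)
  all_keys <- union(ka, kb)
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  tibble::tibble(
    from = parts[, 1],
    to = parts[, 2],
    status = dplyr::case_when(
      all_keys %in% ka & all_keys %in% kb ~ "shared",
      all_keys %in% ka ~ "only_a",
      TRUE ~ "only_b"
    ),
    rho_a = ea$rho[match(all_keys, ka)],
    rho_b = eb$rho[match(all_keys, kb)]
  )
}
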