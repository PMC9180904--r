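test_that("metrics on the 3-path match hand enumeration", {
  m <- node_metrics(path_net())
  m <- m[match(c("A", "B", "C"), m$node), ]
  expect_equal(m$degree, c(1L, 2L, 1L))
  expect_equal(m$neighbourhood_connectivity, c(2, 1, 2))
  expect_equal(m$stress, c(0L, 1L, 0L))
  expect_equal(m$betweenness, c(0, 1, 0))
  expect_equal(m$closeness, c(2 / 3, 1, 2 / 3))
  eb <- edge_betweenness_table(path_net())
  expect_equal(eb$edge_betweenness, c(2, 2))
})

test_that("metrics on the star match the definitions", {
  m <- node_metrics(star_net())
  centre <- m[m$node == "c", ]
  leaves <- m[m$node != "c", ]
  expect_equal(centre$degree, 3L)
  expect_equal(centre$neighbourhood_connectivity, 1)
  expect_equal(leaves$neighbourhood_connectivity, rep(3, 3))
  expect_equal(centre$stress, 3L)  # one geodesic per leaf pair
  expect_equal(centre$closeness, 1)
  expect_equal(leaves$stress, rep(0L, 3))
})

test_that("metrics on the 4-cycle match exhaustive enumeration", {
  m <- node_metrics(cycle4_net())
  expect_equal(m$stress, rep(1L, 4))
  expect_equal(m$betweenness, rep(0.5, 4))
  expect_equal(m$neighbourhood_connectivity, rep(2, 4))  # 2-regular
})

test_that("complete graphs have flat centralities", {
  m <- node_metrics(complete_net(5))
  expect_equal(m$degree, rep(4L, 5))
  expect_equal(m$betweenness, rep(0, 5))
  expect_equal(m$stress, rep(0L, 5))
  eb <- edge_betweenness_table(complete_net(4))
  expect_equal(eb$edge_betweenness, rep(1, 6))
  single <- test_network(c("a", "b"), "a", "b")
  expect_equal(edge_betweenness_table(single)$edge_betweenness, 1)
})

test_that("isolated nodes get zero centralities and undefined connectivity", {
  net <- test_network(c("a", "b", "lonely"), "a", "b")
  m <- node_metrics(net)
  lone <- m[m$node == "lonely", ]
  expect_equal(lone$degree, 0L)
  expect_true(is.na(lone$neighbourhood_connectivity))
  expect_equal(lone$stress, 0L)
  expect_equal(lone$betweenness, 0)
  expect_equal(lone$closeness, 0)
})

test_that("degrees satisfy the handshake lemma on random graphs", {
  set.seed(61)
  for (i in 1:20) {
    net <- random_er_network(sample(4:12, 1), runif(1, 0.2, 0.7))
    expect_equal(sum(node_metrics(net)$degree), 2 * nrow(net$edges))
  }
})

test_that("accumulation metrics equal the geodesic enumeration oracle", {
  set.seed(62)
  for (i in 1:30) {
    net <- random_er_network(sample(4:10, 1), runif(1, 0.2, 0.6))
    m <- node_metrics(net)
    om <- oracle_metrics(net)
    expect_identical(m$stress, unname(as.integer(om$stress[m$node])))
    expect_equal(m$betweenness, unname(om$betweenness[m$node]), tolerance = 1e-10)
    eb_f <- edge_betweenness_table(net)
    eb_c <- edge_betweenness_table(net, variant = "count")
    if (nrow(eb_f) > 0) {
      k <- paste(pmin(eb_f$from, eb_f$to), pmax(eb_f$from, eb_f$to), sep = "|")
      expect_equal(eb_f$edge_betweenness, unname(om$edge_frac[k]), tolerance = 1e-10)
      expect_equal(eb_c$edge_betweenness, unname(om$edge_count[k]), tolerance = 1e-10)
    }
  }
})

test_that("stress equals betweenness on trees (unique geodesics) and dominates otherwise", {
  set.seed(63)
  for (i in 1:10) {
    g <- igraph::sample_tree(sample(4:10, 1))
    igraph::V(g)$name <- paste0("t", seq_len(igraph::vcount(g)))
    el <- igraph::as_edgelist(g)
    net <- test_network(igraph::V(g)$name, el[, 1], el[, 2])
    m <- node_metrics(net)
    expect_equal(as.numeric(m$stress), m$betweenness, tolerance = 1e-10)
  }
  for (i in 1:10) {
    net <- random_er_network(8, 0.4)
    m <- node_metrics(net)
    expect_true(all(m$stress - m$betweenness >= -1e-10))
  }
})

test_that("metrics are equivariant under node relabelling", {
  set.seed(64)
  net <- random_er_network(9, 0.4)
  perm <- sample(net$nodes$name)
  relabel <- stats::setNames(paste0("R", seq_along(perm)), perm)
  net2 <- test_network(unname(relabel[net$nodes$name]),
                       unname(relabel[net$edges$from]),
                       unname(relabel[net$edges$to]))
  m1 <- node_metrics(net)
  m2 <- node_metrics(net2)
  m2 <- m2[match(unname(relabel[m1$node]), m2$node), ]
  for (col in c("degree", "neighbourhood_connectivity", "stress",
                "betweenness", "closeness")) {
    expect_equal(m2[[col]], m1[[col]], tolerance = 1e-10)
  }
})

test_that("the geodesic oracle enumerates paths exactly and enforces its cap", {
  paths <- geodesic_oracle(path_net())
  canon <- sort(vapply(paths, paste, "", collapse = "-"))
  expect_equal(canon, c("A-B", "A-B-C", "B-C"))
  cyc <- geodesic_oracle(cycle4_net())
  opposite <- Filter(function(p) {
    (p[1] == "a" && p[length(p)] == "c") || (p[1] == "b" && p[length(p)] == "d")
  }, cyc)
  expect_equal(length(opposite), 4)  # two geodesics for each opposite pair
  lonely <- test_network(c("a", "b", "z"), "a", "b")
  expect_false(any(vapply(geodesic_oracle(lonely), function(p) "z" %in% p, TRUE)))
  expect_error(geodesic_oracle(complete_net(13)), "12 nodes")
})
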