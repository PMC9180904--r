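test_that("spearman_rho matches the rank-correlation definition", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 0.8)  # 1 - 6*4/(5*24)
  expect_true(is.na(spearman_rho(rep(2, 10), 1:10)))      # constant vector
  expect_true(is.na(spearman_rho(c(1, 2, NA, NA, NA), c(1, 2, 3, 4, 5))))
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40)
  base <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), base)
  expect_equal(spearman_rho(x, y^3), base)
  expect_equal(spearman_rho(-x, y), -base)
})

test_that("spearman_pvalue follows the two-sided t approximation", {
  expect_equal(spearman_pvalue(0, 20), 1)
  expect_equal(spearman_pvalue(1, 10), 0)
  expect_equal(spearman_pvalue(-1, 10), 0)
  expect_equal(spearman_pvalue(0.8, 5), 0.104088, tolerance = 1e-5)
  expect_error(spearman_pvalue(0.5, 3), "at least 4")
})

test_that("correlation_matrix is symmetric with correct pairwise-complete counts", {
  set.seed(12)
  tab <- tibble::tibble(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  tab$b[1:5] <- NA
  res <- correlation_matrix(tab)
  expect_equal(res$rho, t(res$rho))
  expect_equal(res$p, t(res$p))
  expect_equal(unname(res$n["a", "b"]), 25)
  expect_equal(unname(res$n["a", "c"]), 30)
  expect_equal(unname(diag(res$rho)), rep(1, 3))
  expect_equal(unname(diag(res$p)), rep(0, 3))
})

test_that("duplicated columns correlate perfectly and constants are flagged", {
  tab <- tibble::tibble(a = rnorm(20), b = 0, c = 1:20)
  tab$d <- tab$a
  expect_message(res <- correlation_matrix(tab), "constant")
  expect_equal(unname(res$rho["a", "d"]), 1)
  expect_true(all(is.na(res$rho["b", ])))
  expect_true(all(is.na(res$rho[, "b"])))
})

test_that("correlation_matrix equals Pearson on mid-ranks (oracle equivalence)", {
  set.seed(8)
  m <- matrix(rnorm(150), 30, 5)
  m[, 3] <- round(m[, 3])  # induce ties
  res <- correlation_matrix(tibble::as_tibble(as.data.frame(m)))
  oracle <- stats::cor(apply(m, 2, rank))
  expect_equal(unname(res$rho), unname(oracle), tolerance = 1e-12)
})

test_that("network construction thresholds p strictly below alpha and keeps all nodes", {
  panel <- default_panel()
  rho <- diag(30); dimnames(rho) <- list(panel$name, panel$name)
  p <- matrix(1, 30, 30, dimnames = dimnames(rho)); diag(p) <- 0
  n <- matrix(49, 30, 30, dimnames = dimnames(rho))
  corr <- structure(list(rho = rho, p = p, n = n), class = "correlation_result")
  net <- build_network(corr, alpha = 0.05, panel = panel)
  expect_equal(nrow(net$nodes), 30)
  expect_equal(nrow(net$edges), 0)

  p["sBP", "dBP"] <- p["dBP", "sBP"] <- 0.04
  rho["sBP", "dBP"] <- rho["dBP", "sBP"] <- -0.4
  p["MMSE", "MoCA"] <- p["MoCA", "MMSE"] <- 0.2
  corr2 <- structure(list(rho = rho, p = p, n = n), class = "correlation_result")
  net2 <- build_network(corr2, alpha = 0.05, panel = panel)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$sign, "negative")
  expect_equal(net2$edges$weight, 0.4)
  # p exactly at alpha is excluded (strict inequality)
  net3 <- build_network(corr2, alpha = 0.04, panel = panel)
  expect_equal(nrow(net3$edges), 0)
})

test_that("edge count is monotone non-decreasing in alpha", {
  set.seed(91)
  cs <- correlation_structure(default_panel(), diag(30))
  corr <- correlation_matrix(sample_group(cs, 49, seed = 14))
  counts <- vapply(c(0.01, 0.05, 0.2, 0.5),
                   function(a) nrow(build_network(corr, alpha = a)$edges), 0L)
  expect_true(all(diff(counts) >= 0))
  edges_small <- build_network(corr, alpha = 0.01)$edges
  edges_big <- build_network(corr, alpha = 0.05)$edges
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(edges_small) %in% key(edges_big)))
})

test_that("BH-adjusted mode is at most as permissive as raw thresholding", {
  cs <- correlation_structure(default_panel(), diag(30))
  corr <- correlation_matrix(sample_group(cs, 49, seed = 15))
  expect_lte(nrow(build_network(corr, adjust = "BH")$edges),
             nrow(build_network(corr)$edges))
})

test_that("differential edges partition the union of edge sets", {
  a <- test_network(c("PP", "vaspin", "MMSE"), c("PP", "MMSE"), c("vaspin", "PP"))
  b <- test_network(c("PP", "vaspin", "MMSE"), "MMSE", "PP")
  de <- differential_edges(a, b)
  expect_setequal(de$status[de$from == "PP" & de$to == "vaspin"], "only_a")
  expect_equal(sum(de$status == "shared"), 1)
  expect_equal(nrow(de), 2)

  same <- differential_edges(a, a)
  expect_true(all(same$status == "shared"))
  disjoint <- differential_edges(
    test_network(c("x", "y", "z"), "x", "y"),
    test_network(c("x", "y", "z"), "y", "z"))
  expect_false(any(disjoint$status == "shared"))
  expect_error(differential_edges(a, test_network(c("x", "y"), "x", "y")),
               "panel")
})
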