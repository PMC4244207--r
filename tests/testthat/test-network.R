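test_that("network construction thresholds, dedupes and drops isolates", {
  pairs <- data.frame(
    gene_a = c("a", "a", "a", "b", "b", "c"),
    gene_b = c("b", "c", "d", "c", "d", "d"),
    weight = c(0.9, 0.6, 0.2, 0.55, 0.1, 0.05))

  net0 <- build_network(pairs, "INT", 0)
  expect_equal(length(net0$nodes), 4L)
  expect_equal(nrow(net0$edges), 6L)     # complete graph on recorded pairs

  net <- build_network(pairs, "INT", 0.5)
  expect_setequal(net$nodes, c("a", "b", "c"))    # d isolated, excluded
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$weight >= 0.5))

  net1 <- build_network(pairs, "INT", 1)
  expect_equal(nrow(net1$edges), 0L)
  expect_equal(length(net1$nodes), 0L)

  # nestedness: higher threshold keeps a subset of edges
  for (t1 in c(0.1, 0.3)) for (t2 in c(0.55, 0.8)) {
    e1 <- fgnet:::edge_keys(build_network(pairs, "INT", t1))
    e2 <- fgnet:::edge_keys(build_network(pairs, "INT", t2))
    expect_true(all(e2 %in% e1))
  }
})

test_that("clustering coefficient follows the degree<2 convention", {
  tri <- net_from_edges(c("a", "b", "c"), c("b", "c", "a"))
  expect_equal(clustering_coefficient(tri), 1)
  star <- net_from_edges(rep("h", 4), paste0("l", 1:4))
  expect_equal(clustering_coefficient(star), 0)
  empty <- build_network(data.frame(gene_a = "a", gene_b = "b", weight = 0.1),
                         "INT", 0.9)
  expect_equal(clustering_coefficient(empty), 0)

  for (s in 1:50) {
    net <- random_network(sample(5:20, 1), runif(1, 0.15, 0.5), seed = s)
    expect_equal(clustering_coefficient(net), oracle_clustering(net))
  }
})

test_that("the random expectation matches its closed form and Monte Carlo", {
  k4 <- net_from_edges(c("a", "a", "a", "b", "b", "c"),
                       c("b", "c", "d", "c", "d", "d"))
  expect_equal(random_clustering_expectation(k4), 1 / 3)

  empty <- build_network(data.frame(gene_a = "a", gene_b = "b", weight = 0.1),
                         "INT", 0.9)
  expect_equal(random_clustering_expectation(empty), 0)

  # Erdos-Renyi: expectation within 3 standard errors of sampled clustering
  set.seed(77)
  n <- 200; p <- 0.1
  samples <- replicate(100, {
    g <- igraph::sample_gnp(n, p)
    mean(igraph::transitivity(g, type = "localundirected",
                              isolates = "zero"))
  })
  g0 <- igraph::sample_gnp(n, p)
  el <- igraph::as_data_frame(g0)
  net <- net_from_edges(as.character(el$from), as.character(el$to))
  expected <- random_clustering_expectation(net)
  se <- sd(samples) / sqrt(length(samples))
  expect_lt(abs(expected - mean(samples)), 3 * se + 0.01)
})

test_that("first-peak selection follows the boundary semantics", {
  grid <- seq(0, 1, by = 0.01)
  decreasing <- seq(1, 0, length.out = 101)
  expect_equal(fgnet:::select_first_peak(decreasing, grid), 0.01)
  increasing <- seq(0, 1, length.out = 101)
  expect_warning(sel <- fgnet:::select_first_peak(increasing, grid),
                 "whole grid")
  expect_equal(sel, 1)
  peaked <- c(seq(0, 0.5, length.out = 41), seq(0.49, 0, length.out = 60))
  expect_equal(fgnet:::select_first_peak(peaked, grid), 0.40)
  # a plateau stops the increasing run
  plateau <- c(seq(0, 0.5, length.out = 41), rep(0.5, 60))
  expect_equal(fgnet:::select_first_peak(plateau, grid), 0.40)
})

test_that("threshold scan recovers planted thresholds", {
  pn <- simulate_planted_network(seed = 101)
  sc <- threshold_scan(pn$pairs, "INT")
  expect_s3_class(sc, "threshold_scan")
  expect_true(all(diff(sc$edges) <= 0))           # edges non-increasing
  expect_equal(sc$delta, sc$c_obs - sc$c_rand)
  expect_equal(attr(sc, "selected"), pn$truth$threshold)

  # c_obs at threshold 0 equals the clustering of the full pair graph
  full <- build_network(pn$pairs, "INT", 0)
  expect_equal(sc$c_obs[1], clustering_coefficient(full))

  expect_error(threshold_scan(data.frame(gene_a = "a", gene_b = "b",
                                         weight = 0)), "zero")

  hits <- 0L
  for (s in 1:8) {
    pn <- simulate_planted_network(seed = 1000 + s,
                                   threshold = sample(seq(0.5, 0.9, 0.1), 1))
    sel <- attr(suppressWarnings(threshold_scan(pn$pairs, "INT")), "selected")
    if (abs(sel - pn$truth$threshold) <= 0.0100001) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("global properties match closed forms and a naive reimplementation", {
  path3 <- net_from_edges(c("a", "b"), c("b", "c"))
  gp <- global_properties(path3)
  expect_equal(gp$diameter, 2)
  expect_equal(gp$density, 2 / 3)
  expect_equal(gp$components, 1)

  two_tri <- net_from_edges(c("a", "b", "c", "x", "y", "z"),
                            c("b", "c", "a", "y", "z", "x"))
  gp2 <- global_properties(two_tri)
  expect_equal(gp2$components, 2)
  expect_equal(gp2$clustering_coefficient, 1)

  net <- random_network(30, 0.15, seed = 5)
  gp3 <- global_properties(net)
  k <- oracle_degrees(net)
  expect_equal(gp3$nodes, length(net$nodes))
  expect_equal(gp3$edges, nrow(net$edges))
  expect_equal(gp3$mean_neighbors, mean(k))
  expect_equal(gp3$density,
               nrow(net$edges) / pair_count(length(net$nodes)))
  expect_equal(gp3$heterogeneity, sd(k) / mean(k),
               tolerance = 0.05)  # population vs sample sd normalisation
  expect_equal(gp3$clustering_coefficient, oracle_clustering(net))

  # naive BFS diameter of the largest component
  g <- as_igraph(net)
  comp <- igraph::components(g)
  giant <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  d <- igraph::distances(g, v = giant, to = giant, weights = NA)
  expect_equal(gp3$diameter, max(d))
})

test_that("network writers emit edge lists, SIF and scan summaries", {
  net <- net_from_edges(c("a", "b"), c("b", "c"), weight = c(0.9, 0.8))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f1)
  expect_equal(read.delim(f1)$weight, c(0.9, 0.8))
  f2 <- withr::local_tempfile(fileext = ".sif")
  write_network(net, f2, format = "sif")
  expect_equal(readLines(f2), c("a\tsim\tb", "b\tsim\tc"))

  pn <- simulate_planted_network(seed = 3)
  sc <- threshold_scan(pn$pairs, "INT")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  f4 <- withr::local_tempfile(fileext = ".json")
  write_scan(sc, f3, f4)
  expect_equal(nrow(read.delim(f3)), 101L)
  expect_equal(jsonlite::read_json(f4)$selected, attr(sc, "selected"))
})
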