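test_that("read_obo transcribes terms and edges, honouring exclusions", {
  ont <- ont_from_obo(c(
    obo_term("GO:0000001"),
    obo_term("GO:0000002", is_a = "GO:0000001"),
    obo_term("GO:0000003", rel = "part_of GO:0000002")))
  expect_setequal(ont$terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(ont$n_edges, 2L)
  expect_equal(ont$parents[["GO:0000003"]], "GO:0000002")
  expect_equal(unname(ont$roots["BP"]), "GO:0000001")

  # obsolete terms are excluded entirely
  ont2 <- ont_from_obo(c(
    obo_term("GO:0000001"),
    obo_term("GO:0000002", is_a = "GO:0000001"),
    obo_term("GO:0000009", is_a = "GO:0000001", obsolete = TRUE)))
  expect_false("GO:0000009" %in% ont2$terms)
  expect_true("GO:0000009" %in% ont2$obsolete)

  # has_part relationships are not parent edges
  ont3 <- ont_from_obo(c(
    obo_term("GO:0000001"),
    obo_term("GO:0000002", is_a = "GO:0000001",
             rel = "has_part GO:0000001")))
  expect_equal(ont3$n_edges, 1L)
})

test_that("read_obo rejects malformed stanzas and cyclic graphs", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:1", "namespace: biological_process",
               "garbage-line-without-separator"), f)
  expect_error(suppressMessages(read_obo(f)), "line")

  expect_error(ont_from_obo(c(
    obo_term("GO:1"),
    obo_term("GO:2", is_a = c("GO:1", "GO:3")),
    obo_term("GO:3", is_a = "GO:2"))), "cycle")
})

test_that("descendant counts match brute-force reachability", {
  # 6-term diamond: root -> {A, B} -> C (both) -> D leaf, plus leaf E
  ont <- ont_from_obo(c(
    obo_term("GO:R"),
    obo_term("GO:A", is_a = "GO:R"),
    obo_term("GO:B", is_a = "GO:R"),
    obo_term("GO:C", is_a = c("GO:A", "GO:B")),
    obo_term("GO:D", is_a = "GO:C"),
    obo_term("GO:E", is_a = "GO:A")))
  d <- descendant_counts(ont)
  expect_equal(unname(d["GO:D"]), 1L)        # leaf counts itself
  expect_equal(unname(d["GO:R"]), 6L)        # root counts everything
  expect_equal(d[ont$terms], oracle_descendants(ont)[ont$terms])

  for (s in 1:100) {
    sim <- simulate_ontology(n_terms = c(BP = sample(5:30, 1)),
                             p_multi_parent = 0.4, seed = s)
    ont <- sim$ontology
    expect_equal(descendant_counts(ont)[ont$terms],
                 oracle_descendants(ont)[ont$terms])
  }
})

test_that("T-values follow the attenuated parent average", {
  # root with a single child: omega = 1/2, T(child) = 0.5
  ont <- ont_from_obo(c(obo_term("GO:R"), obo_term("GO:A", is_a = "GO:R")))
  st <- term_stats(ont)
  expect_equal(unname(st$t_value["GO:R"]), 1)
  expect_equal(unname(st$t_value["GO:A"]), 0.5)

  # multi-parent averaging under a constant omega strategy:
  # T = omega * mean(parent T-values)
  ont2 <- ont_from_obo(c(
    obo_term("GO:R"),
    obo_term("GO:A", is_a = "GO:R"),
    obo_term("GO:B", is_a = "GO:R"),
    obo_term("GO:C", is_a = c("GO:A", "GO:B"))))
  st2 <- term_stats(ont2, omega = function(desc, t, p) 0.25)
  expect_equal(unname(st2$t_value["GO:C"]),
               0.25 * mean(c(st2$t_value[["GO:A"]], st2$t_value[["GO:B"]])))

  # random DAGs: equality with direct recursion, and strict decrease below
  # the parents' mean
  for (s in 1:25) {
    sim <- simulate_ontology(n_terms = c(BP = 20), p_multi_parent = 0.5,
                             seed = s)
    ont <- sim$ontology
    st <- term_stats(ont)
    expect_equal(st$t_value[ont$terms],
                 oracle_t_values(ont, st$descendants)[ont$terms])
    for (t in setdiff(ont$terms, ont$roots)) {
      expect_lt(st$t_value[[t]], mean(st$t_value[ont$parents[[t]]]))
      expect_gt(st$t_value[[t]], 0)
    }
  }
})

test_that("LCA shortest path is minimal, symmetric and well-bounded", {
  ont <- ont_from_obo(c(
    obo_term("GO:R"),
    obo_term("GO:A", is_a = "GO:R"),
    obo_term("GO:B", is_a = "GO:R")))
  st <- term_stats(ont)
  expect_equal(lca_shortest_path(ont, st, "GO:A", "GO:A"), "GO:A")
  expect_equal(lca_shortest_path(ont, st, "GO:A", "GO:B"),
               c("GO:A", "GO:R", "GO:B"))

  # 8-term DAG with two candidate LCAs: cost equals the exhaustive optimum
  ont8 <- ont_from_obo(c(
    obo_term("GO:R"),
    obo_term("GO:P1", is_a = "GO:R"),
    obo_term("GO:P2", is_a = "GO:R"),
    obo_term("GO:M1", is_a = c("GO:P1", "GO:P2")),
    obo_term("GO:M2", is_a = c("GO:P1", "GO:P2")),
    obo_term("GO:X", is_a = "GO:M1"),
    obo_term("GO:Y", is_a = c("GO:M1", "GO:M2")),
    obo_term("GO:Z", is_a = "GO:M2")))
  st8 <- term_stats(ont8)
  path <- lca_shortest_path(ont8, st8, "GO:X", "GO:Z")
  best <- oracle_best_path_cost(ont8, st8$t_value, "GO:X", "GO:Z")
  expect_equal(length(path) - 1L, best[1])
  expect_equal(sum(st8$t_value[path]), best[2])

  # symmetry and optimality on random DAGs
  for (s in 1:20) {
    sim <- simulate_ontology(n_terms = c(BP = 15), p_multi_parent = 0.5,
                             seed = s)
    ont <- sim$ontology; st <- term_stats(ont)
    prs <- replicate(5, sample(ont$terms, 2), simplify = FALSE)
    for (pr in prs) {
      p12 <- lca_shortest_path(ont, st, pr[1], pr[2])
      p21 <- lca_shortest_path(ont, st, pr[2], pr[1])
      expect_equal(rev(p21), p12)
      best <- oracle_best_path_cost(ont, st$t_value, pr[1], pr[2])
      expect_equal(length(p12) - 1L, best[1])
      expect_equal(sum(st$t_value[p12]), best[2])
    }
  }

  expect_error(lca_shortest_path(ont_from_obo(c(
    obo_term("GO:R"), obo_term("GO:S", ns = "molecular_function"))),
    st, "GO:R", "GO:S"), "aspect")
})

test_that("term statistics export writes the four-column TSV", {
  sim <- simulate_ontology(n_terms = c(BP = 6), seed = 1)
  st <- term_stats(sim$ontology)
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- write_term_stats(sim$ontology, st, f)
  back <- read.delim(f)
  expect_equal(names(back),
               c("term", "aspect", "descendant_count", "t_value"))
  expect_equal(back$t_value, unname(st$t_value[back$term]))
})
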