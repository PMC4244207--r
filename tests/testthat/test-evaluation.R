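test_that("shared-pathway reference forms cliques per term", {
  ref <- kegg_reference(data.frame(gene = c("a", "b", "c"), term = "K1"))
  expect_equal(nrow(ref$edges), 3L)

  ref2 <- kegg_reference(data.frame(gene = c("a", "b", "c", "d"),
                                    term = c("K1", "K1", "K2", "K2")))
  expect_equal(nrow(ref2$edges), 2L)

  # overlapping terms: edge iff the pair shares at least one term
  set.seed(31)
  links <- data.frame(gene = sample(letters[1:8], 30, replace = TRUE),
                      term = sample(paste0("K", 1:5), 30, replace = TRUE))
  ref3 <- kegg_reference(links)
  genes <- sort(unique(links$gene))
  for (i in seq_along(genes)) for (j in seq_along(genes)) {
    if (i >= j) next
    shares <- length(intersect(links$term[links$gene == genes[i]],
                               links$term[links$gene == genes[j]])) > 0
    has_edge <- any(ref3$edges$from == genes[i] & ref3$edges$to == genes[j])
    expect_equal(has_edge, shares)
  }
})

test_that("co-expression reference applies the absolute-PCC rule", {
  base <- rbind(a = 1:10, b = (1:10) * 2, c = -(1:10), d = rnorm(10))
  ref <- coexpression_reference(list(base), min_samples = 5)
  expect_true(any(ref$edges$from == "a" & ref$edges$to == "b"))  # identical
  expect_true(any(ref$edges$from == "a" & ref$edges$to == "c"))  # anti

  # a constant gene is skipped with a warning
  withcst <- rbind(base, e = rep(1, 10))
  expect_warning(coexpression_reference(list(withcst), min_samples = 5),
                 "constant")

  # datasets under the sample floor are discarded
  expect_error(coexpression_reference(list(base[, 1:3]), min_samples = 5),
               "fewer than 5")

  # block-correlation recovery against the generator's plan
  sim <- simulate_expression(blocks = c(10, 10), rho = c(0.95, 0.3),
                             n_independent = 10, n_samples = c(100, 6),
                             seed = 8)
  ref2 <- coexpression_reference(sim$datasets, min_samples = 20,
                                 pcc_cutoff = 0.8)
  truth <- sim$truth
  hi <- truth$gene[!is.na(truth$block) & truth$rho >= 0.9]
  hi_pairs <- t(combn(hi, 2))
  linked <- vapply(seq_len(nrow(hi_pairs)), function(i)
    any(ref2$edges$from == min(hi_pairs[i, ]) &
          ref2$edges$to == max(hi_pairs[i, ])), logical(1))
  expect_gte(mean(linked), 0.95)

  lo <- truth$gene[is.na(truth$block) | truth$rho <= 0.5]
  lo_pairs <- t(combn(lo, 2))
  linked_lo <- vapply(seq_len(nrow(lo_pairs)), function(i)
    any(ref2$edges$from == min(lo_pairs[i, ]) &
          ref2$edges$to == max(lo_pairs[i, ])), logical(1))
  expect_lte(mean(linked_lo), 0.05)
})

test_that("orthology transfer expands edges through the ortholog map", {
  one <- orthology_transfer(data.frame(a = "s1", b = "s2"),
                            data.frame(src = c("s1", "s2"),
                                       tgt = c("t1", "t2")))
  expect_equal(nrow(one$edges), 1L)

  many <- orthology_transfer(
    data.frame(a = "s1", b = "s2"),
    data.frame(src = c("s1", "s1", "s2", "s2"),
               tgt = c("t1", "t2", "t3", "t4")))
  expect_equal(nrow(many$edges), 4L)

  selfmap <- orthology_transfer(
    data.frame(a = "s1", b = "s2"),
    data.frame(src = c("s1", "s2"), tgt = c("t1", "t1")))
  expect_error(selfmap, NA)
  expect_equal(nrow(selfmap$edges), 0L)
})

test_that("coverage and accuracy reproduce ratio arithmetic", {
  net <- net_from_edges(c("a", "b", "c"), c("b", "c", "a"))
  self <- coverage_accuracy(net, net)
  expect_equal(self$gene_coverage_pct, 100)
  expect_equal(self$linkage_accuracy_pct, 100)

  # relabel invariance
  perm <- setNames(c("x", "y", "z"), c("a", "b", "c"))
  relq <- net_from_edges(unname(perm[net$edges$from]),
                         unname(perm[net$edges$to]))
  expect_equal(coverage_accuracy(relq, relq)$linkage_accuracy_pct, 100)

  ref <- net_from_edges(c("a", "b", "d"), c("b", "d", "e"))
  rep1 <- coverage_accuracy(net, ref)
  expect_equal(rep1$n_shared_genes, 2L)          # a, b
  expect_equal(rep1$gene_coverage_pct, round(100 * 2 / 4, 2))
  expect_equal(rep1$n_reference_links, 1L)       # query edge a-b
  expect_equal(rep1$n_query_links_shared, 1L)    # also in ref
  expect_equal(rep1$linkage_accuracy_pct, 100)

  # degenerate reference
  lonely <- net_from_edges("p", "q")
  deg <- coverage_accuracy(net, lonely)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$linkage_accuracy_pct))
})

test_that("rewiring preserves the degree multiset exactly", {
  for (s in 1:5) {
    net <- random_network(20, 0.2, seed = 40 + s)
    set.seed(s)
    rw <- rewire_network(net)
    expect_equal(sort(unname(oracle_degrees(rw)[net$nodes])),
                 sort(unname(oracle_degrees(net)[net$nodes])))
    expect_false(any(rw$edges$from == rw$edges$to))
    expect_false(any(duplicated(rw$edges[c("from", "to")])))
  }
})

test_that("randomized background separates planted overlap from null", {
  # planted: query largely copied from the reference
  set.seed(61)
  ref <- random_network(40, 0.15, seed = 201)
  take <- sample(nrow(ref$edges), floor(nrow(ref$edges) * 0.7))
  extra <- random_network(40, 0.05, seed = 202)
  query <- net_from_edges(c(ref$edges$from[take], extra$edges$from),
                          c(ref$edges$to[take], extra$edges$to))
  rep1 <- randomized_background(query, ref, n_random = 200, seed = 62)
  expect_lt(rep1$p_value, 0.05)
  expect_gt(rep1$linkage_accuracy_pct, rep1$background_mean_accuracy)

  # null: query sampled independently of the reference
  query0 <- random_network(40, 0.12, seed = 203)
  rep0 <- randomized_background(query0, ref, n_random = 200, seed = 63)
  expect_lt(abs(rep0$linkage_accuracy_pct - rep0$background_mean_accuracy),
            3 * rep0$background_sd + 1e-9)
})

test_that("the ANOVA mode contrasts background distributions", {
  b <- list(net1 = rnorm(50, 2, 0.5), net2 = rnorm(50, 4, 0.5))
  fit <- la_anova(b)
  expect_s3_class(fit, "aov")
  expect_lt(summary(fit)[[1]][["Pr(>F)"]][1], 0.01)
})
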