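# Naive, independent re-implementations used as oracles. They share no code
# with the package internals: plain loops over explicit adjacency.

# Build a go_ontology from an OBO text written on the fly.
ont_from_obo <- function(lines, keep_relations = "part_of") {
  f <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(lines, f)
  suppressMessages(read_obo(f, keep_relations = keep_relations))
}

obo_term <- function(id, ns = "biological_process", is_a = character(),
                     rel = character(), obsolete = FALSE) {
  c("[Term]", paste0("id: ", id), paste0("namespace: ", ns),
    paste0("is_a: ", is_a),
    if (length(rel)) paste0("relationship: ", rel),
    if (obsolete) "is_obsolete: true")
}

# Reachability-based descendant counting: t's descendants are all u whose
# ancestor closure (upward over parent edges) contains t, plus t itself.
oracle_descendants <- function(ont) {
  anc <- lapply(ont$terms, function(u) {
    seen <- u; frontier <- u
    while (length(frontier)) {
      nxt <- setdiff(unlist(ont$parents[frontier], use.names = FALSE), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    seen
  })
  names(anc) <- ont$terms
  vapply(ont$terms, function(t)
    sum(vapply(anc, function(a) t %in% a, logical(1))), integer(1))
}

# Direct recursion of the T-value averaging rule with the ratio omega.
oracle_t_values <- function(ont, desc) {
  memo <- new.env()
  rec <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- ont$parents[[t]]
    v <- if (!length(ps)) 1
         else mean(vapply(ps, function(p)
           (desc[[t]] / desc[[p]]) * rec(p), numeric(1)))
    memo[[t]] <- v
    v
  }
  vapply(ont$terms, rec, numeric(1))
}

# Every upward path from `from` to each of its ancestors (including the
# trivial path), as term vectors.
oracle_up_paths <- function(ont, from) {
  out <- list()
  rec <- function(node, acc) {
    out[[length(out) + 1L]] <<- acc
    for (p in ont$parents[[node]]) rec(p, c(acc, p))
  }
  rec(from, from)
  out
}

# Exhaustive minimum over joined up-paths: returns c(hops, sum of T-values)
# of the best t1 -> ancestor -> t2 path.
oracle_best_path_cost <- function(ont, tv, t1, t2) {
  p1 <- oracle_up_paths(ont, t1)
  p2 <- oracle_up_paths(ont, t2)
  best <- c(Inf, Inf)
  for (a in p1) for (b in p2) {
    if (a[length(a)] != b[length(b)]) next
    path <- c(a, rev(b)[-1])
    if (anyDuplicated(path)) next
    cand <- c(length(path) - 1L, sum(tv[path]))
    if (cand[1] < best[1] || (cand[1] == best[1] && cand[2] < best[2] - 1e-12))
      best <- cand
  }
  best
}

# Random gene_network via G(n, p); nodes g01..gn, unit weights.
random_network <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  prs <- t(combn(nodes, 2L))
  keep <- which(runif(nrow(prs)) < p)
  if (length(keep) < 1L) return(random_network(n, min(1, p * 2), seed + 1000))
  pairs <- data.frame(gene_a = prs[keep, 1, drop = TRUE],
                      gene_b = prs[keep, 2, drop = TRUE],
                      weight = rep(1, length(keep)), stringsAsFactors = FALSE)
  build_network(pairs, "INT", 0)
}

net_from_edges <- function(from, to, weight = 1) {
  build_network(data.frame(gene_a = from, gene_b = to,
                           weight = rep_len(weight, length(from)),
                           stringsAsFactors = FALSE), "INT", 0)
}

# O(n^3) mean local clustering with the degree<2 => 0 convention.
oracle_clustering <- function(net) {
  nodes <- net$nodes
  if (!length(nodes)) return(0)
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(net$edges))) {
    adj[net$edges$from[i], net$edges$to[i]] <- TRUE
    adj[net$edges$to[i], net$edges$from[i]] <- TRUE
  }
  ci <- vapply(nodes, function(v) {
    nb <- nodes[adj[v, ]]
    k <- length(nb)
    if (k < 2) return(0)
    e <- 0L
    for (a in seq_along(nb)) for (b in seq_along(nb))
      if (a < b && adj[nb[a], nb[b]]) e <- e + 1L
    2 * e / (k * (k - 1))
  }, numeric(1))
  mean(ci)
}

oracle_degrees <- function(net) {
  k <- setNames(integer(length(net$nodes)), net$nodes)
  for (i in seq_len(nrow(net$edges))) {
    k[net$edges$from[i]] <- k[net$edges$from[i]] + 1L
    k[net$edges$to[i]] <- k[net$edges$to[i]] + 1L
  }
  k
}

# Newman's closed-form assortativity over edge endpoint degrees.
oracle_assortativity <- function(net) {
  k <- oracle_degrees(net)
  j <- k[net$edges$from]; l <- k[net$edges$to]
  m <- length(j)
  num <- sum(j * l) / m - (sum((j + l) / 2) / m)^2
  den <- sum((j^2 + l^2) / 2) / m - (sum((j + l) / 2) / m)^2
  num / den
}
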