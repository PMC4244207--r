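#' Read an OBO ontology into a rooted DAG
#'
#' Parses an OBO 1.2/1.4 stanza file into a `go_ontology` object: a set of
#' terms with parent edges (`is_a` plus any relationship types listed in
#' `keep_relations`), one namespace (aspect) per term, and one root term per
#' aspect. Obsolete terms are recorded but carry no edges. Cross-aspect edges
#' are dropped with a warning, matching the convention of excluding
#' inter-ontology links.
#'
#' @param path Path to an OBO file.
#' @param keep_relations Character vector of `relationship:` types to retain
#'   as parent edges in addition to `is_a`. Default `"part_of"`; `has_part`
#'   and other relations are always excluded unless listed here.
#' @return A `go_ontology` object: list with `terms`, `parents` (named list,
#'   term -> character vector of parent terms), `children` (reverse map),
#'   `aspect` (named character, values `"BP"`, `"MF"`, `"CC"`), `roots`
#'   (named by aspect), `obsolete`, and `n_edges`.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: GO:0008150", "name: biological_process",
#'   "namespace: biological_process",
#'   "[Term]", "id: GO:0000001", "namespace: biological_process",
#'   "is_a: GO:0008150"), obo)
#' ont <- read_obo(obo)
#' ont$roots
#' @export
read_obo <- function(path, keep_relations = "part_of") {
  if (!file.exists(path)) stop_fgnet("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  ns_map <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")

  terms <- character()
  aspect <- character()
  obsolete <- character()
  parent_from <- character()
  parent_to <- character()

  in_term <- FALSE
  cur_id <- NA_character_
  cur_ns <- NA_character_
  cur_obs <- FALSE
  cur_parents <- character()

  flush_term <- function() {
    if (is.na(cur_id)) return(invisible())
    terms[length(terms) + 1L] <<- cur_id
    aspect[cur_id] <<- cur_ns
    if (cur_obs) {
      obsolete[length(obsolete) + 1L] <<- cur_id
    } else if (length(cur_parents)) {
      parent_from <<- c(parent_from, rep(cur_id, length(cur_parents)))
      parent_to <<- c(parent_to, cur_parents)
    }
  }

  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "!")) next
    if (startsWith(ln, "[")) {
      if (in_term) flush_term()
      in_term <- identical(ln, "[Term]")
      cur_id <- NA_character_; cur_ns <- NA_character_
      cur_obs <- FALSE; cur_parents <- character()
      next
    }
    if (!in_term) next
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 0L) stop_fgnet("malformed OBO stanza line ", i, ": ", ln)
    tag <- substr(ln, 1L, colon - 1L)
    val <- trimws(substr(ln, colon + 1L, nchar(ln)))
    val <- sub("\\s*!.*$", "", val)  # strip trailing comments
    if (tag == "id") {
      cur_id <- val
    } else if (tag == "namespace") {
      cur_ns <- unname(ns_map[val]) %||% NA_character_
      if (is.na(cur_ns)) cur_ns <- val
    } else if (tag == "is_obsolete") {
      cur_obs <- identical(val, "true")
    } else if (tag == "is_a") {
      cur_parents <- c(cur_parents, strsplit(val, "\\s+")[[1]][1])
    } else if (tag == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) < 2L)
        stop_fgnet("malformed relationship on line ", i, ": ", ln)
      if (parts[1] %in% keep_relations)
        cur_parents <- c(cur_parents, parts[2])
    }
  }
  if (in_term) flush_term()

  keep <- setdiff(terms, obsolete)
  drop_edge <- !(parent_from %in% keep) | !(parent_to %in% keep)
  cross <- aspect[parent_from] != aspect[parent_to]
  cross[is.na(cross)] <- FALSE
  if (any(cross & !drop_edge))
    warn_fgnet(sum(cross & !drop_edge), " cross-aspect edge(s) dropped")
  drop_edge <- drop_edge | cross
  parent_from <- parent_from[!drop_edge]
  parent_to <- parent_to[!drop_edge]

  ont <- new_ontology(keep, parent_from, parent_to, aspect[keep], obsolete)
  message(sprintf("read_obo: %d terms (%d obsolete excluded), %d parent edges",
                  length(keep), length(obsolete), ont$n_edges))
  ont
}

# Assemble and validate a go_ontology from term/edge vectors.
new_ontology <- function(terms, parent_from, parent_to, aspect, obsolete = character()) {
  parents <- split(parent_to, factor(parent_from, levels = terms))
  children <- split(parent_from, factor(parent_to, levels = terms))
  names(aspect) <- terms

  roots <- character()
  for (asp in unique(aspect)) {
    tset <- terms[aspect == asp]
    r <- tset[lengths(parents[tset]) == 0L]
    if (length(r) != 1L)
      stop_fgnet("aspect ", asp, " must have exactly one root, found ",
                 length(r), ": ", paste(r, collapse = ", "))
    roots[asp] <- r
  }

  ont <- structure(
    list(terms = terms, parents = parents, children = children,
         aspect = aspect, roots = roots, obsolete = obsolete,
         n_edges = length(parent_from)),
    class = "go_ontology")
  assert_acyclic(ont)
  ont
}

# Kahn topological sort over parent edges; errors on cycles.
# Returns terms ordered so every parent precedes its children.
topo_order <- function(ont) {
  n_par <- lengths(ont$parents)
  queue <- ont$terms[n_par == 0L]
  out <- character(length(ont$terms)); k <- 0L
  indeg <- n_par
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    k <- k + 1L; out[k] <- t
    for (ch in ont$children[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (k < length(ont$terms))
    stop_fgnet("ontology contains a cycle involving: ",
               paste(head(ont$terms[!ont$terms %in% out[seq_len(k)]], 5),
                     collapse = ", "))
  out[seq_len(k)]
}

assert_acyclic <- function(ont) invisible(topo_order(ont))

#' @export
print.go_ontology <- function(x, ...) {
  cat("Gene Ontology DAG:", length(x$terms), "terms,", x$n_edges,
      "parent edges\n")
  for (asp in names(x$roots))
    cat(sprintf("  %s: %d terms, root %s\n", asp,
                sum(x$aspect == asp), x$roots[asp]))
  if (length(x$obsolete)) cat("  obsolete excluded:", length(x$obsolete), "\n")
  invisible(x)
}

ont_as_igraph <- function(ont) {
  el <- cbind(rep(names(ont$parents), lengths(ont$parents)),
              unlist(ont$parents, use.names = FALSE))
  igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = ont$terms, stringsAsFactors = FALSE))
}

#' Descendant counts for every ontology term
#'
#' The descendant count of a term is the number of terms from which it is
#' reachable by parent edges, including the term itself; leaves therefore
#' count 1 and an aspect root counts every term of its aspect.
#'
#' @param ont A `go_ontology`.
#' @return Named integer vector over all terms.
#' @export
descendant_counts <- function(ont) {
  g <- ont_as_igraph(ont)
  counts <- vapply(ont$terms, function(t)
    length(igraph::subcomponent(g, t, mode = "in")), integer(1))
  counts
}

#' Per-edge semantic differentiation factor
#'
#' The default strategy: the ratio of the child's to the parent's descendant
#' count. It lies strictly in (0, 1) for every true child edge, decreases
#' down the hierarchy, and grows with the child's local density.
#'
#' @param desc Named integer vector of descendant counts.
#' @param term,parent Term identifiers of a child edge.
#' @return Scalar in (0, 1).
#' @export
omega_ratio <- function(desc, term, parent) {
  unname(desc[term] / desc[parent])
}

#' Semantic totipotency (T-values) and descendant counts
#'
#' Computes the per-term statistics the SSDD similarity is built on. Each
#' aspect root has T-value 1; every other term's T-value is the mean over its
#' parents of the parent's T-value attenuated by the per-edge differentiation
#' factor: T(t) = mean_p [ omega(t, p) * T(p) ]. Evaluated in topological
#' order, so all T-values lie in (0, 1].
#'
#' @param ont A `go_ontology`.
#' @param omega Strategy function `(desc, term, parent) -> numeric` giving
#'   the per-edge differentiation factor; default [omega_ratio].
#' @return A `term_stats` object: list with `descendants` (named integer) and
#'   `t_value` (named numeric).
#' @export
term_stats <- function(ont, omega = omega_ratio) {
  desc <- descendant_counts(ont)
  tv <- setNames(rep(NA_real_, length(ont$terms)), ont$terms)
  tv[ont$roots] <- 1
  for (t in topo_order(ont)) {
    if (!is.na(tv[t])) next
    ps <- ont$parents[[t]]
    tv[t] <- mean(vapply(ps, function(p) omega(desc, t, p) * tv[p], numeric(1)))
  }
  if (anyNA(tv))
    stop_fgnet("terms unreachable from an aspect root: ",
               paste(names(tv)[is.na(tv)], collapse = ", "))
  structure(list(descendants = desc, t_value = tv, omega = omega),
            class = "term_stats")
}

#' @export
print.term_stats <- function(x, ...) {
  cat("Term statistics for", length(x$t_value), "terms\n")
  cat("  T-value range:",
      sprintf("[%.4g, %.4g]", min(x$t_value), max(x$t_value)), "\n")
  invisible(x)
}

# Upward single-source search over parent edges minimising (hops, summed
# T-value) lexicographically, with a deterministic predecessor tie-break.
# Returns list(hops, tsum, pred) over reachable ancestors.
up_search <- function(ont, tv, from) {
  hops <- setNames(rep(Inf, length(ont$terms)), ont$terms)
  tsum <- hops
  pred <- setNames(rep(NA_character_, length(ont$terms)), ont$terms)
  hops[from] <- 0; tsum[from] <- tv[from]
  queue <- from
  while (length(queue)) {
    u <- queue[[1]]; queue <- queue[-1]
    for (p in sort(ont$parents[[u]])) {
      nh <- hops[u] + 1; nt <- tsum[u] + tv[p]
      better <- nh < hops[p] ||
        (nh == hops[p] && nt < tsum[p] - 1e-12) ||
        (nh == hops[p] && abs(nt - tsum[p]) <= 1e-12 &&
           !is.na(pred[p]) && u < pred[p])
      if (better) {
        if (hops[p] == Inf) queue <- c(queue, p)
        hops[p] <- nh; tsum[p] <- nt; pred[p] <- u
      }
    }
  }
  list(hops = hops, tsum = tsum, pred = pred)
}

walk_pred <- function(pred, from, to) {
  path <- to
  while (path[[1]] != from) path <- c(pred[path[[1]]], path)
  path
}

#' Shortest path between two terms through a lowest common ancestor
#'
#' Finds the term path t1 -> LCA -> t2 with the fewest hops; ties are broken
#' by the minimal summed T-value along the path (the quantity the SSDD
#' distance accumulates), then lexicographically for determinism. Both
#' endpoints and the common ancestor appear exactly once.
#'
#' @param ont A `go_ontology`.
#' @param stats A `term_stats` object.
#' @param t1,t2 Term identifiers in the same aspect.
#' @return Character vector of terms from `t1` to `t2`.
#' @export
lca_shortest_path <- function(ont, stats, t1, t2) {
  if (!t1 %in% ont$terms || !t2 %in% ont$terms)
    stop_fgnet("unknown term(s): ", paste(setdiff(c(t1, t2), ont$terms),
                                          collapse = ", "))
  if (ont$aspect[t1] != ont$aspect[t2])
    stop_fgnet("terms belong to different aspects: ",
               ont$aspect[t1], " vs ", ont$aspect[t2])
  if (t1 == t2) return(t1)
  tv <- stats$t_value
  s1 <- up_search(ont, tv, t1)
  s2 <- up_search(ont, tv, t2)
  common <- ont$terms[is.finite(s1$hops) & is.finite(s2$hops)]
  stopifnot(length(common) > 0L)  # single-rooted aspect guarantees the root
  h <- s1$hops[common] + s2$hops[common]
  ts <- s1$tsum[common] + s2$tsum[common] - tv[common]
  ord <- order(h, ts, common)
  a <- common[ord[[1]]]
  up1 <- walk_pred(s1$pred, t1, a)
  up2 <- walk_pred(s2$pred, t2, a)
  unname(c(up1, rev(up2)[-1]))
}

#' Write per-term statistics as TSV
#'
#' Columns: term, aspect, descendant_count, t_value.
#'
#' @param ont A `go_ontology`.
#' @param stats A `term_stats` object.
#' @param path Output file path.
#' @return Invisibly, the data frame written.
#' @export
write_term_stats <- function(ont, stats, path) {
  df <- data.frame(term = ont$terms,
                   aspect = unname(ont$aspect[ont$terms]),
                   descendant_count = unname(stats$descendants[ont$terms]),
                   t_value = unname(stats$t_value[ont$terms]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
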