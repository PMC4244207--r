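net_neighbors <- function(net, gene) {
  c(net$edges$to[net$edges$from == gene],
    net$edges$from[net$edges$to == gene])
}

#' Guilt-by-association candidate genes
#'
#' Returns the union of the direct network neighbours of the query
#' (function-known) genes, minus the queries themselves. Queries absent from
#' the network are dropped with a warning; if none remain, an error is
#' raised.
#'
#' @param net A `gene_network` object.
#' @param queries Character vector of query gene identifiers.
#' @return Character vector of candidate genes (sorted).
#' @export
gba_candidates <- function(net, queries) {
  missing <- setdiff(queries, net$nodes)
  if (length(missing))
    warn_fgnet(length(missing), " query gene(s) absent from the network ",
               "dropped: ", paste(head(missing, 5), collapse = ", "))
  queries <- intersect(queries, net$nodes)
  if (!length(queries)) stop_fgnet("no query gene is present in the network")
  nb <- unlist(lapply(queries, net_neighbors, net = net), use.names = FALSE)
  sort(setdiff(unique(nb), queries))
}

#' Extract the largest query-plus-candidate module
#'
#' Induces the subgraph on queries and candidates and keeps its largest
#' connected component — the densest functional module the queries anchor.
#'
#' @param net A `gene_network` object.
#' @param queries Query gene identifiers.
#' @param candidates Candidate genes, typically from [gba_candidates].
#' @return List with `network` (the component as a `gene_network`),
#'   `queries` and `candidates` (the members falling inside it).
#' @export
extract_module <- function(net, queries, candidates) {
  members <- intersect(c(queries, candidates), net$nodes)
  keep <- net$edges$from %in% members & net$edges$to %in% members
  sub <- net$edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sub, directed = FALSE,
                                     vertices = data.frame(name = members))
  comps <- igraph::components(g)
  in_giant <- names(comps$membership)[comps$membership ==
                                        which.max(comps$csize)]
  keep2 <- sub$from %in% in_giant & sub$to %in% in_giant
  modnet <- structure(list(nodes = sort(in_giant),
                           edges = sub[keep2, , drop = FALSE],
                           threshold = net$threshold, aspect = net$aspect),
                      class = "gene_network")
  rownames(modnet$edges) <- NULL
  list(network = modnet,
       queries = sort(intersect(queries, in_giant)),
       candidates = sort(intersect(candidates, in_giant)))
}

#' Weighted-rating prioritization of module candidates
#'
#' For each candidate, v counts its query neighbours inside the module and F
#' averages the weights of the edges linking it to them. The weighted rating
#' shrinks F toward the cross-candidate mean C according to the neighbour
#' count: `WR = v/(v+m) * F + m/(v+m) * C`, with the prior count m set to
#' the first quartile (linear-interpolation quantile) of the candidates'
#' v distribution. Candidates are ranked by WR descending, ties broken
#' lexicographically by gene identifier.
#'
#' @param module List from [extract_module] (fields `network`, `queries`,
#'   `candidates`).
#' @param queries Optional override of the query set (defaults to
#'   `module$queries`).
#' @return A `wr_ranking`: data frame `gene`, `v`, `F`, `wr`, `rank` with
#'   attributes `m` and `C`.
#' @export
wr_scores <- function(module, queries = module$queries) {
  net <- module$network
  cands <- module$candidates
  v <- integer(0); f <- numeric(0); kept <- character(0)
  for (g in cands) {
    sel <- (net$edges$from == g & net$edges$to %in% queries) |
           (net$edges$to == g & net$edges$from %in% queries)
    vi <- sum(sel)
    if (vi == 0L) next
    kept <- c(kept, g); v <- c(v, vi)
    f <- c(f, mean(net$edges$weight[sel]))
  }
  if (length(kept) < length(cands))
    warn_fgnet(length(cands) - length(kept),
               " candidate(s) without a query neighbour excluded")
  if (!length(kept)) stop_fgnet("no candidate is adjacent to a query gene")
  m <- unname(quantile(v, 0.25, type = 7))
  C <- mean(f)
  wr <- v / (v + m) * f + m / (v + m) * C
  out <- data.frame(gene = kept, v = v, F = f, wr = wr,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$wr, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, m = m, C = C, class = c("wr_ranking", "data.frame"))
}

#' @export
print.wr_ranking <- function(x, ...) {
  cat(sprintf("WR ranking of %d candidates (m = %.3g, C = %.4f)\n",
              nrow(x), attr(x, "m"), attr(x, "C")))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Status summary of classified candidates
#'
#' Tallies candidates by status label with percentages to two decimals, and
#' reports the percent increase of all identified genes (known plus newly
#' predicted) over the previously known ones, to one decimal.
#'
#' @param candidates Character vector of candidate genes.
#' @param status_labels Named character vector (names = genes) or unnamed
#'   vector aligned with `candidates`; values among `"known"`,
#'   `"predicted"`, `"unknown"`, `"false_positive"`.
#' @return List with `counts`, `percentages` (2 decimals), `n_identified`,
#'   and `pct_increase` (1 decimal; `NA` when nothing was previously known).
#' @export
classification_summary <- function(candidates,
                                   status_labels) {
  if (!is.null(names(status_labels)))
    status_labels <- status_labels[candidates]
  if (length(status_labels) != length(candidates) || anyNA(status_labels))
    stop_fgnet("every candidate must carry a status label")
  lv <- c("known", "predicted", "unknown", "false_positive")
  if (!all(status_labels %in% lv))
    stop_fgnet("unknown status label(s): ",
               paste(setdiff(status_labels, lv), collapse = ", "))
  counts <- table(factor(status_labels, levels = lv))
  total <- length(candidates)
  pct <- round(100 * as.numeric(counts) / total, 2)
  names(pct) <- lv
  identified <- sum(counts[c("known", "predicted")])
  known <- counts[["known"]]
  list(counts = setNames(as.integer(counts), lv),
       percentages = pct,
       n_identified = as.integer(identified),
       pct_increase = if (known > 0)
         round(100 * (identified - known) / known, 1) else NA_real_)
}

#' One-step Gaussian label-propagation smoothing (extension)
#'
#' An optional extension to the direct-neighbour rule: seed labels 1 on the
#' queries and diffuse them one step through the weight-normalised adjacency,
#' blending with the seed by `alpha`. Candidate discovery itself uses
#' [gba_candidates]; this smoother only refines scores.
#'
#' @param net A `gene_network` object.
#' @param queries Query gene identifiers.
#' @param alpha Diffusion weight in \[0, 1\] (default 0.5): 0 returns the
#'   seed labels, 1 the fully diffused ones.
#' @return Named numeric vector of smoothed scores over `net$nodes`.
#' @export
gba_diffusion <- function(net, queries, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  seed <- setNames(as.numeric(net$nodes %in% queries), net$nodes)
  num <- setNames(numeric(length(net$nodes)), net$nodes)
  den <- num
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$from[i]; b <- net$edges$to[i]; w <- net$edges$weight[i]
    num[a] <- num[a] + w * seed[b]; den[a] <- den[a] + w
    num[b] <- num[b] + w * seed[a]; den[b] <- den[b] + w
  }
  den[den == 0] <- 1
  (1 - alpha) * seed + alpha * num / den
}

#' Write a WR ranking as TSV
#'
#' Columns: gene, v, F, wr, rank.
#'
#' @param ranking A `wr_ranking` object.
#' @param path Output path.
#' @return Invisibly, `ranking`.
#' @export
write_ranking <- function(ranking, path) {
  write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(ranking)
}
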