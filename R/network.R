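# Resolve the weight column for an aspect from a similarity/edge table.
weight_column <- function(pairs, aspect) {
  col <- switch(aspect, INT = "s_int", BP = "s_bp", MF = "s_mf", CC = "s_cc")
  if (!is.null(col) && col %in% names(pairs)) return(col)
  if ("weight" %in% names(pairs)) return("weight")
  stop_fgnet("no weight column for aspect ", aspect, " in the pair table")
}

pair_columns <- function(pairs) {
  if (all(c("gene_a", "gene_b") %in% names(pairs))) c("gene_a", "gene_b")
  else if (all(c("from", "to") %in% names(pairs))) c("from", "to")
  else stop_fgnet("pair table must have gene_a/gene_b or from/to columns")
}

#' Build a thresholded weighted gene network
#'
#' Keeps every gene pair whose functional similarity is at least the
#' threshold and connects it by an edge weighted with that similarity.
#' Genes left without any surviving edge are excluded from the node set, so
#' the network shrinks as the threshold rises.
#'
#' @param pairs Data frame of gene pairs: columns `gene_a`/`gene_b` (or
#'   `from`/`to`) plus a weight column (`s_bp`/`s_mf`/`s_cc`/`s_int` chosen
#'   by `aspect`, or a generic `weight`).
#' @param aspect One of `"INT"`, `"BP"`, `"MF"`, `"CC"` (selects the weight
#'   column of a similarity table).
#' @param threshold Edge-weight cutoff in \[0, 1\].
#' @return A `gene_network` object: list with `nodes`, `edges` (data frame
#'   `from`, `to`, `weight`), `threshold`, `aspect`.
#' @export
build_network <- function(pairs, aspect = "INT", threshold = 0) {
  stopifnot(threshold >= 0, threshold <= 1)
  pc <- pair_columns(pairs)
  w <- pairs[[weight_column(pairs, aspect)]]
  keep <- w >= threshold & pairs[[pc[1]]] != pairs[[pc[2]]]
  edges <- data.frame(from = pairs[[pc[1]]][keep],
                      to = pairs[[pc[2]]][keep],
                      weight = w[keep], stringsAsFactors = FALSE)
  # canonical unordered orientation, then dedupe
  flip <- edges$from > edges$to
  tmp <- edges$from[flip]; edges$from[flip] <- edges$to[flip]
  edges$to[flip] <- tmp
  edges <- edges[!duplicated(edges[c("from", "to")]), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$from, edges$to))),
                 edges = edges, threshold = threshold, aspect = aspect),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Gene network (%s): %d nodes, %d edges, threshold %.2f\n",
              x$aspect, length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Convert a gene network to an igraph graph
#'
#' @param net A `gene_network` (or reference network) object.
#' @return An undirected weighted `igraph` graph.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Average clustering coefficient of a network
#'
#' The mean over all nodes of the local clustering coefficient
#' `C_i = 2 e_i / (k_i (k_i - 1))`, where `e_i` counts edges among node i's
#' neighbours; nodes of degree below 2 contribute `C_i = 0`. An empty
#' network returns 0.
#'
#' @param net A `gene_network` object.
#' @return Scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  if (!length(net$nodes) || !nrow(net$edges)) return(0)
  g <- as_igraph(net)
  mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
}

#' Expected clustering coefficient of a degree-matched random network
#'
#' The configuration-model expectation computed from the degree sequence:
#' `(<k^2> - <k>)^2 / (N <k>^3)`. Returns 0 for an empty degree sequence or
#' zero mean degree.
#'
#' @param net A `gene_network` object.
#' @return Non-negative scalar.
#' @export
random_clustering_expectation <- function(net) {
  k <- node_degrees(net)
  if (!length(k) || mean(k) == 0) return(0)
  (mean(k^2) - mean(k))^2 / (length(k) * mean(k)^3)
}

node_degrees <- function(net) {
  if (!nrow(net$edges)) return(setNames(integer(0), character(0)))
  tab <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes))
  setNames(as.integer(tab), names(tab))
}

#' Clustering-gap threshold scan
#'
#' Builds the network at every threshold on a 0.00..1.00 grid (step 0.01)
#' and records the observed clustering coefficient, the degree-matched
#' random expectation, and their gap delta = c_obs - c_rand. The selected
#' threshold is the first peak of delta scanning upward from 0.01: the
#' smallest grid value whose delta is not exceeded by the next grid point
#' (plateaus stop the increasing run). A delta that still rises at the end
#' of the grid selects 1.00 with a warning.
#'
#' @inheritParams build_network
#' @param grid Numeric vector of thresholds (default `seq(0, 1, 0.01)`).
#' @param c_rand_fun Strategy computing the random expectation from a
#'   network; default [random_clustering_expectation].
#' @return A `threshold_scan` object: data frame `threshold`, `nodes`,
#'   `edges`, `c_obs`, `c_rand`, `delta` with attribute `selected`.
#' @export
threshold_scan <- function(pairs, aspect = "INT", grid = seq(0, 1, by = 0.01),
                           c_rand_fun = random_clustering_expectation) {
  w <- pairs[[weight_column(pairs, aspect)]]
  if (all(w == 0)) stop_fgnet("all similarities are zero; nothing to scan")
  res <- data.frame(threshold = grid, nodes = NA_integer_,
                    edges = NA_integer_, c_obs = NA_real_,
                    c_rand = NA_real_, delta = NA_real_)
  for (i in seq_along(grid)) {
    net <- build_network(pairs, aspect, grid[i])
    res$nodes[i] <- length(net$nodes)
    res$edges[i] <- nrow(net$edges)
    res$c_obs[i] <- clustering_coefficient(net)
    res$c_rand[i] <- c_rand_fun(net)
    res$delta[i] <- res$c_obs[i] - res$c_rand[i]
  }
  sel <- select_first_peak(res$delta, grid)
  structure(res, selected = sel, aspect = aspect,
            class = c("threshold_scan", "data.frame"))
}

# First peak of delta on the grid, scanning upward from the second grid
# point (the unfiltered complete table at threshold 0 takes no part).
select_first_peak <- function(delta, grid) {
  for (i in 2:(length(grid) - 1L))
    if (delta[i] >= delta[i + 1L]) return(grid[i])
  warn_fgnet("delta increases through the whole grid; selecting ",
             grid[length(grid)])
  grid[length(grid)]
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("Threshold scan (%s): %d grid points, selected threshold %.2f\n",
              attr(x, "aspect"), nrow(x), attr(x, "selected")))
  i <- which(x$threshold == attr(x, "selected"))
  cat(sprintf("  at selection: %d nodes, %d edges, c_obs %.4f, c_rand %.4f\n",
              x$nodes[i], x$edges[i], x$c_obs[i], x$c_rand[i]))
  invisible(x)
}

#' @export
plot.threshold_scan <- function(x, ...) {
  graphics::plot(x$threshold, x$delta, type = "l", col = "red",
                 xlab = "threshold", ylab = expression(Delta * C), ...)
  graphics::lines(x$threshold, x$c_obs, col = "blue")
  graphics::lines(x$threshold, x$c_rand, col = "darkgreen")
  graphics::abline(v = attr(x, "selected"), lty = 2)
  graphics::legend("topleft", legend = c("c_obs", "c_rand", "delta"),
                   col = c("blue", "darkgreen", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Global topological properties of a network
#'
#' Node and edge counts, clustering coefficient, connected components,
#' diameter and radius of the largest component, characteristic path length
#' (mean shortest path over connected pairs), mean neighbour count, density,
#' degree centralisation, and heterogeneity (coefficient of variation of the
#' degree sequence).
#'
#' @param net A `gene_network` object.
#' @return Named list of properties.
#' @export
global_properties <- function(net) {
  g <- as_igraph(net)
  n <- length(net$nodes)
  k <- igraph::degree(g)
  comps <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, names(comps$membership)[comps$membership == which.max(comps$csize)])
  list(
    nodes = n,
    edges = nrow(net$edges),
    clustering_coefficient = clustering_coefficient(net),
    components = comps$no,
    diameter = if (n) igraph::diameter(giant, weights = NA) else 0,
    radius = if (n) igraph::radius(giant) else 0,
    characteristic_path_length = if (n) igraph::mean_distance(g) else 0,
    mean_neighbors = if (n) mean(k) else 0,
    density = if (n > 1) igraph::edge_density(g) else 0,
    centralisation = if (n > 2)
      igraph::centr_degree(g, loops = FALSE)$centralization else 0,
    heterogeneity = if (n && mean(k) > 0)
      sqrt(mean(k^2) / mean(k)^2 - 1) else 0)
}

#' Write a network as a weighted edge list or SIF file
#'
#' @param net A `gene_network` object.
#' @param path Output path.
#' @param format `"tsv"` (columns from, to, weight) or `"sif"`
#'   (`from<TAB>sim<TAB>to`).
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(paste(net$edges$from, "sim", net$edges$to, sep = "\t"), path)
  }
  invisible(net)
}

#' Write a threshold scan as TSV plus a JSON summary
#'
#' @param scan A `threshold_scan` object.
#' @param tsv_path,json_path Output paths (either may be NULL to skip).
#' @return Invisibly, `scan`.
#' @export
write_scan <- function(scan, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    write.table(as.data.frame(scan), tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(aspect = attr(scan, "aspect"), selected = attr(scan, "selected"),
           grid_points = nrow(scan)),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(scan)
}
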