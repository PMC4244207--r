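new_reference <- function(from, to, kind) {
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  flip <- from > to
  tmp <- from[flip]; from[flip] <- to[flip]; to[flip] <- tmp
  edges <- unique(data.frame(from = from, to = to,
                             weight = rep(1, length(from)),
                             stringsAsFactors = FALSE))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$from, edges$to))),
                 edges = edges, threshold = NA_real_, aspect = kind,
                 kind = kind),
            class = "gene_network")
}

#' Reference network from shared pathway membership
#'
#' Links every pair of genes annotated to the same pathway term (a clique
#' per term), unioned over terms and deduplicated — the construction used
#' for pathway-derived benchmark networks such as those from KEGG LinkDB
#' gene/KO link tables.
#'
#' @param links Data frame (or two-column table): gene identifiers in
#'   column 1, pathway/KO terms in column 2.
#' @return A `gene_network` with `kind = "kegg"` and unit edge weights.
#' @export
kegg_reference <- function(links) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  gene <- as.character(links[[1]]); term <- as.character(links[[2]])
  from <- character(); to <- character()
  for (members in split(gene, term)) {
    members <- unique(members)
    if (length(members) < 2L) next
    prs <- combn(sort(members), 2L)
    from <- c(from, prs[1, ]); to <- c(to, prs[2, ])
  }
  if (!length(from)) stop_fgnet("no pathway term is shared by two genes")
  new_reference(from, to, "kegg")
}

#' Reference network from co-expression profiles
#'
#' Datasets with fewer than `min_samples` samples are discarded. Within each
#' remaining dataset two genes are linked when the absolute Pearson
#' correlation of their expression profiles exceeds `pcc_cutoff` (strictly).
#' The final network is the union of per-dataset linkages. Genes with
#' constant expression in a dataset have undefined correlations; their pairs
#' are skipped with a warning.
#'
#' @param datasets List of numeric matrices, genes in rows (rownames = gene
#'   identifiers), samples in columns.
#' @param min_samples Minimum sample count for a dataset to be used
#'   (default 20).
#' @param pcc_cutoff Absolute-correlation cutoff, exceeded strictly
#'   (default 0.8).
#' @return A `gene_network` with `kind = "coexpression"`.
#' @export
coexpression_reference <- function(datasets, min_samples = 20,
                                   pcc_cutoff = 0.8) {
  if (!is.list(datasets)) datasets <- list(datasets)
  from <- character(); to <- character()
  n_used <- 0L
  for (mat in datasets) {
    if (ncol(mat) < min_samples) next
    n_used <- n_used + 1L
    sds <- apply(mat, 1, sd)
    if (any(sds == 0)) {
      warn_fgnet(sum(sds == 0), " constant-expression gene(s) skipped in a ",
                 "dataset (undefined correlation)")
      mat <- mat[sds > 0, , drop = FALSE]
    }
    if (nrow(mat) < 2L) next
    cc <- cor(t(mat))
    hit <- which(abs(cc) > pcc_cutoff & upper.tri(cc), arr.ind = TRUE)
    if (nrow(hit)) {
      from <- c(from, rownames(mat)[hit[, 1]])
      to <- c(to, rownames(mat)[hit[, 2]])
    }
  }
  if (n_used == 0L) stop_fgnet("every dataset has fewer than ", min_samples,
                               " samples")
  if (!length(from))
    stop_fgnet("no gene pair exceeds the correlation cutoff")
  new_reference(from, to, "coexpression")
}

#' Reference network transferred through orthology
#'
#' For every edge (a, b) of a source-species network and every ortholog a'
#' of a and b' of b, adds the target-species edge (a', b'); self-pairs are
#' dropped and duplicates collapsed.
#'
#' @param source_edges Data frame/two-column table of source-species edges.
#' @param orthologs Data frame/two-column table mapping source genes
#'   (column 1) to target genes (column 2); may be one-to-many.
#' @return A `gene_network` with `kind = "orthology"`.
#' @export
orthology_transfer <- function(source_edges, orthologs) {
  source_edges <- as.data.frame(source_edges, stringsAsFactors = FALSE)
  orthologs <- as.data.frame(orthologs, stringsAsFactors = FALSE)
  omap <- split(as.character(orthologs[[2]]), as.character(orthologs[[1]]))
  from <- character(); to <- character()
  for (i in seq_len(nrow(source_edges))) {
    a <- omap[[as.character(source_edges[i, 1])]]
    b <- omap[[as.character(source_edges[i, 2])]]
    if (is.null(a) || is.null(b)) next
    grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    from <- c(from, grid$a); to <- c(to, grid$b)
  }
  if (!length(from)) stop_fgnet("no source edge maps to the target species")
  new_reference(from, to, "orthology")
}

edge_keys <- function(net) {
  paste(net$edges$from, net$edges$to, sep = "\r")
}

#' Coverage and accuracy percentages
#'
#' The two ratio statistics of network validation, reported to two decimals:
#' gene coverage `Cg = 100 * Ns / Nk` (shared genes over reference genes)
#' and linkage accuracy `La = 100 * Ls / Lk` (shared links over compared
#' links).
#'
#' @param n_shared Count of shared genes (or links).
#' @param n_total Reference gene count (or compared link count).
#' @return Percentage rounded to 2 decimals; `NA` when `n_total` is 0.
#' @export
gene_coverage <- function(n_shared, n_total) {
  ifelse(n_total > 0, round(100 * n_shared / n_total, 2), NA_real_)
}

#' @rdname gene_coverage
#' @export
linkage_accuracy <- gene_coverage

#' Gene coverage and linkage accuracy of a query network
#'
#' Gene coverage Cg = 100 * Ns / Nk, where Ns counts genes shared by query
#' and reference and Nk the reference's genes. Linkage accuracy
#' La = 100 * Ls / Lk. By default (`la_mode = "query"`) Lk counts query
#' edges whose endpoints are both shared genes and Ls those of them also
#' present in the reference, so La is a true precision in \[0, 100\]. With
#' `la_mode = "reference"` the denominator is instead the reference's edge
#' count among shared genes.
#'
#' @param query,ref `gene_network` objects.
#' @param la_mode `"query"` (default) or `"reference"`.
#' @return A `validation_report`: list with `n_shared_genes`,
#'   `n_reference_genes`, `gene_coverage_pct`, `n_query_links_shared`,
#'   `n_reference_links`, `linkage_accuracy_pct` (percentages to 2
#'   decimals; `NA` with `degenerate = TRUE` when a denominator is 0).
#' @export
coverage_accuracy <- function(query, ref, la_mode = c("query", "reference")) {
  la_mode <- match.arg(la_mode)
  shared <- intersect(query$nodes, ref$nodes)
  ns <- length(shared); nk <- length(ref$nodes)
  q_in <- query$edges$from %in% shared & query$edges$to %in% shared
  r_in <- ref$edges$from %in% shared & ref$edges$to %in% shared
  qk <- edge_keys(query)[q_in]
  rk <- edge_keys(ref)[r_in]
  ls <- sum(qk %in% rk)
  lk <- if (la_mode == "query") sum(q_in) else sum(r_in)
  degenerate <- nk == 0L || lk == 0L
  structure(list(
    n_shared_genes = ns,
    n_reference_genes = nk,
    gene_coverage_pct = gene_coverage(ns, nk),
    n_query_links_shared = ls,
    n_reference_links = lk,
    linkage_accuracy_pct = linkage_accuracy(ls, lk),
    la_mode = la_mode, degenerate = degenerate,
    reference_kind = ref$kind %||% ref$aspect),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation against", x$reference_kind, "reference\n")
  cat(sprintf("  gene coverage Cg: %d/%d = %.2f%%\n",
              x$n_shared_genes, x$n_reference_genes, x$gene_coverage_pct))
  cat(sprintf("  linkage accuracy La: %d/%d = %.2f%%\n",
              x$n_query_links_shared, x$n_reference_links,
              x$linkage_accuracy_pct))
  if (!is.null(x$background_mean_accuracy))
    cat(sprintf("  background La: %.2f%% (400-rewiring mean), p = %.4g\n",
                x$background_mean_accuracy, x$p_value))
  invisible(x)
}

#' Linkage accuracy of degree-preserving randomized backgrounds
#'
#' Rewires the query network `n_random` times by uniform double-edge swaps
#' that preserve every node's degree (rejecting loops and multi-edges,
#' 10 * |E| accepted swaps per replicate), computes the linkage accuracy of
#' each randomized network against the reference, and reports the empirical
#' one-sided significance of the observed accuracy (rank-based, add-one
#' corrected).
#'
#' @inheritParams coverage_accuracy
#' @param n_random Number of randomized replicates (default 400).
#' @param seed Optional integer seed for the rewiring RNG.
#' @return A `validation_report` with the additional fields
#'   `background_mean_accuracy`, `background_sd`, `p_value`, and
#'   `background_la` (per-replicate accuracies).
#' @export
randomized_background <- function(query, ref, n_random = 400, seed = NULL,
                                  la_mode = c("query", "reference")) {
  la_mode <- match.arg(la_mode)
  if (nrow(query$edges) < 2L)
    stop_fgnet("query network needs at least 2 edges to rewire")
  if (!is.null(seed)) set.seed(seed)
  report <- coverage_accuracy(query, ref, la_mode)
  bg <- vapply(seq_len(n_random), function(i) {
    coverage_accuracy(rewire_network(query), ref,
                      la_mode)$linkage_accuracy_pct
  }, numeric(1))
  if (all(bg == report$linkage_accuracy_pct, na.rm = TRUE))
    warn_fgnet("rewiring left the accuracy unchanged in every replicate")
  report$background_mean_accuracy <- mean(bg, na.rm = TRUE)
  report$background_sd <- sd(bg, na.rm = TRUE)
  report$p_value <-
    (1 + sum(bg >= report$linkage_accuracy_pct, na.rm = TRUE)) /
    (n_random + 1)
  report$background_la <- bg
  report
}

#' Degree-preserving randomization of a network
#'
#' Applies uniform double-edge swaps (rejecting swaps that would create a
#' self-loop or duplicate edge), leaving every node's degree unchanged.
#'
#' @param net A `gene_network` object.
#' @param niter Number of accepted swaps (default 10 times the edge count).
#' @return A rewired `gene_network` over the same node set, edge weights
#'   reset to 1.
#' @export
rewire_network <- function(net, niter = 10L * nrow(net$edges)) {
  g <- as_igraph(net)
  rg <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
  el <- igraph::as_data_frame(rg, what = "edges")
  out <- new_reference(el$from, el$to, "rewired")
  out$nodes <- net$nodes  # keep the full node set in place
  out
}

#' One-way ANOVA of observed versus background accuracies
#'
#' When several query networks are validated against the same reference,
#' compares their randomized-background accuracy distributions by one-way
#' ANOVA. The per-network empirical p-value from [randomized_background]
#' remains the primary significance measure for a single network.
#'
#' @param backgrounds Named list of numeric vectors of per-replicate
#'   background accuracies, one per query network.
#' @return The fitted `aov` object.
#' @export
la_anova <- function(backgrounds) {
  stopifnot(length(backgrounds) >= 2L)
  df <- data.frame(
    la = unlist(backgrounds, use.names = FALSE),
    network = factor(rep(names(backgrounds), lengths(backgrounds))))
  stats::aov(la ~ network, data = df)
}
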