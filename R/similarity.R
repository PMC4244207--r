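#' SSDD semantic distance and similarity between two terms
#'
#' The shortest semantic differentiation distance between two terms sums the
#' T-values of every term on the shortest path connecting them through a
#' lowest common ancestor, then normalises the sum into (0, 1) with
#' `(2/pi) * arctan(.)`. Similarity is one minus the distance.
#'
#' Under the literal path rule the self-similarity of a term is below 1
#' (its path is the term itself, whose T-value is positive); set
#' `identical_term_sim = 1` to force sim(t, t) = 1 instead.
#'
#' @param ont A `go_ontology`.
#' @param stats A `term_stats` object.
#' @param t1,t2 Term identifiers. A cross-aspect pair yields similarity 0
#'   with a warning rather than an error.
#' @param identical_term_sim Either `"literal"` (default) or the number 1.
#' @return Scalar similarity in (0, 1). The corresponding distance is
#'   `1 - similarity`; see [ssdd_distance].
#' @export
ssdd_similarity <- function(ont, stats, t1, t2, identical_term_sim = "literal") {
  if (ont$aspect[t1] != ont$aspect[t2]) {
    warn_fgnet("cross-aspect term pair (", t1, ", ", t2, "): similarity 0")
    return(0)
  }
  if (t1 == t2 && identical(identical_term_sim, 1)) return(1)
  1 - ssdd_distance(ont, stats, t1, t2)
}

#' @rdname ssdd_similarity
#' @export
ssdd_distance <- function(ont, stats, t1, t2) {
  path <- lca_shortest_path(ont, stats, t1, t2)
  (2 / pi) * atan(sum(stats$t_value[path]))
}

#' Best-match-average similarity of two term sets
#'
#' Each term of the first set is paired with its most similar term in the
#' second set and vice versa; the two directional means are averaged. An
#' empty set on either side yields similarity 0 (the gene is simply not
#' annotated in this aspect), not an error.
#'
#' @inheritParams ssdd_similarity
#' @param terms_a,terms_b Character vectors of term identifiers (one
#'   gene's annotations in one aspect).
#' @param cache Optional environment memoising term-pair similarities
#'   across calls (keys `"t1|t2"` with t1 <= t2).
#' @return Scalar in \[0, 1\].
#' @export
bma_gene_similarity <- function(ont, stats, terms_a, terms_b,
                                identical_term_sim = "literal",
                                cache = NULL) {
  if (!length(terms_a) || !length(terms_b)) return(0)
  sim1 <- function(a, b) {
    if (is.null(cache))
      return(ssdd_similarity(ont, stats, a, b, identical_term_sim))
    key <- if (a <= b) paste0(a, "|", b) else paste0(b, "|", a)
    val <- cache[[key]]
    if (is.null(val)) {
      val <- ssdd_similarity(ont, stats, a, b, identical_term_sim)
      cache[[key]] <- val
    }
    val
  }
  m <- matrix(0, length(terms_a), length(terms_b))
  for (i in seq_along(terms_a))
    for (j in seq_along(terms_b))
      m[i, j] <- sim1(terms_a[[i]], terms_b[[j]])
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

#' Similarity-weighted integration of the three aspect similarities
#'
#' Combines per-aspect functional similarities with each aspect weighted by
#' its own similarity: `(s_bp^2 + s_mf^2 + s_cc^2) / (s_bp + s_mf + s_cc)`.
#' The aspect in which a gene pair is most alike dominates, and a zero in
#' one aspect cannot collapse the integrated value. All-zero input returns 0.
#'
#' @param s_bp,s_mf,s_cc Numeric vectors in \[0, 1\] (recycled together).
#' @return Numeric vector of integrated similarities in \[0, 1\].
#' @export
integrate_aspects <- function(s_bp, s_mf, s_cc) {
  s <- cbind(s_bp, s_mf, s_cc)
  if (any(s < 0 | s > 1))
    stop_fgnet("aspect similarities must lie in [0, 1]")
  tot <- rowSums(s)
  out <- ifelse(tot > 0, rowSums(s^2) / tot, 0)
  unname(out)
}

#' Functional similarity of one gene pair
#'
#' @inheritParams bma_gene_similarity
#' @param ann A `go_annotations` object.
#' @param gene_a,gene_b Gene identifiers.
#' @return Named list with `s_bp`, `s_mf`, `s_cc`, `s_int`.
#' @export
gene_similarity <- function(ont, stats, ann, gene_a, gene_b,
                            identical_term_sim = "literal", cache = NULL) {
  s <- vapply(ASPECTS, function(a)
    bma_gene_similarity(ont, stats,
                        ann$by_aspect[[a]][[gene_a]],
                        ann$by_aspect[[a]][[gene_b]],
                        identical_term_sim, cache),
    numeric(1))
  list(s_bp = s[["BP"]], s_mf = s[["MF"]], s_cc = s[["CC"]],
       s_int = integrate_aspects(s[["BP"]], s[["MF"]], s[["CC"]]))
}

#' Number of unordered gene pairs
#'
#' @param n Non-negative integer count of genes.
#' @return `n * (n - 1) / 2` as a double (exact well beyond 2^31).
#' @examples
#' pair_count(27594)  # 380700621
#' @export
pair_count <- function(n) {
  stopifnot(all(n >= 0))
  n <- as.numeric(n)
  n * (n - 1) / 2
}

#' All-pairs gene functional similarity table
#'
#' Emits every unordered pair of the relevant gene universe exactly once:
#' for a single aspect the genes annotated in that aspect; for `"INT"` the
#' union of genes annotated in any aspect. Computed block-wise with a shared
#' term-pair cache; output is sorted by gene pair for deterministic files.
#'
#' @inheritParams gene_similarity
#' @param aspect `"INT"` (default), `"BP"`, `"MF"` or `"CC"`.
#' @param block_size Number of pairs per computation block.
#' @param file Optional path; when given, blocks are appended to a TSV as
#'   they are computed and the table is also returned invisibly.
#' @return Data frame `gene_a`, `gene_b`, `s_bp`, `s_mf`, `s_cc`, `s_int`.
#' @export
all_pairs_similarity <- function(ont, stats, ann, aspect = "INT",
                                 identical_term_sim = "literal",
                                 block_size = 10000L, file = NULL) {
  aspect <- match.arg(aspect, c("INT", ASPECTS))
  universe <- if (aspect == "INT") ann$genes
              else sort(names(ann$by_aspect[[aspect]]))
  n <- length(universe)
  if (n < 2L) stop_fgnet("need at least two genes in the ", aspect, " universe")
  cache <- new.env(parent = emptyenv())
  ij <- combn(n, 2L)
  total <- ncol(ij)
  chunks <- split(seq_len(total), ceiling(seq_len(total) / block_size))
  out <- vector("list", length(chunks))
  first <- TRUE
  for (ci in seq_along(chunks)) {
    idx <- chunks[[ci]]
    block <- data.frame(
      gene_a = universe[ij[1, idx]], gene_b = universe[ij[2, idx]],
      s_bp = NA_real_, s_mf = NA_real_, s_cc = NA_real_, s_int = NA_real_,
      stringsAsFactors = FALSE)
    for (k in seq_len(nrow(block))) {
      s <- gene_similarity(ont, stats, ann, block$gene_a[k], block$gene_b[k],
                           identical_term_sim, cache)
      block[k, 3:6] <- unlist(s)
    }
    if (!is.null(file)) {
      write.table(block, file, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = first, append = !first)
      first <- FALSE
    }
    out[[ci]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(file)) invisible(res) else res
}
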