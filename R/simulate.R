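# Seeded generators for every input the pipeline consumes. Each generator
# records ground truth computed by its own independent bookkeeping (brute
# force, not the package's production code paths), so downstream stages can
# be tested without external downloads.

# --- independent truth helpers (deliberately naive) -------------------------

# descendants (incl. self) by recursive child expansion
brute_descendants <- function(children, term) {
  seen <- character(0)
  stack <- term
  while (length(stack)) {
    t <- stack[[1]]; stack <- stack[-1]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, children[[t]])
  }
  length(seen)
}

# T-value by direct top-down recursion of the averaging rule
brute_t_value <- function(parents, desc, term, memo = new.env()) {
  if (!is.null(memo[[term]])) return(memo[[term]])
  ps <- parents[[term]]
  val <- if (!length(ps)) 1
         else mean(vapply(ps, function(p)
           (desc[[term]] / desc[[p]]) * brute_t_value(parents, desc, p, memo),
           numeric(1)))
  memo[[term]] <- val
  val
}

#' Simulate a toy ontology
#'
#' Generates one single-rooted random DAG per aspect: terms are added in
#' order, each drawing one or (with probability `p_multi_parent`) two
#' parents among the existing terms. Ground-truth descendant counts and
#' T-values are computed by the generator's own brute-force recursion and
#' returned alongside, so they can serve as an oracle for the production
#' code paths.
#'
#' @param n_terms Named integer vector of term counts per aspect, e.g.
#'   `c(BP = 15, MF = 10, CC = 8)`. Aspects may be omitted (at least one
#'   required); each aspect needs >= 2 terms.
#' @param p_multi_parent Probability that a non-root term has two parents.
#' @param seed Integer seed; identical seed and sizes give identical output.
#' @param obo_path Optional path; when given, the ontology is also written
#'   as an OBO file (extra parents become `relationship: part_of` lines when
#'   `use_part_of` is TRUE).
#' @param use_part_of Write second parents as `part_of` relationships.
#' @return List with `ontology` (a `go_ontology`), `truth` (data frame
#'   `term`, `aspect`, `descendant_count`, `t_value`), and `obo_path`.
#' @export
simulate_ontology <- function(n_terms = c(BP = 15, MF = 10, CC = 8),
                              p_multi_parent = 0.3, seed = 1,
                              obo_path = NULL, use_part_of = TRUE) {
  stopifnot(length(n_terms) >= 1, all(n_terms >= 2))
  set.seed(seed)
  term <- character(); aspect <- character()
  parent_from <- character(); parent_to <- character()
  part_of_edge <- logical(0)
  for (asp in names(n_terms)) {
    ids <- sprintf("GO:%s%04d", asp, seq_len(n_terms[[asp]]))
    term <- c(term, ids); aspect <- c(aspect, rep(asp, length(ids)))
    for (i in seq_along(ids)[-1]) {
      k <- if (i > 2 && runif(1) < p_multi_parent) 2L else 1L
      ps <- sample(ids[seq_len(i - 1L)], k)
      parent_from <- c(parent_from, rep(ids[i], k))
      parent_to <- c(parent_to, ps)
      part_of_edge <- c(part_of_edge, c(FALSE, use_part_of)[seq_len(k)])
    }
  }
  ont <- new_ontology(term, parent_from, parent_to, aspect)

  children <- split(parent_from, factor(parent_to, levels = term))
  parents <- split(parent_to, factor(parent_from, levels = term))
  desc <- vapply(term, function(t) brute_descendants(children, t), numeric(1))
  memo <- new.env()
  tv <- vapply(term, function(t) brute_t_value(parents, desc, t, memo),
               numeric(1))
  truth <- data.frame(term = term, aspect = aspect,
                      descendant_count = as.integer(desc), t_value = tv,
                      row.names = NULL, stringsAsFactors = FALSE)

  if (!is.null(obo_path)) {
    ns_long <- c(BP = "biological_process", MF = "molecular_function",
                 CC = "cellular_component")
    lines <- c("format-version: 1.2", "ontology: fgnet-simulated")
    edge_idx <- split(seq_along(parent_from),
                      factor(parent_from, levels = term))
    for (i in seq_along(term)) {
      t <- term[i]
      lines <- c(lines, "", "[Term]", paste0("id: ", t),
                 paste0("name: simulated term ", t),
                 paste0("namespace: ", ns_long[aspect[i]] %||% aspect[i]))
      for (e in edge_idx[[t]]) {
        lines <- c(lines, if (part_of_edge[e])
          paste0("relationship: part_of ", parent_to[e])
          else paste0("is_a: ", parent_to[e]))
      }
    }
    writeLines(lines, obo_path)
  }
  list(ontology = ont, truth = truth, obo_path = obo_path)
}

#' Simulate module-structured gene annotations
#'
#' Partitions genes into functional modules and, per aspect, assigns each
#' module a pool of terms from which its genes draw their annotation sets;
#' pools of different modules are disjoint (zero overlap) unless
#' `pool_overlap` terms are shared. Genes of the same module therefore share
#' planted function, which the returned truth records.
#'
#' @param ont A `go_ontology` (e.g. from [simulate_ontology]).
#' @param n_genes Number of genes.
#' @param n_modules Number of planted modules.
#' @param terms_per_gene Range (length-2 integer) of annotation-set sizes.
#' @param pool_size Terms per module pool and aspect.
#' @param pool_overlap Number of pool terms shared between adjacent modules.
#' @param aspects Aspects to annotate (default: all present in `ont`).
#' @param seed Integer seed.
#' @param gaf_path Optional path to also write the annotations as GAF 2.1.
#' @return List with `annotations` (a `go_annotations`), `truth` (data frame
#'   `gene`, `module`), and `gaf_path`.
#' @export
simulate_annotations <- function(ont, n_genes = 20, n_modules = 2,
                                 terms_per_gene = c(2L, 4L),
                                 pool_size = 4L, pool_overlap = 0L,
                                 aspects = names(ont$roots), seed = 1,
                                 gaf_path = NULL) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  module <- rep(seq_len(n_modules), length.out = n_genes)
  gene_v <- character(); term_v <- character(); asp_v <- character()
  for (asp in aspects) {
    tset <- setdiff(ont$terms[ont$aspect == asp], ont$roots[asp])
    psz <- min(pool_size, length(tset) %/% n_modules)
    if (psz < 1L) stop_fgnet("aspect ", asp, " has too few terms for ",
                             n_modules, " module pools")
    shuffled <- sample(tset)
    pools <- lapply(seq_len(n_modules), function(m)
      shuffled[((m - 1L) * psz + 1L):(m * psz)])
    if (pool_overlap > 0L)
      for (m in seq_len(n_modules)[-1])
        pools[[m]] <- unique(c(
          pools[[m]], pools[[m - 1L]][seq_len(min(pool_overlap, psz))]))
    for (i in seq_len(n_genes)) {
      k <- sample(terms_per_gene[1]:terms_per_gene[2], 1)
      ts <- sample(pools[[module[i]]], min(k, length(pools[[module[i]]])))
      gene_v <- c(gene_v, rep(genes[i], length(ts)))
      term_v <- c(term_v, ts)
      asp_v <- c(asp_v, rep(asp, length(ts)))
    }
  }
  ann <- new_annotations(gene_v, term_v, asp_v,
                         provenance = list(source = "simulated", seed = seed))
  if (!is.null(gaf_path)) write_gaf(ann, gaf_path)
  list(annotations = ann,
       truth = data.frame(gene = genes, module = module,
                          stringsAsFactors = FALSE),
       gaf_path = gaf_path)
}

#' Write annotations in GAF 2.1 format
#'
#' @param ann A `go_annotations` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gaf <- function(ann, path) {
  asp_letter <- c(BP = "P", MF = "F", CC = "C")
  rows <- character()
  for (a in ASPECTS) {
    for (g in names(ann$by_aspect[[a]])) {
      for (t in ann$by_aspect[[a]][[g]]) {
        rows <- c(rows, paste(
          "FGNET", g, g, "", t, "FGNET:0000001", "IEA", "",
          asp_letter[[a]], "", "", "protein", "taxon:3847", "20260101",
          "FGNET", "", "", sep = "\t"))
      }
    }
  }
  writeLines(c("!gaf-version: 2.1", rows), path)
  invisible(path)
}

#' Simulate a similarity table with a planted threshold
#'
#' Plants disjoint cliques whose internal weights all lie at or above the
#' planted threshold, and a sparse background whose weights are stratified
#' below it: every 0.01 grid bin from `bg_min` up to the planted threshold
#' holds `bg_per_bin` background edges, so each grid step of a threshold
#' scan removes some background and the clustering gap rises until the
#' background is exhausted — the gap's first peak lands on the planted
#' value.
#'
#' @param n_genes Total genes (clique members plus background-only genes).
#' @param n_cliques Number of planted cliques.
#' @param clique_size Genes per clique (`n_cliques * clique_size` must not
#'   exceed `n_genes`).
#' @param threshold Planted threshold, a 0.01-grid value in (0.05, 0.9).
#' @param bg_per_bin Background edges per 0.01 weight bin.
#' @param bg_min Lowest background weight bin (default 0.01 so every scan step removes background).
#' @param seed Integer seed.
#' @return List with `pairs` (data frame `gene_a`, `gene_b`, `weight`) and
#'   `truth` (list `threshold`, `membership`).
#' @export
simulate_planted_network <- function(n_genes = 60, n_cliques = 3,
                                     clique_size = 10, threshold = 0.8,
                                     bg_per_bin = 1L, bg_min = 0.01,
                                     seed = 1) {
  stopifnot(n_cliques * clique_size <= n_genes,
            abs(threshold * 100 - round(threshold * 100)) < 1e-9,
            threshold > bg_min + 0.02, threshold <= 0.9)
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  membership <- rep(NA_integer_, n_genes)
  membership[seq_len(n_cliques * clique_size)] <-
    rep(seq_len(n_cliques), each = clique_size)

  from <- character(); to <- character(); w <- numeric()
  for (cl in seq_len(n_cliques)) {
    members <- genes[which(membership == cl)]
    prs <- combn(members, 2L)
    from <- c(from, prs[1, ]); to <- c(to, prs[2, ])
    w <- c(w, runif(ncol(prs), min(threshold + 0.05, 0.95), 0.99))
  }
  # Background: pendant edges from background-only genes into the cliques,
  # never two edges from one background gene into the same clique, so no
  # background edge closes a triangle. Removing one then strictly raises
  # the network clustering (the zero-clustering endpoint thins or drops
  # out; the clique endpoint's neighbourhood gets denser), which keeps the
  # clustering gap monotonically increasing up to the planted threshold.
  bg_genes <- genes[is.na(membership)]
  bins <- seq(bg_min, threshold - 0.01, by = 0.01)
  n_bg_edges <- length(bins) * bg_per_bin
  if (n_bg_edges > length(bg_genes) * n_cliques)
    stop_fgnet("not enough background genes for ", n_bg_edges,
               " triangle-free background edges")
  e <- 0L
  for (b in bins) {
    for (r in seq_len(bg_per_bin)) {
      bgg <- bg_genes[(e %% length(bg_genes)) + 1L]
      cl <- (e %/% length(bg_genes)) %% n_cliques + 1L
      anchor <- sample(genes[which(membership == cl)], 1L)
      from <- c(from, min(bgg, anchor)); to <- c(to, max(bgg, anchor))
      w <- c(w, runif(1, b, b + 0.0099))
      e <- e + 1L
    }
  }
  pairs <- data.frame(gene_a = from, gene_b = to, weight = w,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       truth = list(threshold = threshold,
                    membership = setNames(membership, genes)))
}

#' Simulate block-correlated expression datasets
#'
#' Each dataset draws gene expression from a one-factor-per-block model:
#' within a block of planted correlation rho, every gene is
#' `sqrt(rho) * z + sqrt(1 - rho) * noise` around a shared factor z, so the
#' population correlation of any within-block pair is rho; genes of
#' different blocks (and the independent filler genes) are uncorrelated.
#' Sample counts below a co-expression reader's minimum exercise dataset
#' dropping.
#'
#' @param blocks Integer vector of block sizes.
#' @param rho Numeric vector of within-block correlations (recycled).
#' @param n_independent Number of uncorrelated filler genes.
#' @param n_samples Integer vector: one dataset per entry, with that many
#'   samples.
#' @param seed Integer seed.
#' @return List with `datasets` (list of genes x samples matrices with gene
#'   rownames) and `truth` (data frame `gene`, `block`, `rho`; block `NA`
#'   for independent genes).
#' @export
simulate_expression <- function(blocks = c(10, 10), rho = c(0.95, 0.9),
                                n_independent = 10,
                                n_samples = c(100, 6), seed = 1) {
  set.seed(seed)
  rho <- rep_len(rho, length(blocks))
  n_genes <- sum(blocks) + n_independent
  genes <- sprintf("g%03d", seq_len(n_genes))
  block_of <- c(rep(seq_along(blocks), blocks), rep(NA, n_independent))
  rho_of <- c(rep(rho, blocks), rep(NA, n_independent))
  datasets <- lapply(n_samples, function(ns) {
    mat <- matrix(NA_real_, n_genes, ns, dimnames = list(genes, NULL))
    for (b in seq_along(blocks)) {
      z <- rnorm(ns)
      rows <- which(block_of == b)
      for (r in rows)
        mat[r, ] <- sqrt(rho[b]) * z + sqrt(1 - rho[b]) * rnorm(ns)
    }
    rows <- which(is.na(block_of))
    for (r in rows) mat[r, ] <- rnorm(ns)
    colnames(mat) <- sprintf("s%03d", seq_len(ns))
    mat
  })
  list(datasets = datasets,
       truth = data.frame(gene = genes, block = block_of, rho = rho_of,
                          stringsAsFactors = FALSE))
}
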