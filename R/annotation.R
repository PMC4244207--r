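#' Read a GAF annotation file
#'
#' Parses a tab-separated GAF 2.x file into per-aspect gene -> term-set maps.
#' Comment lines (`!`) are skipped; qualifier values containing `NOT` are
#' dropped by default; duplicate (gene, term) pairs collapse to one entry.
#' Evidence filtering is opt-in: by default every code is kept, including
#' IEA, since bulk GOA releases are predominantly electronically inferred.
#'
#' @param path Path to a GAF file.
#' @param evidence_exclude Character vector of evidence codes to drop
#'   (e.g. `"IEA"`). Default: none.
#' @param drop_not Drop rows whose qualifier contains `NOT` (default TRUE).
#' @param ontology Optional `go_ontology`; annotations to terms absent from
#'   it (or recorded under a different aspect) are dropped with a warning.
#' @return A `go_annotations` object: list with `by_aspect` (aspect -> named
#'   list of gene -> character vector of terms), `genes` (the gene universe),
#'   and `provenance`.
#' @export
read_gaf <- function(path, evidence_exclude = character(),
                     drop_not = TRUE, ontology = NULL) {
  if (!file.exists(path)) stop_fgnet("GAF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  # trailing optional columns (16-17) may be empty and vanish in the split
  bad <- which(lengths(fields) < 15L | lengths(fields) > 17L)
  if (length(bad))
    stop_fgnet("GAF line ", idx[bad[1]], " has ", lengths(fields)[bad[1]],
               " columns, expected 15-17")
  fields <- lapply(fields, function(f) c(f, rep("", 17L - length(f))))
  m <- do.call(rbind, fields)
  gene <- m[, 2]; qualifier <- m[, 4]; term <- m[, 5]
  evidence <- m[, 7]; asp_code <- m[, 9]
  asp <- c(P = "BP", F = "MF", C = "CC")[asp_code]
  drop <- is.na(asp)
  if (drop_not) drop <- drop | grepl("(^|\\|)NOT($|\\|)", qualifier)
  drop <- drop | evidence %in% evidence_exclude
  gene <- gene[!drop]; term <- term[!drop]; asp <- asp[!drop]

  if (!is.null(ontology)) {
    known <- term %in% ontology$terms
    if (any(!known))
      warn_fgnet(sum(!known), " annotation(s) to terms absent from the ",
                 "ontology dropped")
    match_asp <- known & unname(ontology$aspect[term]) == asp
    match_asp[is.na(match_asp)] <- FALSE
    if (any(known & !match_asp))
      warn_fgnet(sum(known & !match_asp), " annotation(s) with mismatched ",
                 "aspect dropped")
    gene <- gene[match_asp]; term <- term[match_asp]; asp <- asp[match_asp]
  }

  new_annotations(gene, term, asp,
                  provenance = list(source = path,
                                    evidence_exclude = evidence_exclude,
                                    drop_not = drop_not))
}

new_annotations <- function(gene, term, asp, provenance = list()) {
  by_aspect <- lapply(setNames(ASPECTS, ASPECTS), function(a) {
    sel <- asp == a
    if (!any(sel)) return(structure(list(), names = character()))
    lapply(split(term[sel], gene[sel]), function(ts) sort(unique(ts)))
  })
  structure(list(by_aspect = by_aspect,
                 genes = sort(unique(gene)),
                 provenance = provenance),
            class = "go_annotations")
}

#' @export
print.go_annotations <- function(x, ...) {
  cat("GO annotations:", length(x$genes), "genes\n")
  s <- annotation_summary(x)
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %d genes, %d entries\n",
                s$aspect[i], s$n_genes[i], s$n_entries[i]))
  invisible(x)
}

#' Remap gene identifiers of an annotation set
#'
#' Replaces gene identifiers through a two-column mapping table. When several
#' source identifiers map to one target, their term sets are merged.
#'
#' @param ann A `go_annotations` object.
#' @param mapping Data frame (or two-column matrix) with source identifiers
#'   in column 1 and target identifiers in column 2.
#' @param drop_unmapped Drop genes absent from the mapping (default FALSE:
#'   they keep their original identifier).
#' @return A remapped `go_annotations` object.
#' @export
map_identifiers <- function(ann, mapping, drop_unmapped = FALSE) {
  mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
  if (nrow(mapping) == 0L) stop_fgnet("empty identifier mapping")
  map <- setNames(as.character(mapping[[2]]), as.character(mapping[[1]]))
  gene <- character(); term <- character(); asp <- character()
  for (a in ASPECTS) {
    genes_a <- names(ann$by_aspect[[a]])
    for (g in genes_a) {
      tgt <- if (g %in% names(map)) unname(map[g])
             else if (drop_unmapped) next else g
      ts <- ann$by_aspect[[a]][[g]]
      gene <- c(gene, rep(tgt, length(ts)))
      term <- c(term, ts)
      asp <- c(asp, rep(a, length(ts)))
    }
  }
  new_annotations(gene, term, asp,
                  provenance = c(ann$provenance, list(remapped = TRUE)))
}

#' Per-aspect annotation counts
#'
#' @param ann A `go_annotations` object.
#' @return Data frame with columns `aspect`, `n_genes`, `n_entries`.
#' @export
annotation_summary <- function(ann) {
  data.frame(
    aspect = ASPECTS,
    n_genes = vapply(ASPECTS, function(a)
      length(ann$by_aspect[[a]]), integer(1)),
    n_entries = vapply(ASPECTS, function(a)
      sum(lengths(ann$by_aspect[[a]])), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write annotations as a three-column TSV
#'
#' Columns: gene, aspect, term. [read_annotation_tsv] reads the format back.
#'
#' @param ann A `go_annotations` object.
#' @param path Output path.
#' @return Invisibly, the data frame written.
#' @export
write_annotations <- function(ann, path) {
  rows <- do.call(rbind, lapply(ASPECTS, function(a) {
    g <- names(ann$by_aspect[[a]])
    if (!length(g)) return(NULL)
    data.frame(gene = rep(g, lengths(ann$by_aspect[[a]])),
               aspect = a,
               term = unlist(ann$by_aspect[[a]], use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' @rdname write_annotations
#' @export
read_annotation_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  new_annotations(df$gene, df$term, df$aspect,
                  provenance = list(source = path))
}
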