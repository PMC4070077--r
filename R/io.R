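#' Read a weighted edge list
#'
#' Parses a tab- (or whitespace-) separated edge list with columns
#' `geneA geneB weight` into a [weighted_network()]. Lines starting with
#' `#` are skipped. Duplicate records for the same unordered gene pair
#' are resolved by keeping the maximum weight; self-edges are dropped
#' (the gene itself is retained in the universe).
#'
#' @param path Path to the edge-list file.
#' @param universe Optional [gene_universe()]; when given, the network is
#'   indexed over it and genes in the file but not in the universe are
#'   dropped with a warning. When `NULL` the universe is built from the
#'   file in order of first appearance.
#' @param name Network label; defaults to the file name.
#' @return A [weighted_network()]. Its `coverage` records the genes that
#'   actually appeared in the file.
#' @export
read_edge_list <- function(path, universe = NULL,
                           name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "[\t ]+")
  if (length(parts) == 0L) stop("no edge records in ", path)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop("line ", lineno[bad[1L]], ": expected 3 columns (geneA, geneB, weight)")
  }
  ga <- vapply(parts, `[[`, "", 1L)
  gb <- vapply(parts, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(w)) {
    stop("line ", lineno[which(is.na(w))[1L]], ": unparseable weight")
  }
  if (any(w < 0)) {
    stop("line ", lineno[which(w < 0)[1L]], ": negative weight")
  }

  file_genes <- unique(c(rbind(ga, gb)))  # first-appearance order
  if (is.null(universe)) {
    universe <- gene_universe(file_genes)
    coverage <- file_genes
  } else {
    if (!inherits(universe, "gene_universe")) universe <- gene_universe(universe)
    unknown <- setdiff(file_genes, unclass(universe))
    if (length(unknown)) {
      warning(length(unknown), " gene(s) in ", basename(path),
              " not in universe; their edges were dropped")
      ok <- ga %in% unclass(universe) & gb %in% unclass(universe)
      ga <- ga[ok]; gb <- gb[ok]; w <- w[ok]
    }
    coverage <- intersect(file_genes, unclass(universe))
  }

  self <- ga == gb
  ga <- ga[!self]; gb <- gb[!self]; w <- w[!self]
  if (length(w)) {
    lo <- pmin(ga, gb); hi <- pmax(ga, gb)
    key <- paste(lo, hi, sep = "\r")
    if (anyDuplicated(key)) {
      mx <- tapply(w, key, max)
      first <- !duplicated(key)
      ga <- lo[first]; gb <- hi[first]; w <- as.numeric(mx[key[first]])
      message("read_edge_list: duplicate edge records resolved by maximum weight")
    } else {
      ga <- lo; gb <- hi
    }
  }
  network_from_edges(ga, gb, w, universe, name = name, coverage = coverage)
}

#' Write a network as a tab-separated edge list
#'
#' One row per undirected edge (`geneA geneB weight`), each pair written
#' once with `geneA < geneB` lexicographically; rows sorted for
#' determinism.
#'
#' @param net A [weighted_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  et <- edge_table(net)
  et <- et[order(et$from, et$to), , drop = FALSE]
  utils::write.table(et, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bipartite gene-entity table
#'
#' Tab-separated columns `gene entity [weight]`; a missing third column
#' means weight 1. Duplicate (gene, entity) records keep the maximum
#' weight.
#'
#' @param path Path to the table.
#' @param universe Optional [gene_universe()] restricting the genes.
#' @return A [bipartite_association()].
#' @export
read_bipartite <- function(path, universe = NULL) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  parts <- strsplit(trimws(lines[keep]), "[\t ]+")
  if (length(parts) == 0L) stop("no records in ", path)
  if (any(lengths(parts) < 2L)) stop("expected at least 2 columns (gene, entity)")
  g <- vapply(parts, `[[`, "", 1L)
  e <- vapply(parts, `[[`, "", 2L)
  w <- vapply(parts, function(p) {
    if (length(p) >= 3L) suppressWarnings(as.numeric(p[[3L]])) else 1
  }, 0)
  if (anyNA(w) || any(w < 0)) stop("weights must be nonnegative numbers")
  genes <- unique(g)
  if (is.null(universe)) {
    universe <- gene_universe(genes)
  } else {
    if (!inherits(universe, "gene_universe")) universe <- gene_universe(universe)
    ok <- g %in% unclass(universe)
    if (!all(ok)) {
      warning(sum(!ok), " record(s) with genes outside the universe dropped")
      g <- g[ok]; e <- e[ok]; w <- w[ok]
    }
  }
  ents <- unique(e)
  m <- Matrix::sparseMatrix(i = universe_index(universe, g),
                            j = match(e, ents), x = w,
                            dims = c(length(universe), length(ents)),
                            dimnames = list(unclass(universe), ents),
                            use.last.ij = FALSE)
  # sparseMatrix sums duplicates; rebuild with max where needed
  if (anyDuplicated(paste(g, e, sep = "\r"))) {
    key <- paste(g, e, sep = "\r")
    mx <- tapply(w, key, max)
    first <- !duplicated(key)
    m <- Matrix::sparseMatrix(i = universe_index(universe, g[first]),
                              j = match(e[first], ents),
                              x = as.numeric(mx[key[first]]),
                              dims = c(length(universe), length(ents)),
                              dimnames = list(unclass(universe), ents))
  }
  bipartite_association(m, universe)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `set-id description
#' gene1 gene2 ...`. Member genes absent from the universe are dropped
#' (a message reports the count); sets left empty are removed with a
#' warning.
#'
#' @param path Path to the GMT file.
#' @param universe Reference [gene_universe()].
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe) {
  if (!inherits(universe, "gene_universe")) universe <- gene_universe(universe)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- parts[lengths(parts) >= 3L]
  if (length(parts) == 0L) stop("no parseable gene sets in ", path)
  ids <- vapply(parts, `[[`, "", 1L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  dropped <- sum(vapply(sets, function(g) sum(!(g %in% unclass(universe))), 0L))
  if (dropped > 0L) {
    message("read_gmt: dropped ", dropped, " gene(s) not in the universe")
  }
  sets <- lapply(sets, function(g) g[g %in% unclass(universe)])
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sum(empty), " gene set(s) had no resolvable members and were removed")
    sets <- sets[!empty]
  }
  gene_set_collection(sets, universe)
}

#' Write a GMT gene-set collection
#'
#' @param sets A [gene_set_collection()].
#' @param path Output path.
#' @param descriptions Optional named character vector of per-set
#'   descriptions (column 2); defaults to the set identifier.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(inherits(sets, "gene_set_collection"))
  ids <- names(sets)
  desc <- if (is.null(descriptions)) ids else descriptions[ids]
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(ids[i], desc[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene ranking
#'
#' Sorts genes by descending score (ties broken lexicographically by
#' gene identifier for determinism) and writes a TSV with columns
#' `rank`, `gene`, `score`, `annotated`. The `annotated` flag is 1 for
#' genes in `positives`, 0 otherwise, and `NA` when no labels are given.
#'
#' @param scores Named numeric vector of finite gene scores.
#' @param path Output path.
#' @param positives Optional character vector of annotated (seed) genes.
#' @return The ranking `data.frame`, invisibly.
#' @export
write_ranking <- function(scores, path, positives = NULL) {
  if (is.null(names(scores))) stop("scores must be named by gene")
  if (any(!is.finite(scores))) stop("scores must be finite")
  ord <- order(-scores, names(scores), method = "radix")
  ann <- if (is.null(positives)) NA_integer_
         else as.integer(names(scores)[ord] %in% positives)
  df <- data.frame(rank = seq_along(ord), gene = names(scores)[ord],
                   score = unname(scores[ord]), annotated = ann,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a ranking written by [write_ranking()]
#'
#' @param path Path to the ranking TSV.
#' @return A `data.frame` with columns `rank`, `gene`, `score`,
#'   `annotated`.
#' @export
read_ranking <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("integer", "character", "numeric", "integer"))
}
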