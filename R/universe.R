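#' Gene universe
#'
#' An ordered set of unique gene identifiers that fixes the row/column
#' indexing of every adjacency and kernel matrix in a prioritization run.
#' Identifiers are opaque, case-sensitive strings; no symbol mapping is
#' performed.
#'
#' @param genes Character vector of gene identifiers. Duplicates are an
#'   error.
#' @return An object of class `gene_universe`: a character vector of
#'   identifiers whose order defines matrix indexing.
#' @examples
#' u <- gene_universe(c("BRCA1", "TP53", "EGFR"))
#' length(u)
#' @export
gene_universe <- function(genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("a gene universe must contain at least one gene")
  if (anyNA(genes) || any(!nzchar(genes))) {
    stop("gene identifiers must be non-empty strings")
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicate gene identifiers in universe: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  structure(genes, class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("<gene_universe> ", length(x), " genes: ",
      paste(utils::head(unclass(x), 4L), collapse = ", "),
      if (length(x) > 4L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Coerce character vectors (or universes) to a plain character vector of
# gene ids, validating membership against `universe` when given.
as_gene_ids <- function(x) {
  if (inherits(x, "gene_universe")) unclass(x) else as.character(x)
}

# 1-based positions of `genes` in `universe`; error on misses.
universe_index <- function(universe, genes) {
  idx <- match(genes, universe)
  if (anyNA(idx)) {
    miss <- genes[is.na(idx)]
    stop("genes not in universe: ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  idx
}

#' Gene-set collection
#'
#' A mapping from disease (or other phenotype class) identifiers to their
#' annotated "seed" gene sets, resolved against a reference
#' [gene_universe()]. Seed genes act as the positive labels of each
#' prioritization task.
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param universe A [gene_universe()] every member gene must belong to.
#' @return An object of class `gene_set_collection`: a named list of
#'   character vectors with the universe attached as an attribute.
#' @export
gene_set_collection <- function(sets, universe) {
  if (!inherits(universe, "gene_universe")) universe <- gene_universe(universe)
  sets <- as.list(sets)
  if (length(sets) && (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    stop("every gene set must be named by its disease identifier")
  }
  if (anyDuplicated(names(sets))) stop("duplicate disease identifiers")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  sizes <- lengths(sets)
  if (any(sizes == 0L)) stop("empty gene sets are not allowed")
  for (nm in names(sets)) universe_index(universe, sets[[nm]])
  structure(sets, universe = universe, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x), " sets over ",
      length(attr(x, "universe")), " genes; sizes ",
      if (length(x)) paste(range(lengths(x)), collapse = "-") else "NA",
      "\n", sep = "")
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  out <- NextMethod()
  structure(out, universe = attr(x, "universe"), class = "gene_set_collection")
}

#' Filter disease sets by size
#'
#' Retains only the gene sets whose size lies within an inclusive range.
#' The defaults keep sets with at least 5 and at most 200 genes, dropping
#' classes with too little prior information or too heterogeneous a gene
#' complement to define a meaningful ranking task.
#'
#' @param sets A [gene_set_collection()].
#' @param min_size,max_size Inclusive size bounds.
#' @return The filtered `gene_set_collection` (possibly empty).
#' @export
filter_diseases <- function(sets, min_size = 5L, max_size = 200L) {
  stopifnot(inherits(sets, "gene_set_collection"), min_size <= max_size)
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  structure(unclass(sets)[keep],
            universe = attr(sets, "universe"),
            class = "gene_set_collection")
}
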