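#' Weighted gene network
#'
#' A symmetric, nonnegative weighted adjacency matrix over a
#' [gene_universe()]. An absent entry (structural zero) means "no
#' evidence of functional relationship", not evidence of absence; the
#' distinction matters for per-edge integration, which is why each
#' network carries a *coverage* set recording which genes the underlying
#' evidence source actually measured.
#'
#' @param weights Square numeric matrix (dense or `Matrix` sparse) with
#'   gene identifiers as dimnames, or without dimnames if `universe` is
#'   given. Must be symmetric with nonnegative entries.
#' @param universe Optional [gene_universe()]; defaults to the matrix
#'   rownames.
#' @param name Label for the network (used in logs and gamma tables).
#' @param coverage Character vector of genes the source actually covers;
#'   defaults to the whole universe.
#' @return An object of class `weighted_network` with fields `weights`
#'   (a sparse `dgCMatrix`), `universe`, `name` and `coverage`.
#' @export
weighted_network <- function(weights, universe = NULL, name = "net",
                             coverage = NULL) {
  if (is.null(universe)) {
    if (is.null(rownames(weights))) {
      stop("weights must have gene identifiers as dimnames, or pass `universe`")
    }
    universe <- gene_universe(rownames(weights))
  } else if (!inherits(universe, "gene_universe")) {
    universe <- gene_universe(universe)
  }
  n <- length(universe)
  if (nrow(weights) != n || ncol(weights) != n) {
    stop("weights must be ", n, "x", n, " to match the universe")
  }
  w <- methods::as(methods::as(Matrix::Matrix(weights, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  w <- Matrix::drop0(w)
  dimnames(w) <- list(unclass(universe), unclass(universe))
  if (any(w@x < 0)) stop("negative edge weights are not allowed")
  if (!Matrix::isSymmetric(w, tol = 1e-12)) stop("adjacency must be symmetric")
  if (is.null(coverage)) coverage <- unclass(universe)
  coverage <- as.character(coverage)
  universe_index(universe, coverage)
  structure(list(weights = w, universe = universe, name = name,
                 coverage = coverage),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  ne <- Matrix::nnzero(x$weights) / 2
  cat("<weighted_network> '", x$name, "': ", length(x$universe),
      " genes, ", ne, " edges, coverage ", length(x$coverage), " genes\n",
      sep = "")
  invisible(x)
}

# Dense copy of the adjacency (base matrix with dimnames).
dense_weights <- function(net) as.matrix(net$weights)

# Number of undirected edges.
edge_count <- function(net) Matrix::nnzero(net$weights) / 2

# Upper-triangle edge table: data.frame(from, to, weight), from < to.
edge_table <- function(net) {
  m <- methods::as(Matrix::triu(net$weights, k = 1L), "TsparseMatrix")
  g <- unclass(net$universe)
  data.frame(from = g[m@i + 1L], to = g[m@j + 1L], weight = m@x,
             stringsAsFactors = FALSE)
}

# Rebuild a network from an edge table over the same universe.
network_from_edges <- function(from, to, weight, universe, name = "net",
                               coverage = NULL) {
  universe <- if (inherits(universe, "gene_universe")) universe
              else gene_universe(universe)
  n <- length(universe)
  i <- universe_index(universe, from)
  j <- universe_index(universe, to)
  w <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(weight, weight),
                            dims = c(n, n),
                            dimnames = list(unclass(universe), unclass(universe)))
  weighted_network(w, universe, name = name, coverage = coverage)
}

#' Bipartite gene-entity association
#'
#' The incidence structure linking genes (top nodes) to entities such as
#' functional modules, chemicals or interaction partners (bottom nodes).
#' Projection operators collapse it onto a gene-gene network via shared
#' neighbours.
#'
#' @param incidence Numeric matrix (genes x entities), nonnegative;
#'   rownames are gene identifiers, colnames entity identifiers.
#' @param universe Optional [gene_universe()] for the genes.
#' @return An object of class `bipartite_association`.
#' @export
bipartite_association <- function(incidence, universe = NULL) {
  if (is.null(universe)) {
    if (is.null(rownames(incidence))) stop("incidence needs gene rownames")
    universe <- gene_universe(rownames(incidence))
  } else if (!inherits(universe, "gene_universe")) {
    universe <- gene_universe(universe)
  }
  if (is.null(colnames(incidence))) stop("incidence needs entity colnames")
  if (anyDuplicated(colnames(incidence))) stop("duplicate entity identifiers")
  m <- methods::as(methods::as(Matrix::Matrix(incidence, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (any(m@x < 0)) stop("incidence entries must be nonnegative")
  rownames(m) <- unclass(universe)
  structure(list(incidence = Matrix::drop0(m), universe = universe,
                 entities = colnames(incidence)),
            class = "bipartite_association")
}

#' @export
print.bipartite_association <- function(x, ...) {
  cat("<bipartite_association> ", length(x$universe), " genes x ",
      length(x$entities), " entities, ", Matrix::nnzero(x$incidence),
      " links\n", sep = "")
  invisible(x)
}
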