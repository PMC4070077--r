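#' Automatic edge-weight threshold
#'
#' Chooses the network-wide edge filtering threshold that removes as many
#' weak edges as possible while guaranteeing that no node becomes a
#' singleton: for each node take the maximum weight among its incident
#' edges, then take the minimum of these per-node maxima. Filtering at
#' this threshold (inclusive) leaves every node with at least one edge.
#'
#' @param net A [weighted_network()] in which every node has at least one
#'   positive-weight edge.
#' @param ignore_isolated If `TRUE`, nodes without any edge are ignored
#'   when taking the minimum (they stay isolated); if `FALSE` (default)
#'   their presence is an error, since no threshold can preserve a
#'   connection they do not have.
#' @return The threshold (a single number).
#' @seealso [filter_edges()], [preprocess_network()]
#' @export
select_threshold <- function(net, ignore_isolated = FALSE) {
  stopifnot(inherits(net, "weighted_network"))
  node_max <- apply_spmax(net$weights)
  isolated <- node_max <= 0
  if (any(isolated) && !ignore_isolated) {
    stop("threshold undefined: ", sum(isolated),
         " isolated node(s), e.g. ",
         unclass(net$universe)[which(isolated)[1L]])
  }
  if (all(isolated)) stop("network has no edges")
  min(node_max[!isolated])
}

# Per-row maximum of a sparse symmetric nonnegative matrix (0 for empty rows).
apply_spmax <- function(w) {
  m <- methods::as(w, "TsparseMatrix")
  out <- numeric(nrow(w))
  if (length(m@x)) {
    mx <- tapply(m@x, m@i, max)
    out[as.integer(names(mx)) + 1L] <- as.numeric(mx)
  }
  out
}

#' Remove edges below a threshold
#'
#' Edges with weight strictly below `threshold` are removed; edges at or
#' above it are kept unchanged. The inclusive keep preserves the
#' single-connection guarantee of [select_threshold()].
#'
#' @param net A [weighted_network()].
#' @param threshold Nonnegative cutoff.
#' @return The filtered [weighted_network()].
#' @export
filter_edges <- function(net, threshold) {
  stopifnot(inherits(net, "weighted_network"), threshold >= 0)
  w <- net$weights
  w@x[w@x < threshold] <- 0
  weighted_network(Matrix::drop0(w), net$universe, name = net$name,
                   coverage = net$coverage)
}

#' Linearly rescale edge weights to \[0, 1\]
#'
#' Maps every surviving edge weight w to (w - min) / (max - min), where
#' min and max are taken over the network's edges only (structural zeros
#' are not weights and stay absent). This makes weights comparable
#' across networks before integration, so that no network dominates a
#' combination merely through the scale of its weights. If all edges
#' share one weight the map is degenerate and every edge is set to 1,
#' so binary networks pass through unchanged.
#'
#' @param net A [weighted_network()] with at least one edge.
#' @return The rescaled [weighted_network()].
#' @export
linear_rescale <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- Matrix::drop0(net$weights)
  if (length(w@x) == 0L) stop("cannot rescale a network with no edges")
  lo <- min(w@x); hi <- max(w@x)
  if (hi == lo) {
    w@x[] <- 1
  } else {
    w@x <- (w@x - lo) / (hi - lo)
  }
  weighted_network(w, net$universe, name = net$name, coverage = net$coverage)
}

#' Align a network to a reference universe
#'
#' Re-indexes the adjacency over `universe`: genes missing from the
#' network get all-zero rows/columns, genes in the network but not in
#' the universe are dropped with a warning. The genes the network
#' originally covered are recorded in its `coverage` field, which
#' per-edge integration ([integrate_pua()]) uses to distinguish "no
#' evidence measured" from "measured and absent".
#'
#' @param net A [weighted_network()].
#' @param universe Target [gene_universe()].
#' @return A [weighted_network()] over `universe`.
#' @export
align_to_universe <- function(net, universe) {
  stopifnot(inherits(net, "weighted_network"))
  if (!inherits(universe, "gene_universe")) universe <- gene_universe(universe)
  old <- unclass(net$universe)
  extra <- setdiff(old, unclass(universe))
  if (length(extra)) {
    warning(length(extra), " gene(s) of network '", net$name,
            "' not in the target universe were dropped")
  }
  kept <- intersect(old, unclass(universe))
  n <- length(universe)
  w <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(n, n),
                            dimnames = list(unclass(universe), unclass(universe)))
  w[kept, kept] <- net$weights[kept, kept]
  coverage <- intersect(net$coverage, kept)
  weighted_network(w, universe, name = net$name, coverage = coverage)
}

# Quiet restriction of a network to a subset of its genes (used by the
# internal weight estimation, where dropping genes is the point).
subset_network <- function(net, genes) {
  genes <- intersect(unclass(net$universe), genes)
  sub <- gene_universe(genes)
  weighted_network(net$weights[genes, genes], sub, name = net$name,
                   coverage = intersect(net$coverage, genes))
}

#' Standard network pre-processing pipeline
#'
#' Applies, in order: automatic (or fixed) threshold filtering and linear
#' rescaling of the surviving weights to \[0, 1\]. This is the
#' preparation step every network undergoes before integration.
#'
#' @param net A [weighted_network()].
#' @param threshold `"auto"` for [select_threshold()] (ignoring already
#'   isolated nodes), a number for a fixed cutoff, or `NA` to skip
#'   filtering.
#' @param rescale Apply [linear_rescale()] after filtering?
#' @return The pre-processed [weighted_network()].
#' @export
preprocess_network <- function(net, threshold = "auto", rescale = TRUE) {
  if (identical(threshold, "auto")) {
    threshold <- select_threshold(net, ignore_isolated = TRUE)
  }
  if (!is.na(threshold)) net <- filter_edges(net, threshold)
  if (rescale) net <- linear_rescale(net)
  net
}

#' Binary bipartite projection
#'
#' Collapses a gene-entity bipartite graph onto the gene space: two
#' distinct genes are connected with weight 1 if they share at least one
#' entity neighbour, 0 otherwise. Any positive incidence counts as a
#' link.
#'
#' @param bip A [bipartite_association()].
#' @return A binary [weighted_network()] over the genes.
#' @export
binary_projection <- function(bip) {
  stopifnot(inherits(bip, "bipartite_association"))
  b <- bip$incidence
  b@x[] <- 1
  p <- Matrix::tcrossprod(b)
  p@x[p@x > 0] <- 1
  Matrix::diag(p) <- 0
  weighted_network(Matrix::drop0(p), bip$universe, name = "binary_projection")
}

#' SUM bipartite projection
#'
#' Collapses a gene-entity bipartite graph onto the gene space with
#' edge weights equal to the number of entity neighbours the two genes
#' share.
#'
#' @param bip A [bipartite_association()].
#' @return A count-weighted [weighted_network()] over the genes.
#' @export
sum_projection <- function(bip) {
  stopifnot(inherits(bip, "bipartite_association"))
  b <- bip$incidence
  b@x[] <- 1
  p <- Matrix::tcrossprod(b)
  Matrix::diag(p) <- 0
  weighted_network(Matrix::drop0(p), bip$universe, name = "sum_projection")
}

#' Binarize a weighted network at a cutoff
#'
#' Sets w(i,j) to 1 where w(i,j) >= cutoff and 0 elsewhere. Typically
#' applied after [sum_projection()] to require a minimum number of
#' shared neighbours (e.g. five or more shared chemical interactors)
#' before declaring a binary interaction.
#'
#' @param net A [weighted_network()].
#' @param cutoff Positive threshold.
#' @return A binary [weighted_network()].
#' @export
binarize <- function(net, cutoff) {
  stopifnot(inherits(net, "weighted_network"), cutoff > 0)
  w <- net$weights
  w@x <- ifelse(w@x >= cutoff, 1, 0)
  weighted_network(Matrix::drop0(w), net$universe, name = net$name,
                   coverage = net$coverage)
}
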