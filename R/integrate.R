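#' Collection of networks over a shared universe
#'
#' Aligns a list of [weighted_network()]s (or accepts them pre-aligned)
#' to one shared [gene_universe()], keeping each member's coverage mask.
#' All integration operators consume this container; kernel matrices can
#' be integrated too by wrapping their Gram matrices as networks with
#' [kernel_as_network()].
#'
#' @param nets List of [weighted_network()]s. Unnamed members are named
#'   after their `name` field.
#' @param universe Target [gene_universe()]; default is the sorted union
#'   of the members' genes.
#' @return An object of class `network_collection`: a named list of
#'   aligned networks with the universe attached.
#' @export
network_collection <- function(nets, universe = NULL) {
  if (inherits(nets, "weighted_network")) nets <- list(nets)
  if (length(nets) == 0L) stop("a network collection needs at least one member")
  stopifnot(all(vapply(nets, inherits, TRUE, "weighted_network")))
  if (is.null(universe)) {
    universe <- gene_universe(sort(unique(unlist(
      lapply(nets, function(n) unclass(n$universe))))))
  } else if (!inherits(universe, "gene_universe")) {
    universe <- gene_universe(universe)
  }
  aligned <- lapply(nets, function(n) {
    if (identical(unclass(n$universe), unclass(universe))) n
    else align_to_universe(n, universe)
  })
  nm <- names(nets)
  if (is.null(nm)) nm <- rep("", length(nets))
  blank <- !nzchar(nm)
  nm[blank] <- vapply(aligned[blank], function(n) n$name, "")
  if (anyDuplicated(nm)) nm <- make.unique(nm, sep = "_")
  names(aligned) <- nm
  structure(aligned, universe = universe, class = "network_collection")
}

#' @export
print.network_collection <- function(x, ...) {
  cat("<network_collection> ", length(x), " networks over ",
      length(attr(x, "universe")), " genes: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Wrap a kernel matrix for integration
#'
#' Integration operators apply unchanged to kernel matrices: the Gram
#' entries k(i,j) simply take the place of the adjacency weights
#' w(i,j). This helper wraps a [kernel_matrix()] as a
#' [weighted_network()] so it can enter a [network_collection()].
#'
#' @param K A [kernel_matrix()] (nonnegative; random-walk kernels with
#'   a >= 1 always are).
#' @param name Label.
#' @return A [weighted_network()] carrying the Gram matrix (diagonal
#'   included).
#' @export
kernel_as_network <- function(K, name = "kernel") {
  stopifnot(inherits(K, "kernel_matrix"))
  weighted_network(K$gram, K$universe, name = name)
}

# Dense member matrices plus logical coverage masks over the universe.
collection_parts <- function(col) {
  stopifnot(inherits(col, "network_collection"))
  universe <- attr(col, "universe")
  list(
    universe = universe,
    mats = lapply(col, dense_weights),
    masks = lapply(col, function(n) unclass(universe) %in% n$coverage)
  )
}

finish_integrated <- function(w, universe, name) {
  w[w < 0] <- 0  # numerical guard; operators preserve nonnegativity
  weighted_network(Matrix::Matrix(w, sparse = TRUE), universe, name = name)
}

#' Unweighted average integration (UA)
#'
#' The combined weight of every gene pair is the plain arithmetic mean
#' of its weights across all member networks; zeros contribute to the
#' average whether they mean "measured and absent" or "gene not covered
#' by this source".
#'
#' @param col A [network_collection()].
#' @return The integrated [weighted_network()].
#' @export
integrate_ua <- function(col) {
  p <- collection_parts(col)
  w <- Reduce(`+`, p$mats) / length(p$mats)
  finish_integrated(w, p$universe, "UA")
}

#' Per-edge unweighted average integration (PUA)
#'
#' Like [integrate_ua()], but each edge (i, j) is averaged only over the
#' networks whose coverage contains *both* genes, so a gene is not
#' penalized for sources in which it was never measured. Pairs covered
#' by no network get weight 0.
#'
#' @param col A [network_collection()] whose members carry coverage
#'   masks (recorded by [align_to_universe()]).
#' @return The integrated [weighted_network()].
#' @export
integrate_pua <- function(col) {
  p <- collection_parts(col)
  num <- Reduce(`+`, p$mats)
  den <- Reduce(`+`, lapply(p$masks, function(m) outer(m, m)))
  w <- ifelse(den > 0, num / pmax(den, 1L), 0)
  finish_integrated(w, p$universe, "PUA")
}

#' Maximum integration (MAX)
#'
#' Takes the elementwise maximum weight across networks: the union of
#' all sources of evidence, trusting the strongest one per edge.
#'
#' @param col A [network_collection()].
#' @return The integrated [weighted_network()].
#' @export
integrate_max <- function(col) {
  p <- collection_parts(col)
  finish_integrated(Reduce(pmax, p$mats), p$universe, "MAX")
}

#' Minimum integration (MIN)
#'
#' The intersection of the member networks. In `"drastic"` mode the
#' combined weight is the plain elementwise minimum, so a single zero
#' (absence in any network) zeroes the edge. In `"soft"` mode zeros are
#' discarded and the minimum is taken over the nonzero weights only; an
#' edge is 0 only if it is absent from every network. Both modes are
#' sensitive to noise and tend to produce highly disconnected networks.
#'
#' @param col A [network_collection()].
#' @param mode `"drastic"` or `"soft"`.
#' @return The integrated [weighted_network()].
#' @export
integrate_min <- function(col, mode = c("drastic", "soft")) {
  mode <- match.arg(mode)
  p <- collection_parts(col)
  if (mode == "drastic") {
    w <- Reduce(pmin, p$mats)
  } else {
    masked <- lapply(p$mats, function(m) ifelse(m > 0, m, Inf))
    w <- Reduce(pmin, masked)
    w[!is.finite(w)] <- 0
  }
  finish_integrated(w, p$universe, paste0("MIN-", mode))
}

#' Network reliability weights from performance metrics
#'
#' Converts a table of per-network, per-disease accuracy metrics M (for
#' example the AUC of a prioritizer run on each network alone, estimated
#' by internal cross-validation) into normalized network weights gamma.
#'
#' * `transform = "linear"`: gamma_d(k) = M_d(k) / sum_j M_j(k).
#' * `transform = "log"`: gamma_d(k) = log(1 - min(M_d(k), b)) /
#'   sum_j log(1 - min(M_j(k), b)), which emphasizes the most
#'   informative networks; the bound b < 1 (default 0.99) keeps the
#'   logarithm finite when a metric reaches 1.
#'
#' Each disease's weights sum to 1. The class-averaged weights
#' gamma_d = mean_k gamma_d(k), used by [integrate_wa()], are stored
#' alongside.
#'
#' @param metrics Numeric matrix, diseases in rows x networks in
#'   columns (a vector is treated as one disease), values in \[0, 1\].
#' @param transform `"linear"` or `"log"`.
#' @param b Upper clip for the log transform, strictly below 1.
#' @return An object of class `gamma_weights` with fields `per_class`
#'   (diseases x networks matrix of gamma_d(k)), `gamma` (class-averaged
#'   gamma_d), `metrics`, `transform`, `b`.
#' @export
compute_gamma <- function(metrics, transform = c("linear", "log"), b = 0.99) {
  transform <- match.arg(transform)
  if (is.null(dim(metrics))) {
    metrics <- matrix(metrics, nrow = 1L,
                      dimnames = list("class1", names(metrics)))
  }
  metrics <- as.matrix(metrics)
  if (is.null(colnames(metrics))) {
    colnames(metrics) <- paste0("net", seq_len(ncol(metrics)))
  }
  if (is.null(rownames(metrics))) {
    rownames(metrics) <- paste0("class", seq_len(nrow(metrics)))
  }
  if (anyNA(metrics) || any(metrics < 0 | metrics > 1)) {
    stop("metric values must lie in [0, 1]")
  }
  if (!is.numeric(b) || length(b) != 1L || b >= 1) stop("`b` must be < 1")
  if (transform == "linear") {
    rs <- rowSums(metrics)
    zero <- rs == 0
    if (any(zero)) {
      warning(sum(zero), " class(es) with all-zero metrics: uniform weights used")
    }
    per <- metrics / ifelse(rs > 0, rs, 1)
    per[zero, ] <- 1 / ncol(metrics)
  } else {
    lg <- log(1 - pmin(metrics, b))
    per <- lg / rowSums(lg)
  }
  structure(list(per_class = per, gamma = colMeans(per),
                 metrics = metrics, transform = transform, b = b),
            class = "gamma_weights")
}

#' @export
print.gamma_weights <- function(x, ...) {
  cat("<gamma_weights> ", nrow(x$per_class), " class(es) x ",
      ncol(x$per_class), " networks (", x$transform, " transform)\n",
      "class-averaged gamma:\n", sep = "")
  print(round(x$gamma, 4))
  invisible(x)
}

check_gamma_names <- function(col, gamma) {
  stopifnot(inherits(gamma, "gamma_weights"))
  if (!identical(colnames(gamma$per_class), names(col))) {
    if (!setequal(colnames(gamma$per_class), names(col))) {
      stop("gamma networks do not match the collection: ",
           paste(colnames(gamma$per_class), collapse = ", "))
    }
  }
  gamma
}

#' Weighted average per class integration (WAP)
#'
#' Builds the integrated network for one disease k as the gamma-weighted
#' sum of the member networks, w(i,j; k) = sum_d gamma_d(k) w_d(i,j),
#' with per-disease weights from [compute_gamma()]. Each disease gets
#' its own integrated network, which fits each class closely but can
#' overfit when seed sets are small.
#'
#' @param col A [network_collection()].
#' @param gamma A `gamma_weights` object whose networks match `col`.
#' @param disease Disease identifier (row of `gamma$per_class`).
#' @return The integrated [weighted_network()] for `disease`.
#' @export
integrate_wap <- function(col, gamma, disease) {
  gamma <- check_gamma_names(col, gamma)
  if (!disease %in% rownames(gamma$per_class)) {
    stop("no gamma weights for disease '", disease, "'")
  }
  g <- gamma$per_class[disease, names(col)]
  p <- collection_parts(col)
  w <- Reduce(`+`, Map(`*`, p$mats, as.list(g)))
  finish_integrated(w, p$universe, paste0("WAP:", disease))
}

#' Weighted average integration (WA)
#'
#' Builds a single integrated network for all diseases using the
#' class-averaged weights gamma_d = mean_k gamma_d(k):
#' w(i,j) = sum_d gamma_d w_d(i,j). Averaging the weights across
#' classes acts as a regularizer against the per-class overfitting that
#' [integrate_wap()] can incur.
#'
#' @param col A [network_collection()].
#' @param gamma A `gamma_weights` object whose networks match `col`.
#' @return The integrated [weighted_network()].
#' @export
integrate_wa <- function(col, gamma) {
  gamma <- check_gamma_names(col, gamma)
  g <- gamma$gamma[names(col)]
  p <- collection_parts(col)
  w <- Reduce(`+`, Map(`*`, p$mats, as.list(g)))
  finish_integrated(w, p$universe, "WA")
}

#' Dispatch an unweighted integration operator by name
#'
#' @param col A [network_collection()].
#' @param method One of `"ua"`, `"pua"`, `"max"`, `"min-drastic"`,
#'   `"min-soft"`.
#' @return The integrated [weighted_network()].
#' @export
integrate_networks <- function(col, method = c("ua", "pua", "max",
                                               "min-drastic", "min-soft")) {
  method <- match.arg(method)
  switch(method,
         "ua" = integrate_ua(col),
         "pua" = integrate_pua(col),
         "max" = integrate_max(col),
         "min-drastic" = integrate_min(col, "drastic"),
         "min-soft" = integrate_min(col, "soft"))
}
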