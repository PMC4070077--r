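#' Kernel matrix over a gene universe
#'
#' A symmetric Gram matrix whose entries measure gene-gene similarity in
#' the Hilbert space induced by a graph kernel. Constructed by
#' [one_step_kernel()] / [q_step_kernel()]; the constructor is exported
#' for users supplying their own precomputed kernels.
#'
#' @param gram Symmetric numeric matrix with gene dimnames (or none, if
#'   `universe` is given).
#' @param universe Optional [gene_universe()].
#' @param a Diagonal-shift parameter the kernel was built with (`NA` for
#'   external kernels).
#' @param q Number of random-walk steps (`NA` for external kernels).
#' @return An object of class `kernel_matrix` with fields `gram`
#'   (dense base matrix), `universe`, `a`, `q`.
#' @export
kernel_matrix <- function(gram, universe = NULL, a = NA_real_, q = NA_integer_) {
  if (is.null(universe)) {
    if (is.null(rownames(gram))) stop("gram needs gene dimnames or a universe")
    universe <- gene_universe(rownames(gram))
  } else if (!inherits(universe, "gene_universe")) {
    universe <- gene_universe(universe)
  }
  g <- as.matrix(gram)
  n <- length(universe)
  if (!all(dim(g) == n)) stop("gram must be ", n, "x", n)
  if (max(abs(g - t(g))) > 1e-8) stop("gram must be symmetric")
  g <- (g + t(g)) / 2
  dimnames(g) <- list(unclass(universe), unclass(universe))
  structure(list(gram = g, universe = universe, a = a, q = q),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat("<kernel_matrix> ", length(x$universe), " genes (a = ", x$a,
      ", q = ", x$q, ")\n", sep = "")
  invisible(x)
}

#' One-step random-walk kernel
#'
#' Builds the Gram matrix K = (a - 1) I + D^(-1/2) W D^(-1/2) from a
#' symmetric nonnegative adjacency W, where D is the diagonal matrix of
#' row sums. The normalized adjacency has spectrum in \[-1, 1\], so for
#' a >= 2 the kernel is positive semidefinite; a > 1 is required.
#' Zero-degree genes get a normalization entry of 0 and are left with
#' self-similarity a - 1 only.
#'
#' @param net A [weighted_network()].
#' @param a Diagonal shift, strictly greater than 1 (default 2, the
#'   smallest value guaranteeing positive semidefiniteness).
#' @return A [kernel_matrix()] with `q = 1`.
#' @export
one_step_kernel <- function(net, a = 2) {
  stopifnot(inherits(net, "weighted_network"))
  if (!is.numeric(a) || length(a) != 1L || a <= 1) {
    stop("`a` must be a single number larger than 1")
  }
  w <- dense_weights(net)
  d <- rowSums(w)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  k <- w * outer(dinv, dinv)
  diag(k) <- diag(k) + (a - 1)
  kernel_matrix(k, net$universe, a = a, q = 1L)
}

#' q-step random-walk kernel
#'
#' Raises a one-step kernel to the q-th matrix power. Larger q lets the
#' kernel score two genes as similar when they are joined by longer
#' paths in the underlying graph: q = 2 or 3 captures paths through one
#' or two intermediate genes, q = 5 or 10 explores the topology more
#' deeply.
#'
#' @param k1 A [kernel_matrix()] (usually from [one_step_kernel()]).
#' @param q Positive integer number of steps.
#' @return A [kernel_matrix()] with gram = k1's gram to the q-th power.
#' @export
q_step_kernel <- function(k1, q) {
  stopifnot(inherits(k1, "kernel_matrix"))
  if (!is.numeric(q) || length(q) != 1L || q < 1 || q != round(q)) {
    stop("`q` must be a positive integer")
  }
  q <- as.integer(q)
  g <- k1$gram
  if (q > 1L) {
    # exponentiation by squaring; q is small but this keeps LOO-scale
    # reruns cheap
    acc <- NULL
    base <- g
    e <- q
    while (e > 0L) {
      if (e %% 2L == 1L) acc <- if (is.null(acc)) base else acc %*% base
      e <- e %/% 2L
      if (e > 0L) base <- base %*% base
    }
    g <- acc
  }
  kernel_matrix(g, k1$universe, a = k1$a, q = q)
}

#' Random-walk kernel in one call
#'
#' Convenience wrapper: [one_step_kernel()] followed by
#' [q_step_kernel()].
#'
#' @inheritParams one_step_kernel
#' @inheritParams q_step_kernel
#' @return A [kernel_matrix()].
#' @export
rw_kernel <- function(net, a = 2, q = 1L) {
  q_step_kernel(one_step_kernel(net, a = a), q)
}
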