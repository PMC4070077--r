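# Shared validation for seed sets against a universe.
check_seeds <- function(universe, seeds) {
  seeds <- unique(as_gene_ids(seeds))
  if (length(seeds) == 0L) stop("the seed gene set must be non-empty")
  universe_index(universe, seeds)
  seeds
}

#' Nearest-neighbour kernel score
#'
#' S_NN(i) = max over seed genes j of K(i, j): a gene scores as high as
#' its kernel similarity to its closest seed. Seeds are scored like any
#' other gene; cross-validation masks them as needed.
#'
#' @param K A [kernel_matrix()].
#' @param seeds Character vector of seed (positive) genes.
#' @return Named numeric score vector over the universe.
#' @export
score_nn <- function(K, seeds) {
  stopifnot(inherits(K, "kernel_matrix"))
  seeds <- check_seeds(K$universe, seeds)
  m <- K$gram[, seeds, drop = FALSE]
  stats::setNames(as.numeric(do.call(pmax, asplit(m, 2L))),
                  unclass(K$universe))
}

#' k-nearest-neighbour kernel score
#'
#' S_kNN(i) = sum of the k largest kernel similarities K(i, j) over the
#' seed genes j. With k = 1 it reduces to [score_nn()]; with
#' k >= number of seeds it sums over all of them.
#'
#' @param K A [kernel_matrix()].
#' @param seeds Character vector of seed genes.
#' @param k Positive integer neighbourhood size.
#' @return Named numeric score vector over the universe.
#' @export
score_knn <- function(K, seeds, k) {
  stopifnot(inherits(K, "kernel_matrix"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer")
  }
  seeds <- check_seeds(K$universe, seeds)
  m <- K$gram[, seeds, drop = FALSE]
  if (k >= length(seeds)) {
    s <- rowSums(m)
  } else {
    s <- apply(m, 1L, function(x) sum(sort(x, decreasing = TRUE)[seq_len(k)]))
  }
  stats::setNames(as.numeric(s), unclass(K$universe))
}

#' Average-similarity kernel score
#'
#' S_AV(i) = -K(i,i)/2 + mean over seed genes j of K(i, j): the average
#' kernel similarity of gene i to the seed set, penalized by half its
#' self-similarity. When every diagonal entry of the kernel is equal the
#' self term shifts all scores by the same constant and can be dropped
#' (`drop_self_term = TRUE`) without changing the ranking; q-step
#' random-walk kernels generally have unequal diagonals, so the full
#' form is the default.
#'
#' @param K A [kernel_matrix()].
#' @param seeds Character vector of seed genes.
#' @param drop_self_term Omit the -K(i,i)/2 term?
#' @return Named numeric score vector over the universe.
#' @export
score_av <- function(K, seeds, drop_self_term = FALSE) {
  stopifnot(inherits(K, "kernel_matrix"))
  seeds <- check_seeds(K$universe, seeds)
  s <- rowMeans(K$gram[, seeds, drop = FALSE])
  if (!drop_self_term) s <- s - 0.5 * diag(K$gram)
  stats::setNames(as.numeric(s), unclass(K$universe))
}

# Row-stochastic transition matrix Q = D^-1 W, with zero-degree rows
# completed by a self-transition of 1 so probability mass is conserved
# even on disconnected or aggressively filtered networks.
transition_matrix <- function(net) {
  w <- dense_weights(net)
  d <- rowSums(w)
  q <- w / ifelse(d > 0, d, 1)
  zero <- d == 0
  if (any(zero)) diag(q)[zero] <- 1
  q
}

#' Random-walk label propagation
#'
#' Starts from the uniform distribution over the seed genes
#' (p0 = 1/|seeds| on seeds, 0 elsewhere) and applies the update
#' p <- t(Q) p exactly `steps` times, with Q = D^-1 W the row-stochastic
#' transition matrix. Run for a small number of steps: with many steps
#' the walker progressively forgets the seed information and the
#' distribution drifts toward a stationary profile of the graph.
#'
#' @param net A [weighted_network()].
#' @param seeds Character vector of seed genes.
#' @param steps Nonnegative integer number of walk steps (0 returns p0).
#' @return Named numeric probability vector (sums to 1) used as scores.
#' @export
rw_score <- function(net, seeds, steps) {
  stopifnot(inherits(net, "weighted_network"))
  if (!is.numeric(steps) || length(steps) != 1L || steps < 0 ||
      steps != round(steps)) {
    stop("`steps` must be a nonnegative integer")
  }
  seeds <- check_seeds(net$universe, seeds)
  qt <- t(transition_matrix(net))
  p <- numeric(length(net$universe))
  p[universe_index(net$universe, seeds)] <- 1 / length(seeds)
  for (i in seq_len(steps)) p <- as.numeric(qt %*% p)
  stats::setNames(p, unclass(net$universe))
}

#' Random walk with restart
#'
#' Label propagation where at every step the walker either moves to a
#' neighbour (probability 1 - theta) or restarts from the initial seed
#' distribution (probability theta):
#' p <- (1 - theta) t(Q) p + theta p0. Iterated until the L1 change
#' falls below `tol` or `max_iter` is reached; the steady state ranks
#' genes by their probability of belonging to the seed class.
#'
#' @param net A [weighted_network()].
#' @param seeds Character vector of seed genes.
#' @param theta Restart probability in (0, 1]; theta = 1 returns p0.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap.
#' @return Named numeric probability vector (sums to 1).
#' @export
rwr_score <- function(net, seeds, theta = 0.6, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(net, "weighted_network"))
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta > 1) {
    stop("`theta` must lie in (0, 1]")
  }
  seeds <- check_seeds(net$universe, seeds)
  n <- length(net$universe)
  p0 <- numeric(n)
  p0[universe_index(net$universe, seeds)] <- 1 / length(seeds)
  if (theta == 1) return(stats::setNames(p0, unclass(net$universe)))
  qt <- t(transition_matrix(net))
  p <- p0
  for (i in seq_len(max_iter)) {
    pn <- (1 - theta) * as.numeric(qt %*% p) + theta * p0
    if (sum(abs(pn - p)) < tol) {
      p <- pn
      break
    }
    p <- pn
  }
  stats::setNames(p, unclass(net$universe))
}

#' Guilt-by-association score
#'
#' S(i) = max over seed genes j adjacent to i of w(i, j): the strongest
#' direct edge from gene i into the seed set, 0 when no seed is a
#' neighbour. A deliberately simple baseline exploiting only direct
#' connections.
#'
#' @param net A [weighted_network()].
#' @param seeds Character vector of seed genes.
#' @return Named numeric score vector over the universe.
#' @export
gba_score <- function(net, seeds) {
  stopifnot(inherits(net, "weighted_network"))
  seeds <- check_seeds(net$universe, seeds)
  m <- as.matrix(net$weights[, seeds, drop = FALSE])
  stats::setNames(as.numeric(do.call(pmax, c(asplit(m, 2L), list(0)))),
                  unclass(net$universe))
}

#' Build a prioritization scorer
#'
#' Binds a ranking method and its parameters to a network (or
#' precomputed kernel), returning a function `f(seeds)` that scores
#' every gene in the universe. This is the unit the cross-validation
#' protocol works with: fold after fold it calls the scorer with
#' training seeds only.
#'
#' Kernel methods (`"sav"`, `"sknn"`, `"snn"`) compute the q-step
#' random-walk kernel once up front (unless `x` is already a
#' [kernel_matrix()]); propagation methods (`"rw"`, `"rwr"`, `"gba"`)
#' operate on the network directly.
#'
#' @param method One of `"sav"`, `"sknn"`, `"snn"`, `"rw"`, `"rwr"`,
#'   `"gba"`.
#' @param x A [weighted_network()] or, for kernel methods, optionally a
#'   [kernel_matrix()].
#' @param params Named list of method parameters: `a`, `q` (kernel
#'   methods; defaults 2 and 1), `k` (sknn, default 19),
#'   `drop_self_term` (sav, default `FALSE`), `steps` (rw, default 3),
#'   `theta`, `tol`, `max_iter` (rwr, defaults 0.6, 1e-10, 1000).
#' @return A function `f(seeds)` returning a named score vector; its
#'   `universe` attribute carries the gene universe.
#' @export
make_scorer <- function(method = c("sav", "sknn", "snn", "rw", "rwr", "gba"),
                        x, params = list()) {
  method <- match.arg(method)
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  if (method %in% c("sav", "sknn", "snn")) {
    K <- if (inherits(x, "kernel_matrix")) x
         else rw_kernel(x, a = p("a", 2), q = p("q", 1L))
    f <- switch(method,
      sav  = function(seeds) score_av(K, seeds,
                                      drop_self_term = p("drop_self_term", FALSE)),
      sknn = function(seeds) score_knn(K, seeds, k = p("k", 19L)),
      snn  = function(seeds) score_nn(K, seeds))
    universe <- K$universe
  } else {
    if (!inherits(x, "weighted_network")) {
      stop("method '", method, "' requires a weighted_network")
    }
    f <- switch(method,
      rw  = function(seeds) rw_score(x, seeds, steps = p("steps", 3L)),
      rwr = function(seeds) rwr_score(x, seeds, theta = p("theta", 0.6),
                                      tol = p("tol", 1e-10),
                                      max_iter = p("max_iter", 1000L)),
      gba = function(seeds) gba_score(x, seeds))
    universe <- x$universe
  }
  attr(f, "universe") <- universe
  attr(f, "method") <- method
  f
}
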