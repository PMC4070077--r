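#' Specification of a synthetic planted-module benchmark
#'
#' Describes a reproducible multi-network benchmark with known ground
#' truth: diseases are random (possibly overlapping) gene subsets, and
#' each network plants extra edges among genes that share a disease.
#' A network's *informativeness* iota scales its within-set edge
#' probability between the background rate `p_out` (iota = 0, pure
#' noise) and `p_in` (iota = 1, maximally informative):
#' p(edge | shared disease) = p_in * iota + p_out * (1 - iota), and
#' p_out otherwise. Edge weights are 1 times multiplicative lognormal
#' jitter, so that linear rescaling is non-trivial; an optional coverage
#' fraction removes genes from a network to exercise per-edge
#' integration.
#'
#' @param n_genes Number of genes in the shared universe.
#' @param n_diseases Number of planted disease sets.
#' @param set_size Inclusive (min, max) disease-set size range.
#' @param p_in Within-set edge probability of a fully informative
#'   network.
#' @param p_out Background edge probability.
#' @param informativeness Numeric vector in \[0, 1\], one entry per
#'   network.
#' @param weight_noise Standard deviation (log scale) of the lognormal
#'   weight jitter.
#' @param coverage Fraction of genes each network covers, in (0, 1];
#'   recycled across networks.
#' @param seed Integer seed; the whole benchmark is a deterministic
#'   function of the spec.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 500L, n_diseases = 20L,
                         set_size = c(5L, 40L), p_in = 0.3, p_out = 0.02,
                         informativeness = c(0.9, 0.5, 0.0),
                         weight_noise = 0.25, coverage = 1, seed = 1L) {
  stopifnot(n_genes >= 2L, n_diseases >= 1L, length(set_size) == 2L,
            set_size[1L] >= 1L, set_size[1L] <= set_size[2L],
            p_out >= 0, p_out <= p_in, p_in <= 1,
            all(informativeness >= 0), all(informativeness <= 1),
            weight_noise >= 0, all(coverage > 0), all(coverage <= 1))
  if (set_size[2L] > n_genes) {
    stop("maximum set size exceeds the number of genes")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_diseases = as.integer(n_diseases),
                 set_size = as.integer(set_size), p_in = p_in, p_out = p_out,
                 informativeness = as.numeric(informativeness),
                 weight_noise = weight_noise,
                 coverage = rep_len(coverage, length(informativeness)),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic multi-network benchmark
#'
#' Draws the benchmark described by a [fixture_spec()]: a shared gene
#' universe, overlapping disease seed sets, and one network per
#' informativeness value with planted within-set edge enrichment.
#' Fully reproducible: the same spec (including its seed) yields an
#' identical benchmark.
#'
#' @param spec A [fixture_spec()].
#' @return List with `networks` (a [network_collection()]), `sets`
#'   (a [gene_set_collection()]) and `truth` (a `data.frame` of
#'   per-network planted parameters).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  genes <- sprintf("g%0*d", nchar(as.character(n)), seq_len(n))
  universe <- gene_universe(genes)

  sizes <- sample(seq(spec$set_size[1L], spec$set_size[2L]),
                  spec$n_diseases, replace = TRUE)
  sets <- lapply(sizes, function(s) sort(sample(genes, s)))
  names(sets) <- sprintf("D%02d", seq_len(spec$n_diseases))
  sets <- gene_set_collection(sets, universe)

  # genes sharing at least one disease
  memb <- matrix(FALSE, n, spec$n_diseases, dimnames = list(genes, NULL))
  for (k in seq_along(sets)) memb[sets[[k]], k] <- TRUE
  shared <- Matrix::tcrossprod(Matrix::Matrix(memb, sparse = TRUE) * 1) > 0
  shared <- as.matrix(shared)
  diag(shared) <- FALSE

  ut <- upper.tri(matrix(0, n, n))
  nets <- vector("list", length(spec$informativeness))
  for (d in seq_along(spec$informativeness)) {
    iota <- spec$informativeness[d]
    p_sig <- spec$p_in * iota + spec$p_out * (1 - iota)
    pmat <- ifelse(shared, p_sig, spec$p_out)
    draw <- matrix(0, n, n)
    draw[ut] <- stats::runif(sum(ut))
    edge <- ut & draw < pmat
    w <- matrix(0, n, n, dimnames = list(genes, genes))
    ne <- sum(edge)
    w[edge] <- if (spec$weight_noise > 0) {
      exp(stats::rnorm(ne, 0, spec$weight_noise))
    } else {
      rep(1, ne)
    }
    w <- w + t(w)
    cov_frac <- spec$coverage[d]
    covered <- if (cov_frac < 1) {
      sort(sample(genes, max(2L, round(cov_frac * n))))
    } else {
      genes
    }
    if (cov_frac < 1) {
      absent <- setdiff(genes, covered)
      w[absent, ] <- 0
      w[, absent] <- 0
    }
    nets[[d]] <- weighted_network(w, universe,
                                  name = sprintf("net%d_iota%.2f", d, iota),
                                  coverage = covered)
  }
  names(nets) <- vapply(nets, function(x) x$name, "")
  truth <- data.frame(network = names(nets),
                      informativeness = spec$informativeness,
                      p_within = spec$p_in * spec$informativeness +
                        spec$p_out * (1 - spec$informativeness),
                      p_out = spec$p_out,
                      coverage = spec$coverage,
                      stringsAsFactors = FALSE)
  list(networks = network_collection(nets, universe), sets = sets,
       truth = truth)
}

#' Write a generated benchmark to disk
#'
#' One edge-list TSV per network, the disease sets as a GMT file, and
#' the planted truth as `truth.tsv`.
#'
#' @param fixture A list from [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return Character vector of the written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (length(fixture$networks) == 0L) stop("empty network collection")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(fixture$networks)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_edge_list(fixture$networks[[nm]], p)
    paths <- c(paths, p)
  }
  gmt <- file.path(dir, "disease_sets.gmt")
  write_gmt(fixture$sets, gmt)
  tr <- file.path(dir, "truth.tsv")
  utils::write.table(fixture$truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, gmt, tr))
}
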