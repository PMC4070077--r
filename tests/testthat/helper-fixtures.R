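# Shared builders for small in-code fixtures; no files are stored in the
# repository, everything is generated at test time.

# Random symmetric nonnegative network on n genes (Erdos-Renyi with
# uniform weights), as a weighted_network with gene names g1..gn.
rand_net <- function(n, p = 0.3, seed = NULL, name = "rand") {
  if (!is.null(seed)) set.seed(seed)
  genes <- paste0("g", seq_len(n))
  w <- matrix(0, n, n, dimnames = list(genes, genes))
  ut <- upper.tri(w)
  edge <- ut & matrix(stats::runif(n * n), n, n) < p
  w[edge] <- stats::runif(sum(edge), 0.1, 1)
  w <- w + t(w)
  weighted_network(w, name = name)
}

# A small 3-gene network: a-b 0.2, b-c 0.5, a-c 0.9.
triangle_net <- function() {
  g <- c("a", "b", "c")
  w <- matrix(0, 3, 3, dimnames = list(g, g))
  w["a", "b"] <- w["b", "a"] <- 0.2
  w["b", "c"] <- w["c", "b"] <- 0.5
  w["a", "c"] <- w["c", "a"] <- 0.9
  weighted_network(w)
}

# 2-node unit-weight graph used by the worked kernel/RWR micro-examples.
pair_net <- function() {
  w <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  weighted_network(w)
}

# Write lines to a temp file and return its path.
tmp_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Small planted-module benchmark for desk-scale prioritizer tests.
small_fixture <- function(seed = 7, n_genes = 150, n_diseases = 6,
                          informativeness = c(1, 0)) {
  generate_fixture(fixture_spec(
    n_genes = n_genes, n_diseases = n_diseases, set_size = c(8L, 20L),
    p_in = 0.5, p_out = 0.02, informativeness = informativeness,
    weight_noise = 0.25, seed = seed))
}

# Exhaustive pair-counting AUC oracle (ties counted 1/2).
auc_oracle <- function(scores, positives) {
  pos <- scores[names(scores) %in% positives]
  neg <- scores[!(names(scores) %in% positives)]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
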