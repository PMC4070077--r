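test_that("the size filter keeps exactly the inclusive-boundary sets", {
  u <- gene_universe(paste0("g", 1:300))
  sizes <- c(S4 = 4, S5 = 5, S200 = 200, S201 = 201)
  sets <- gene_set_collection(
    lapply(sizes, function(s) paste0("g", 1:s)), u)
  kept <- filter_diseases(sets)
  expect_setequal(names(kept), c("S5", "S200"))

  expect_length(filter_diseases(kept[0]), 0L)
  expect_equal(names(filter_diseases(kept)), names(kept))
})

test_that("the AUC equals exhaustive pair counting with ties at 1/2", {
  s <- c(p1 = 0.9, p2 = 0.8, n1 = 0.7, n2 = 0.1)
  expect_equal(ranking_auc(s, c("p1", "p2")), 1)
  expect_equal(ranking_auc(c(a = 0.5, b = 0.5), "a"), 0.5)
  expect_true(is.na(ranking_auc(c(a = 1, b = 2), c("a", "b"))))

  set.seed(8)
  for (rep in 1:10) {
    n <- 30
    scores <- setNames(sample(seq(0, 1, 0.1), n, replace = TRUE),
                       paste0("g", 1:n))
    pos <- paste0("g", sample(n, 6))
    expect_equal(ranking_auc(scores, pos), auc_oracle(scores, pos))
  }
})

test_that("the AUC is invariant under strictly monotone score transforms", {
  set.seed(14)
  scores <- setNames(rnorm(40), paste0("g", 1:40))
  pos <- paste0("g", sample(40, 8))
  a0 <- ranking_auc(scores, pos)
  expect_equal(ranking_auc(exp(scores), pos), a0)
  expect_equal(ranking_auc(3 * scores - 7, pos), a0)
  expect_equal(ranking_auc(rank(scores, ties.method = "average"), pos), a0)
})

test_that("precision at recall matches a brute-force cutoff scan", {
  # positives at ranks 1 and 4 of 4
  s <- c(a = 0.9, b = 0.7, c = 0.5, d = 0.3)
  p <- precision_at_recall(s, c("a", "d"), c(0.5, 1))
  expect_equal(unname(p), c(1, 0.5))

  # all positives ranked first -> precision 1 everywhere
  p2 <- precision_at_recall(s, c("a", "b"), seq(0.1, 1, 0.1))
  expect_true(all(p2 == 1))

  oracle <- function(scores, positives, r) {
    ord <- order(-scores, names(scores))
    lab <- names(scores)[ord] %in% positives
    np <- sum(lab)
    for (cut in seq_along(lab)) {
      if (sum(lab[1:cut]) / np >= r - 1e-12) {
        return(sum(lab[1:cut]) / cut)
      }
    }
  }
  set.seed(9)
  for (rep in 1:8) {
    scores <- setNames(runif(25), paste0("g", 1:25))
    pos <- paste0("g", sample(25, 5))
    for (r in c(0.2, 0.4, 0.6, 0.8, 1)) {
      expect_equal(unname(precision_at_recall(scores, pos, r)),
                   oracle(scores, pos, r))
    }
  }
})

test_that("CV folds partition the universe and each gene is tested once", {
  u <- gene_universe(paste0("g", 1:100))
  plan <- cv_folds(u, f = 5, seed = 3)
  all_genes <- unlist(plan$folds)
  expect_setequal(all_genes, unclass(u))
  expect_equal(anyDuplicated(all_genes), 0L)

  strat <- cv_folds(u, f = 5, seed = 3, stratify = paste0("g", 1:10))
  expect_true(all(vapply(strat$folds, function(f)
    sum(f %in% paste0("g", 1:10)), 0L) == 2L))

  # cross_validate assigns a test score to every gene exactly once
  net <- rand_net(30, seed = 44)
  sets <- gene_set_collection(list(D = paste0("g", 1:8)), net$universe)
  sc <- make_scorer("sav", net, list(a = 2, q = 2))
  rep1 <- cross_validate(sc, sets, cv_folds(net$universe, 5, seed = 2))
  expect_false(anyNA(attr(rep1, "scores")))
})

test_that("cross-validation recovers planted structure but not noise", {
  fx <- small_fixture(seed = 19, informativeness = c(1, 0))
  u <- attr(fx$networks, "universe")
  plan <- cv_folds(u, 5, seed = 6)
  params <- list(a = 2, q = 3)
  good <- cross_validate(make_scorer("sav", fx$networks[[1]], params),
                         fx$sets, plan)
  noise <- cross_validate(make_scorer("sav", fx$networks[[2]], params),
                          fx$sets, plan)
  expect_gt(mean(good$auc), 0.85)
  expect_lt(abs(mean(noise$auc) - 0.5), 0.12)
})

test_that("permutation p-values are the exceedance ratio and reproducible", {
  set.seed(77)
  scores <- setNames(runif(60), paste0("g", 1:60))
  pos <- paste0("g", sample(60, 8))
  r1 <- permutation_test(scores, pos, n_shuffles = 200, seed = 5)
  r2 <- permutation_test(scores, pos, n_shuffles = 200, seed = 5)
  expect_identical(r1, r2)
  expect_equal(r1$p, r1$m / 200)
  r3 <- permutation_test(scores, pos, n_shuffles = 200, seed = 5,
                         add_one = TRUE)
  expect_equal(r3$p, (r3$m + 1) / 201)

  # a cleanly separated ranking is never beaten by shuffles
  sep <- setNames(c(rep(1, 5), runif(55, 0, 0.5)), paste0("g", 1:60))
  rs <- permutation_test(sep, paste0("g", 1:5), n_shuffles = 200, seed = 1)
  expect_equal(rs$m, 0L)
  expect_equal(rs$p, 0)
})

test_that("internal weight estimation never sees test-fold labels", {
  fx <- small_fixture(seed = 23, informativeness = c(0.9, 0))
  u <- attr(fx$networks, "universe")
  genes <- unclass(u)
  set.seed(11)
  train <- sort(sample(genes, 110))
  outside <- setdiff(genes, train)

  g1 <- estimate_internal_weights(fx$networks, fx$sets, "sav",
                                  list(a = 2, q = 2), train_genes = train,
                                  internal_f = 5, seed = 99)
  # sentinel labels: replace every positive outside the training split
  tampered <- lapply(unclass(fx$sets), function(p) {
    inside <- intersect(p, train)
    c(inside, sample(outside, length(setdiff(p, train))))
  })
  tampered <- gene_set_collection(tampered, u)
  g2 <- estimate_internal_weights(fx$networks, tampered, "sav",
                                  list(a = 2, q = 2), train_genes = train,
                                  internal_f = 5, seed = 99)
  expect_identical(g1$per_class, g2$per_class)
})

test_that("internal weights are symmetric for identical networks and 1 alone", {
  net <- rand_net(40, seed = 3, name = "n1")
  twin <- weighted_network(as.matrix(net$weights), net$universe, name = "n2")
  col <- network_collection(list(net, twin))
  sets <- gene_set_collection(list(D1 = paste0("g", 1:8),
                                   D2 = paste0("g", 20:30)), net$universe)
  g <- estimate_internal_weights(col, sets, "sav", list(a = 2, q = 2),
                                 internal_f = 5, seed = 4)
  expect_equal(unname(g$gamma), c(0.5, 0.5), tolerance = 1e-9)

  single <- network_collection(list(net))
  gs <- estimate_internal_weights(single, sets, "sav", list(a = 2, q = 2),
                                  internal_f = 5, seed = 4)
  expect_equal(unname(gs$gamma), 1)
})

test_that("informative networks earn larger gamma than noise", {
  fx <- small_fixture(seed = 29, informativeness = c(1, 0))
  g <- estimate_internal_weights(fx$networks, fx$sets, "sav",
                                 list(a = 2, q = 3), internal_f = 5,
                                 seed = 12)
  expect_gt(g$gamma[[1]], g$gamma[[2]])
  frac <- mean(g$per_class[, 1] > g$per_class[, 2])
  expect_gte(frac, 0.9)
})

test_that("the candidate analysis reproduces the worked ECDF example", {
  u <- gene_universe(c("a1", "a2", "u1", "u2", "u3", "u4"))
  scores <- c(a1 = 0.9, a2 = 0.6, u1 = 0.8, u2 = 0.7, u3 = 0.5, u4 = 0.4)
  sets <- gene_set_collection(list(D = c("a1", "a2")), u)
  report <- structure(
    data.frame(disease = "D", n_pos = 2L, auc = 0.99, p_value = 0.001),
    scores = matrix(scores, ncol = 1, dimnames = list(names(scores), "D")),
    class = c("evaluation_report", "data.frame"))
  res <- candidate_analysis(report, sets, top = 2)
  expect_equal(res$candidates$gene, c("u1", "u2"))
  expect_equal(res$candidates$percentile, c(75, 50))
  expect_false(any(res$candidates$below_support))

  # unannotated gene above every annotated one -> 100th percentile
  scores2 <- c(a1 = 0.5, a2 = 0.4, u1 = 0.9, u2 = 0.1, u3 = 0.1, u4 = 0.1)
  report2 <- structure(
    data.frame(disease = "D", n_pos = 2L, auc = 1, p_value = 0),
    scores = matrix(scores2, ncol = 1, dimnames = list(names(scores2), "D")),
    class = c("evaluation_report", "data.frame"))
  res2 <- candidate_analysis(report2, sets, top = 2)
  expect_equal(res2$candidates$percentile[1], 100)
  # second candidate scores below c -> percentile 0, flagged
  expect_equal(res2$candidates$percentile[2], 0)
  expect_true(res2$candidates$below_support[2])

  # no disease passing -> empty table with a notice
  report3 <- report
  report3$auc <- 0.5
  expect_message(res3 <- candidate_analysis(report3, sets), "no disease")
  expect_equal(nrow(res3$candidates), 0L)
})

test_that("permutation p-values attach to reports by disease", {
  net <- rand_net(40, seed = 15)
  sets <- gene_set_collection(list(D1 = paste0("g", 1:6),
                                   D2 = paste0("g", 30:36)), net$universe)
  rep1 <- cross_validate(make_scorer("sav", net, list(a = 2, q = 2)),
                         sets, cv_folds(net$universe, 5, seed = 2))
  rep2 <- add_permutation_pvalues(rep1, sets, n_shuffles = 100, seed = 3)
  expect_equal(rep2$p_value, rep2$m / 100)
  expect_true(all(rep2$p_value >= 0 & rep2$p_value <= 1))
})
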