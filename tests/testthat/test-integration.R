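# Two tiny aligned networks with partial coverage for worked examples:
# universe g1..g3; net A covers all genes, net B covers g1, g3 only.
tiny_collection <- function() {
  g <- paste0("g", 1:3)
  wa <- matrix(0, 3, 3, dimnames = list(g, g))
  wa[1, 2] <- wa[2, 1] <- 0.6
  wa[1, 3] <- wa[3, 1] <- 0.4
  wb <- matrix(0, 3, 3, dimnames = list(g, g))
  wb[1, 3] <- wb[3, 1] <- 0.6
  network_collection(list(
    A = weighted_network(wa, name = "A"),
    B = weighted_network(wb, name = "B", coverage = c("g1", "g3"))))
}

test_that("UA averages including zeros; PUA divides by covering networks", {
  col <- tiny_collection()
  ua <- integrate_ua(col)
  pua <- integrate_pua(col)

  # pair (g1,g2): B does not cover g2 -> UA halves it, PUA does not
  expect_equal(as.numeric(ua$weights["g1", "g2"]), 0.3)
  expect_equal(as.numeric(pua$weights["g1", "g2"]), 0.6)
  # pair (g1,g3): both networks cover both genes -> UA == PUA
  expect_equal(as.numeric(ua$weights["g1", "g3"]), 0.5)
  expect_equal(as.numeric(pua$weights["g1", "g3"]), 0.5)
})

test_that("each integration operator matches its elementwise formula", {
  set.seed(17)
  for (rep in 1:5) {
    nets <- lapply(1:3, function(d) rand_net(8, p = 0.35,
                                             name = paste0("n", d)))
    col <- network_collection(nets)
    mats <- lapply(col, function(n) as.matrix(n$weights))
    arr <- simplify2array(mats)

    expect_equal(as.matrix(integrate_ua(col)$weights),
                 apply(arr, 1:2, mean))
    expect_equal(as.matrix(integrate_pua(col)$weights),
                 apply(arr, 1:2, mean))  # full coverage: PUA == UA
    expect_equal(as.matrix(integrate_max(col)$weights),
                 apply(arr, 1:2, max))
    expect_equal(as.matrix(integrate_min(col, "drastic")$weights),
                 apply(arr, 1:2, min))
    soft_min <- apply(arr, 1:2, function(x) {
      if (all(x == 0)) 0 else min(x[x != 0])
    })
    expect_equal(as.matrix(integrate_min(col, "soft")$weights), soft_min)

    # elementwise orderings hold on every instance
    d <- as.matrix(integrate_min(col, "drastic")$weights)
    s <- as.matrix(integrate_min(col, "soft")$weights)
    u <- as.matrix(integrate_ua(col)$weights)
    m <- as.matrix(integrate_max(col)$weights)
    expect_true(all(d <= u + 1e-12) && all(u <= m + 1e-12))
    expect_true(all(d <= s + 1e-12) && all(s <= m + 1e-12))
  }
})

test_that("drastic vs soft minimum differ exactly on partially-absent edges", {
  col <- tiny_collection()
  expect_equal(as.numeric(integrate_min(col, "drastic")$weights["g1", "g3"]),
               0.4)
  expect_equal(as.numeric(integrate_min(col, "drastic")$weights["g1", "g2"]),
               0)
  expect_equal(as.numeric(integrate_min(col, "soft")$weights["g1", "g2"]),
               0.6)
})

test_that("gamma weights reproduce the worked linear and log examples", {
  g <- compute_gamma(c(n1 = 0.8, n2 = 0.6))
  expect_equal(unname(g$per_class[1, ]), c(4 / 7, 3 / 7))

  gl <- compute_gamma(c(n1 = 0.9, n2 = 0.5), transform = "log")
  expect_equal(unname(gl$per_class[1, ]),
               c(log(0.1), log(0.5)) / (log(0.1) + log(0.5)))
  expect_equal(unname(round(gl$per_class[1, ], 4)), c(0.7686, 0.2314))

  # metric at 1 is clipped to b before the log
  gb <- compute_gamma(c(n1 = 1, n2 = 0.5), transform = "log", b = 0.99)
  expect_equal(unname(gb$per_class[1, ]),
               c(log(0.01), log(0.5)) / (log(0.01) + log(0.5)))

  expect_error(compute_gamma(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(compute_gamma(c(0.5, 0.6), b = 1), "< 1")
  expect_warning(compute_gamma(rbind(c(0, 0), c(0.5, 0.5))), "all-zero")
})

test_that("gamma rows sum to one per class and after class-averaging", {
  set.seed(5)
  M <- matrix(runif(12, 0.3, 1), 4, 3,
              dimnames = list(paste0("D", 1:4), paste0("n", 1:3)))
  for (tr in c("linear", "log")) {
    g <- compute_gamma(M, transform = tr)
    expect_equal(unname(rowSums(g$per_class)), rep(1, 4), tolerance = 1e-9)
    expect_equal(sum(g$gamma), 1, tolerance = 1e-9)
    expect_true(all(g$per_class >= 0))
  }
})

test_that("WAP and WA combine networks by their gamma weights", {
  col <- tiny_collection()
  M <- rbind(D1 = c(A = 1, B = 0), D2 = c(A = 0, B = 1))
  gamma <- compute_gamma(M)

  # degenerate per-class weights return one member exactly
  w1 <- integrate_wap(col, gamma, "D1")
  expect_equal(as.matrix(w1$weights), as.matrix(col$A$weights))
  w2 <- integrate_wap(col, gamma, "D2")
  expect_equal(as.matrix(w2$weights), as.matrix(col$B$weights))

  # class-averaged (1,0)/(0,1) -> (0.5, 0.5) -> UA
  wa <- integrate_wa(col, gamma)
  expect_equal(as.matrix(wa$weights), as.matrix(integrate_ua(col)$weights))

  # worked weighted sum: gamma (4/7, 3/7), weights (0.6, 0) -> 0.2571...
  g2 <- compute_gamma(rbind(D1 = c(A = 0.8, B = 0.6)))
  w3 <- integrate_wap(col, g2, "D1")
  expect_equal(as.numeric(w3$weights["g1", "g2"]), 0.6 * 4 / 7)

  expect_error(integrate_wap(col, gamma, "nope"), "no gamma")
})

test_that("single-class WA equals WAP; uniform gamma equals UA", {
  set.seed(23)
  col <- network_collection(lapply(1:3, function(d)
    rand_net(7, name = paste0("n", d))))
  g1 <- compute_gamma(rbind(D1 = c(n1 = 0.9, n2 = 0.6, n3 = 0.3)))
  expect_equal(as.matrix(integrate_wa(col, g1)$weights),
               as.matrix(integrate_wap(col, g1, "D1")$weights))

  gu <- compute_gamma(rbind(D1 = c(n1 = 0.5, n2 = 0.5, n3 = 0.5),
                            D2 = c(n1 = 0.2, n2 = 0.2, n3 = 0.2)))
  expect_equal(as.matrix(integrate_wa(col, gu)$weights),
               as.matrix(integrate_ua(col)$weights), tolerance = 1e-12)
})

test_that("integration commutes with simultaneous permutation of genes", {
  set.seed(41)
  nets <- lapply(1:2, function(d) rand_net(6, name = paste0("n", d)))
  col <- network_collection(nets)
  perm <- sample(paste0("g", 1:6))
  permuted <- network_collection(lapply(nets, function(n) {
    weighted_network(as.matrix(n$weights)[perm, perm],
                     gene_universe(perm), name = n$name)
  }), universe = gene_universe(perm))
  for (m in c("ua", "pua", "max", "min-drastic", "min-soft")) {
    a <- as.matrix(integrate_networks(col, m)$weights)[perm, perm]
    b <- as.matrix(integrate_networks(permuted, m)$weights)
    expect_equal(a, b, label = m)
  }
})

test_that("integration operators accept kernel matrices unchanged", {
  net1 <- rand_net(8, seed = 61, name = "k1")
  net2 <- rand_net(8, seed = 62, name = "k2")
  K1 <- rw_kernel(net1, 2, 2)
  K2 <- rw_kernel(net2, 2, 2)
  col <- network_collection(list(kernel_as_network(K1, "k1"),
                                 kernel_as_network(K2, "k2")))
  fused <- integrate_ua(col)
  expect_equal(as.matrix(fused$weights), (K1$gram + K2$gram) / 2,
               tolerance = 1e-12)
  # the fused Gram can be used directly by the score functions
  Kf <- kernel_matrix(as.matrix(fused$weights), attr(col, "universe"))
  s <- score_av(Kf, c("g2", "g3"))
  expect_length(s, 8L)
  expect_true(all(is.finite(s)))
})
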