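test_that("Gini sparsity index hits its extremes and is scale-invariant", {
  # one-hot of length n scores (n-1)/n
  for (n in c(4, 10, 100)) {
    v <- c(1, rep(0, n - 1))
    expect_equal(sparsity_measure(v), (n - 1) / n)
  }
  # constant vectors score 0
  expect_equal(sparsity_measure(rep(2, 8)), 0)
  expect_equal(sparsity_measure(rep(-3, 5)), 0)
  # hand evaluation of the sorted-weights formula for v = (1,0,0,3):
  # sorted |v| = (0,0,1,3), N=4, ||v||1 = 4
  # G = 1 - 2*[1/4*(4-3+0.5)/4 + 3/4*(4-4+0.5)/4] = 1 - 2*(1.5/16 + 1.5/16)
  expect_equal(sparsity_measure(c(1, 0, 0, 3)), 1 - 2 * (1.5 / 16 + 1.5 / 16))
  # scale invariance
  set.seed(4)
  v <- rnorm(32)
  for (c_ in c(-2, 0.001, 1e6))
    expect_equal(sparsity_measure(c_ * v), sparsity_measure(v),
                 tolerance = 1e-12)
  expect_error(sparsity_measure(rep(0, 5)), "all-zero")
})

test_that("wavelet tree preserves energy and kills details on constants", {
  set.seed(8)
  X <- matrix(rnorm(2 * 64), 2)
  for (fam in c("haar", "db2", "db4")) {
    tr <- decompose_tree(X, fam, 3)
    # Parseval at every depth's full tiling
    for (d in 1:3) {
      keys <- paste0(d, ".", seq_len(2^d) - 1)
      e <- sum(vapply(keys, function(k) sum(tr$nodes[[k]]^2), numeric(1)))
      expect_equal(e, sum(X^2), tolerance = 1e-8)
    }
  }
  # vanishing moments: constant row -> detail node ~ 0
  trc <- decompose_tree(rep(5, 32), "db4", 1)
  expect_lt(max(abs(trc$nodes[["1.1"]])), 1e-10)
  expect_equal(sum(trc$nodes[["1.0"]]^2), 32 * 25, tolerance = 1e-8)
  expect_error(decompose_tree(X, "sym9"), "supported families")
})

test_that("a synthesized packet atom concentrates in its own node", {
  # build the atom by inverse transform of a one-hot coefficient vector
  n <- 32
  tr0 <- decompose_tree(rep(0, n), "db2", 2)
  dict <- select_nodes(tr0, 1)
  # force the full level-2 tiling as the dictionary for this check
  dict$selected_nodes <- paste0("2.", 0:3)
  dict$node_lengths <- rep(8L, 4)
  coef <- rep(0, n); coef[13] <- 1        # inside node 2.1
  atom <- reconstruct_sparse(matrix(coef, 1), dict)
  tr <- decompose_tree(atom, "db2", 2)
  energies <- vapply(paste0("2.", 0:3), function(k) sum(tr$nodes[[k]]^2),
                     numeric(1))
  expect_equal(unname(energies["2.1"]) / sum(energies), 1, tolerance = 1e-8)
  expect_equal(max(abs(tr$nodes[["2.1"]])), 1, tolerance = 1e-8)
})

test_that("best-basis search matches exhaustive enumeration of prunings", {
  # all admissible prunings for lengths <= 16, levels <= 3
  set.seed(21)
  cases <- list(
    list(x = rnorm(8), level = 2),
    list(x = rnorm(8), level = 3),
    list(x = c(rep(1, 8), rep(-2, 8)), level = 3),
    list(x = rnorm(16), level = 3),
    list(x = rep(c(1, 0), 8), level = 2),
    list(x = cumsum(rnorm(16)), level = 3))
  for (cs in cases) {
    for (fam in c("haar", "db2")) {
      tr <- decompose_tree(cs$x, fam, cs$level)
      dict <- select_nodes(tr, 1)
      prunings <- enumerate_prunings(cs$level)
      vals <- vapply(prunings, function(pr)
        sum(vapply(pr, function(k) node_sparsity_oracle(tr$nodes[[k]]),
                   numeric(1))), numeric(1))
      expect_equal(dict$basis_value, max(vals), tolerance = 1e-12)
      # the selected leaves attain the maximum
      got <- sum(vapply(dict$selected_nodes, function(k)
        node_sparsity_oracle(tr$nodes[[k]]), numeric(1)))
      expect_equal(got, max(vals), tolerance = 1e-12)
    }
  }
})

test_that("Haar best basis concentrates piecewise-constant energy", {
  # 2 pieces on length 16: a handful of coefficients carry >= 99% energy
  x <- c(rep(3, 8), rep(-1, 8))
  sa <- sparse_approximate(x, family = "haar", level = 3, quality = 1)
  cf <- sort(as.vector(sa$coeffs)^2, decreasing = TRUE)
  n_big <- which(cumsum(cf) / sum(cf) >= 0.99)[1]
  expect_lte(n_big, 2 + 3)  # pieces + level
})

test_that("sparse approximation meets its energy-quality contract", {
  set.seed(12)
  X <- matrix(rnorm(3 * 128), 3)
  # lossless limit
  sa1 <- sparse_approximate(X, family = "db2", level = 3, quality = 1)
  err1 <- sqrt(sum((reconstruct_sparse(sa1$coeffs, sa1$dictionary) - X)^2) /
               sum(X^2))
  expect_lt(err1, 1e-8)
  expect_equal(sa1$quality, 1)
  # white noise at quality 0.95: relative error <= sqrt(0.05)
  sa2 <- sparse_approximate(X, family = "db2", level = 3, quality = 0.95)
  err2 <- sqrt(sum((reconstruct_sparse(sa2$coeffs, sa2$dictionary) - X)^2) /
               sum(X^2))
  expect_lte(err2, sqrt(0.05) + 1e-8)
  expect_lte(err2, sqrt(1 - sa2$quality) + 1e-8)
  expect_gt(sa2$nnz_fraction, 0)
  expect_lte(sa2$nnz_fraction, 1)
  # monotonicity: lower quality -> fewer nonzeros, more error
  sa3 <- sparse_approximate(X, family = "db2", level = 3, quality = 0.80)
  err3 <- sqrt(sum((reconstruct_sparse(sa3$coeffs, sa3$dictionary) - X)^2) /
               sum(X^2))
  expect_lte(sa3$nnz_fraction, sa2$nnz_fraction)
  expect_gte(err3, err2 - 1e-12)
})

test_that("identity dictionary is an exact bypass", {
  set.seed(3)
  X <- matrix(rnorm(2 * 50), 2)
  sa <- sparse_approximate(X, kind = "identity")
  expect_identical(sa$dictionary$kind, "identity")
  expect_length(sa$dictionary$selected_nodes, 0)
  expect_equal(sa$coeffs, X)
  expect_equal(reconstruct_sparse(sa$coeffs, sa$dictionary), X)
})

test_that("synthesis is linear and shape-checked", {
  set.seed(6)
  X <- matrix(rnorm(2 * 64), 2)
  sa <- sparse_approximate(X, family = "haar", level = 2, quality = 1)
  d <- sa$dictionary
  C1 <- matrix(rnorm(2 * d$atom_count), 2)
  C2 <- matrix(rnorm(2 * d$atom_count), 2)
  expect_equal(reconstruct_sparse(C1 + C2, d),
               reconstruct_sparse(C1, d) + reconstruct_sparse(C2, d),
               tolerance = 1e-10)
  expect_equal(reconstruct_sparse(0 * C1, d), matrix(0, 2, 64))
  expect_error(reconstruct_sparse(C1[, 1:10], d), "atom_count")
})

test_that("non-dyadic lengths round-trip through padding", {
  set.seed(14)
  X <- matrix(rnorm(2 * 100), 2)
  sa <- sparse_approximate(X, family = "db4", level = 2, quality = 1)
  expect_equal(reconstruct_sparse(sa$coeffs, sa$dictionary), X,
               tolerance = 1e-8)
  expect_equal(sa$dictionary$signal_length, 100L)
  expect_equal(sa$dictionary$n_pad, 128L)
})
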