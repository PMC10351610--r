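# Shared fixtures, all built in code under fixed seeds.

# A tiny 3-feature x 2-sample block.
tiny_block <- function(name = "mRNA") {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  omics_block(m, name = name)
}

# Write a delimited matrix file and return its path.
write_matrix_file <- function(values, row_ids, col_ids, sep = "\t",
                              path = tempfile(fileext = ".tsv")) {
  df <- data.frame(id = row_ids, values, check.names = FALSE)
  colnames(df) <- c("id", col_ids)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Random mixtures of independent Laplace sources: the canonical
# identifiable blind-source-separation problem.
laplace_mixture <- function(k, n, seed) {
  set.seed(seed)
  S <- matrix(stats::rexp(k * n) - stats::rexp(k * n), k)
  M <- matrix(stats::rnorm(k * k), k)
  list(X = M %*% S, M = M, S = S)
}

# Well-separated group constellations for the affinity-propagation oracle
# tests: ng groups at orthogonal centers (spread 4), noise SD 0.3,
# n <= 8 points. Defined as fixed seeded fixtures.
ap_constellations <- function(seeds = 1:6) {
  lapply(seeds, function(sd) {
    set.seed(sd + 100)
    ng <- sample(2:3, 1)
    npts <- sample(5:8, 1)
    centers <- matrix(0, 4, ng)
    for (j in seq_len(ng)) centers[j, j] <- 4
    asn <- sort(rep_len(seq_len(ng), npts))
    list(points = centers[, asn] + matrix(stats::rnorm(4 * npts, 0, 0.3), 4),
         groups = asn)
  })
}

# Exhaustive exemplar-set search maximizing the affinity-propagation
# energy: sum of each point's similarity to its exemplar plus the
# exemplars' preferences. Independent oracle for apc() on n <= 8 points.
ap_brute_force <- function(s, pref) {
  n <- nrow(s)
  best <- -Inf; best_ex <- NULL
  for (m in seq_len(2^n - 1)) {
    ex <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    e <- comodica:::ap_energy(s, ex, pref)
    if (e > best) { best <- e; best_ex <- ex }
  }
  list(exemplars = best_ex, energy = best)
}

# Node sparsity under the package's best-basis convention: Gini index,
# all-zero nodes scored 1 (the one-hot supremum).
node_sparsity_oracle <- function(v) {
  if (all(v == 0)) 1 else sparsity_measure(v)
}

# Enumerate all admissible prunings of a depth-`level` binary tree, as
# lists of node keys; independent oracle for the best-basis search.
enumerate_prunings <- function(level, depth = 0, index = 0) {
  key <- paste0(depth, ".", index)
  if (depth == level) return(list(key))
  left <- enumerate_prunings(level, depth + 1, 2 * index)
  right <- enumerate_prunings(level, depth + 1, 2 * index + 1)
  combos <- list()
  for (l in left) for (r in right) combos <- c(combos, list(c(l, r)))
  c(list(key), combos)
}

# Adjusted Rand index of two labelings (closed-form pair counting).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  np <- choose(length(a), 2)
  exp_ <- ai * bj / np
  (nij - exp_) / ((ai + bj) / 2 - exp_)
}
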