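# Periodized orthogonal wavelet-packet filter banks.
#
# All transforms here are circular (periodized), which keeps the analysis
# operator exactly orthogonal for any even signal length: Daubechies
# scaling filters have vanishing even-lag autocorrelation, so circular
# shifts by 2 stay orthonormal even when the filter wraps.

wavelet_filters <- function(family) {
  h <- switch(family,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.230377813308855, 0.714846570552542, 0.630880767929590,
            -0.027983769416984, -0.187034811718881, 0.030841381835987,
            0.032883011666983, -0.010597401784997),
    stop("unsupported wavelet family '", family,
         "'; supported families: haar, db2, db4"))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g, L = L)
}

# One periodized analysis step on the rows of X (d x n, n even):
# returns list(A, D), each d x n/2.
wp_analysis_step <- function(X, flt) {
  n <- ncol(X)
  stopifnot(n %% 2 == 0)
  n2 <- n / 2L
  A <- matrix(0, nrow(X), n2)
  D <- matrix(0, nrow(X), n2)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in seq_len(flt$L)) {
    idx <- (base + (m - 1L)) %% n + 1L
    A <- A + flt$h[m] * X[, idx, drop = FALSE]
    D <- D + flt$g[m] * X[, idx, drop = FALSE]
  }
  list(A = A, D = D)
}

# Adjoint of wp_analysis_step (exact inverse, by orthogonality).
wp_synthesis_step <- function(A, D, flt) {
  n2 <- ncol(A)
  n <- 2L * n2
  X <- matrix(0, nrow(A), n)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in seq_len(flt$L)) {
    idx <- (base + (m - 1L)) %% n + 1L
    X[, idx] <- X[, idx] + flt$h[m] * A + flt$g[m] * D
  }
  X
}

next_pow2 <- function(n) 2L^ceiling(log2(n))

# Reflection-pad the rows of X to the next dyadic length.
pad_dyadic <- function(X) {
  n <- ncol(X)
  n_pad <- next_pow2(n)
  if (n_pad > n) {
    extra <- n_pad - n
    # reflect (repeat backwards from the end); tile if shorter than needed
    src <- rev(seq_len(n))
    src <- rep_len(src, extra)
    X <- cbind(X, X[, src, drop = FALSE])
  }
  list(X = X, n = n, n_pad = n_pad)
}

node_key <- function(depth, index) paste0(depth, ".", index)

#' Full wavelet-packet coefficient tree
#'
#' Decomposes each row of `X` (treated as an ordered 1-D signal) into the
#' complete wavelet-packet tree down to `level`, using a periodized
#' orthogonal filter bank. Non-dyadic lengths are reflection-padded to the
#' next power of two (the padding is recorded and stripped on synthesis).
#'
#' @param X Numeric matrix, d x n (signals in rows), or a vector.
#' @param family Wavelet family: `"haar"`, `"db2"` or `"db4"`.
#' @param level Decomposition depth (>= 1); capped so that nodes keep at
#'   least 2 coefficients.
#' @return An object of class `wavelet_tree`: list with `nodes` (named list
#'   of coefficient matrices keyed `"depth.index"`), `family`, `level`,
#'   `n` (original length) and `n_pad`.
#' @export
decompose_tree <- function(X, family = "db4", level = NULL) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  flt <- wavelet_filters(family)
  p <- pad_dyadic(as.matrix(X))
  max_level <- as.integer(log2(p$n_pad))
  if (is.null(level)) level <- min(4L, max_level)
  level <- as.integer(level)
  if (level < 1) stop("level must be >= 1")
  if (level > max_level)
    stop("level ", level, " exceeds floor(log2(padded length)) = ", max_level)
  nodes <- list()
  nodes[[node_key(0, 0)]] <- p$X
  for (d in seq_len(level)) {
    for (i in seq_len(2L^(d - 1L)) - 1L) {
      ad <- wp_analysis_step(nodes[[node_key(d - 1L, i)]], flt)
      nodes[[node_key(d, 2L * i)]] <- ad$A
      nodes[[node_key(d, 2L * i + 1L)]] <- ad$D
    }
  }
  structure(list(nodes = nodes, family = family, level = level,
                 n = p$n, n_pad = p$n_pad),
            class = "wavelet_tree")
}

#' Gini sparsity index
#'
#' Scale-invariant sparsity measure on coefficient magnitudes: 0 for a
#' constant-magnitude vector, (n-1)/n for a one-hot vector (approaching 1
#' as n grows). Used as the additive node criterion in best-basis search.
#'
#' @param v Numeric vector (or matrix, flattened), not all zero.
#' @return Scalar in \[0, 1).
#' @export
sparsity_measure <- function(v) {
  c_ <- sort(abs(as.vector(v)))
  if (sum(c_) == 0) stop("sparsity_measure is undefined for an all-zero vector")
  N <- length(c_)
  1 - 2 * sum(c_ / sum(c_) * (N - seq_len(N) + 0.5) / N)
}

# Node criterion for the best-basis search: Gini sparsity, with an
# all-zero node scored at the one-hot supremum 1 (nothing to represent,
# so keeping it collapsed is always admissible).
node_sparsity <- function(v) {
  if (all(v == 0)) 1 else sparsity_measure(v)
}

# Best-basis dynamic programme: value(node) = max(own sparsity,
# sum of children's best values); a parent is kept when its sparsity is
# at least the children's total.
best_basis <- function(tree) {
  level <- tree$level
  val <- list(); keep <- list()
  for (d in level:0) {
    for (i in seq_len(2L^d) - 1L) {
      key <- node_key(d, i)
      s <- node_sparsity(tree$nodes[[key]])
      if (d == level) {
        val[[key]] <- s; keep[[key]] <- TRUE
      } else {
        child_val <- val[[node_key(d + 1L, 2L * i)]] +
          val[[node_key(d + 1L, 2L * i + 1L)]]
        if (s >= child_val) {
          val[[key]] <- s; keep[[key]] <- TRUE
        } else {
          val[[key]] <- child_val; keep[[key]] <- FALSE
        }
      }
    }
  }
  # walk down from the root collecting kept leaves, left to right
  leaves <- character(0)
  walk <- function(d, i) {
    key <- node_key(d, i)
    if (keep[[key]]) leaves <<- c(leaves, key)
    else { walk(d + 1L, 2L * i); walk(d + 1L, 2L * i + 1L) }
  }
  walk(0L, 0L)
  list(leaves = leaves, value = val[[node_key(0, 0)]])
}

#' Select an optimal sparse basis from a wavelet-packet tree
#'
#' Prunes the wavelet-packet tree to the admissible leaf tiling that
#' maximizes the total Gini sparsity of the leaf nodes (additive
#' best-basis search). An all-zero node scores the one-hot supremum 1.
#'
#' @param tree A [decompose_tree] result.
#' @param quality Default energy-retention target stored with the
#'   dictionary (used by [sparse_approximate] when thresholding).
#' @return An object of class `sparse_dictionary` with fields `kind`
#'   (`"wavelet_packet"`), `family`, `level`, `selected_nodes` (leaf keys in
#'   left-to-right order), `node_lengths`, `atom_count`, `signal_length`
#'   (`n`), `n_pad` and `quality`.
#' @export
select_nodes <- function(tree, quality = 0.95) {
  stopifnot(inherits(tree, "wavelet_tree"), quality > 0, quality <= 1)
  bb <- best_basis(tree)
  node_lengths <- vapply(bb$leaves, function(k) ncol(tree$nodes[[k]]),
                         integer(1))
  structure(list(kind = "wavelet_packet", family = tree$family,
                 level = tree$level, selected_nodes = bb$leaves,
                 node_lengths = node_lengths, atom_count = tree$n_pad,
                 signal_length = tree$n, n_pad = tree$n_pad,
                 quality = quality, basis_value = bb$value),
            class = "sparse_dictionary")
}

#' Identity dictionary (sparse-approximation bypass)
#'
#' @param n Signal length; atoms are the canonical unit vectors.
#' @return A `sparse_dictionary` of kind `"identity"`.
#' @export
identity_dictionary <- function(n) {
  structure(list(kind = "identity", family = NA_character_, level = 0L,
                 selected_nodes = character(0),
                 node_lengths = integer(0), atom_count = as.integer(n),
                 signal_length = as.integer(n), n_pad = as.integer(n),
                 quality = 1), class = "sparse_dictionary")
}

#' @export
print.sparse_dictionary <- function(x, ...) {
  if (x$kind == "identity")
    cat("<sparse_dictionary> identity,", x$atom_count, "atoms\n")
  else
    cat("<sparse_dictionary> wavelet_packet (", x$family, "), level ",
        x$level, ", ", length(x$selected_nodes), " leaf nodes, ",
        x$atom_count, " atoms\n", sep = "")
  invisible(x)
}

# Analysis of X under a fixed dictionary: d x atom_count coefficients.
analyze_sparse <- function(X, dict) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (dict$kind == "identity") {
    stopifnot(ncol(X) == dict$atom_count)
    return(as.matrix(X))
  }
  tree <- decompose_tree(X, dict$family, dict$level)
  stopifnot(tree$n_pad == dict$n_pad)
  do.call(cbind, lapply(dict$selected_nodes, function(k) tree$nodes[[k]]))
}

#' Synthesize signals from sparse coefficients
#'
#' Inverse transform restricted to the dictionary's selected nodes; linear
#' in the coefficients. Padding introduced at analysis time is stripped.
#'
#' @param C Coefficient matrix, d x atom_count.
#' @param dict A `sparse_dictionary`.
#' @return d x signal_length matrix.
#' @export
reconstruct_sparse <- function(C, dict) {
  if (is.vector(C)) C <- matrix(C, nrow = 1)
  stopifnot(inherits(dict, "sparse_dictionary"))
  if (ncol(C) != dict$atom_count)
    stop("coefficient columns (", ncol(C), ") != atom_count (",
         dict$atom_count, ")")
  if (dict$kind == "identity") return(as.matrix(C))
  flt <- wavelet_filters(dict$family)
  # split the coefficient vector back into leaf-node segments
  ends <- cumsum(dict$node_lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  nodes <- list()
  for (j in seq_along(dict$selected_nodes))
    nodes[[dict$selected_nodes[j]]] <- C[, starts[j]:ends[j], drop = FALSE]
  # merge siblings bottom-up
  for (d in dict$level:1) {
    keys <- names(nodes)
    depths <- as.integer(sub("\\..*", "", keys))
    for (key in keys[depths == d]) {
      if (is.null(nodes[[key]])) next
      i <- as.integer(sub(".*\\.", "", key))
      sib_i <- ifelse(i %% 2L == 0L, i + 1L, i - 1L)
      a_i <- min(i, sib_i)
      A <- nodes[[node_key(d, a_i)]]
      D <- nodes[[node_key(d, a_i + 1L)]]
      nodes[[node_key(d - 1L, a_i %/% 2L)]] <- wp_synthesis_step(A, D, flt)
      nodes[[node_key(d, a_i)]] <- NULL
      nodes[[node_key(d, a_i + 1L)]] <- NULL
    }
  }
  out <- nodes[[node_key(0, 0)]]
  out[, seq_len(dict$signal_length), drop = FALSE]
}

#' Sparse approximation of a matrix under a wavelet-packet dictionary
#'
#' Composes [decompose_tree] and [select_nodes], then zeroes the smallest
#' coefficients (globally, by magnitude) while the retained energy stays at
#' or above `quality` of the total. The achieved quality is re-measured
#' against the original input, so the reconstruction-error bound
#' relative Frobenius error <= sqrt(1 - quality) holds by construction.
#'
#' @param X Numeric matrix, d x n (rows are signals over the feature axis).
#' @param family Wavelet family (ignored for `kind = "identity"`).
#' @param level Decomposition depth (default `min(4, log2(padded n))`).
#' @param quality Energy-retention target in (0, 1].
#' @param kind `"wavelet_packet"` or `"identity"`.
#' @return An object of class `sparse_approx`: list with `dictionary`,
#'   `coeffs` (d x atom_count), `quality` (achieved), `nnz_fraction`.
#' @export
sparse_approximate <- function(X, family = "db4", level = NULL,
                               quality = 0.95,
                               kind = c("wavelet_packet", "identity")) {
  kind <- match.arg(kind)
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  stopifnot(quality > 0, quality <= 1)
  if (kind == "identity") {
    dict <- identity_dictionary(ncol(X))
    return(structure(list(dictionary = dict, coeffs = X, quality = 1,
                          nnz_fraction = max(mean(X != 0), .Machine$double.xmin)),
                     class = "sparse_approx"))
  }
  tree <- decompose_tree(X, family, level)
  dict <- select_nodes(tree, quality)
  C <- do.call(cbind, lapply(dict$selected_nodes, function(k) tree$nodes[[k]]))
  if (quality < 1) {
    e <- as.vector(C)^2
    total <- sum(e)
    ord <- order(e)
    drop_energy <- cumsum(e[ord])
    n_drop <- sum(drop_energy <= (1 - quality) * total)
    if (n_drop > 0) C[ord[seq_len(n_drop)]] <- 0
  }
  Xhat <- reconstruct_sparse(C, dict)
  nX <- sum(X^2)
  achieved <- if (nX == 0) 1 else max(0, min(1, 1 - sum((X - Xhat)^2) / nX))
  structure(list(dictionary = dict, coeffs = C, quality = achieved,
                 nnz_fraction = max(mean(C != 0), .Machine$double.xmin)),
            class = "sparse_approx")
}

#' @export
print.sparse_approx <- function(x, ...) {
  cat("<sparse_approx>", nrow(x$coeffs), "x", ncol(x$coeffs),
      sprintf("coefficients, quality %.4f, nnz %.3f\n",
              x$quality, x$nnz_fraction))
  invisible(x)
}
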