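# Affinity propagation: exemplar-based clustering by responsibility /
# availability message passing. Deterministic given its inputs (the only
# randomness is a seeded 1e-12 tie-breaking jitter on the similarities).

#' Pairwise similarity of basis columns
#'
#' @param columns Matrix with observations in columns, or a list of
#'   equal-length vectors.
#' @param metric `"neg_sqeuclid_signfree"`:
#'   `s(i,k) = -min(||xi - xk||^2, ||xi + xk||^2)` (invariant to the sign
#'   indeterminacy of ICA basis columns); or `"abs_correlation"`:
#'   `|Pearson r| - 1`.
#' @return Symmetric n x n similarity matrix with zero diagonal,
#'   non-positive off-diagonal.
#' @export
similarity_matrix <- function(columns,
                              metric = c("neg_sqeuclid_signfree",
                                         "abs_correlation")) {
  metric <- match.arg(metric)
  if (is.list(columns)) columns <- do.call(cbind, columns)
  columns <- as.matrix(columns)
  n <- ncol(columns)
  if (n < 2) stop("at least 2 columns are required")
  if (metric == "neg_sqeuclid_signfree") {
    sq <- colSums(columns^2)
    G <- crossprod(columns)                       # x_i . x_k
    d_minus <- outer(sq, sq, "+") - 2 * G
    d_plus <- outer(sq, sq, "+") + 2 * G
    s <- -pmin(d_minus, d_plus)
    s[s > 0] <- 0                                 # numerical guard
  } else {
    v <- apply(columns, 2, stats::sd)
    if (any(v == 0))
      stop("zero-variance column(s) under the correlation metric: ",
           paste(which(v == 0), collapse = ", "))
    s <- abs(stats::cor(columns)) - 1
  }
  diag(s) <- 0
  (s + t(s)) / 2
}

#' Affinity propagation clustering
#'
#' Standard responsibility / availability message passing:
#' `r(i,k) <- s(i,k) - max_{k' != k} (a(i,k') + s(i,k'))` and
#' `a(i,k) <- min(0, r(k,k) + sum_{i' not in (i,k)} max(0, r(i',k)))` for
#' `i != k`, `a(k,k) <- sum_{i' != k} max(0, r(i',k))`, with damping.
#' Exemplars are points with `r(k,k) + a(k,k) > 0`; the run stops when the
#' exemplar set is stable for `conv_window` iterations.
#'
#' @param similarity Square symmetric similarity matrix.
#' @param preference Scalar, per-point vector, or `"median"` (median of the
#'   off-diagonal similarities; the common convention). Placed on the
#'   diagonal; larger values yield more clusters.
#' @param damping Message damping factor in \[0.5, 1).
#' @param max_iter Maximum iterations.
#' @param conv_window Iterations of exemplar-set stability required.
#' @param tie_jitter Scale of the seeded symmetric jitter added to break
#'   exact ties (relative to the similarity range).
#' @param seed Seed for the tie-breaking jitter.
#' @return Object of class `apc_result`: `labels` (exemplar index per
#'   point), `exemplars`, `n_clusters`, `converged`, `n_iter`,
#'   `similarity`, `responsibility`, `availability`, `preference`,
#'   `damping`.
#' @export
apc <- function(similarity, preference = "median", damping = 0.9,
                max_iter = 1000, conv_window = 50, tie_jitter = 1e-12,
                seed = 0) {
  s <- as.matrix(similarity)
  n <- nrow(s)
  stopifnot(ncol(s) == n, damping >= 0.5, damping < 1)
  if (n == 1)
    return(structure(list(labels = 1L, exemplars = 1L, n_clusters = 1L,
                          converged = TRUE, n_iter = 0L, similarity = s,
                          responsibility = matrix(0, 1, 1),
                          availability = matrix(0, 1, 1),
                          preference = if (identical(preference, "median")) 0
                                       else preference,
                          damping = damping),
                     class = "apc_result"))
  if (max(abs(s - t(s))) > 1e-8 * max(1, max(abs(s))))
    stop("similarity matrix must be symmetric")
  off <- s[row(s) != col(s)]
  pref <- if (identical(preference, "median")) stats::median(off) else preference
  diag(s) <- pref
  scale <- max(abs(s)); if (scale == 0) scale <- 1
  jit <- local({
    set.seed(seed)
    matrix(stats::rnorm(n * n), n)
  })
  s <- s + tie_jitter * scale * (jit + t(jit)) / 2

  R <- matrix(0, n, n); A <- matrix(0, n, n)
  stable <- 0L; exemplars_prev <- integer(0); converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + s
    max1_idx <- max.col(AS, ties.method = "first")
    max1 <- AS[cbind(seq_len(n), max1_idx)]
    AS2 <- AS; AS2[cbind(seq_len(n), max1_idx)] <- -Inf
    max2 <- AS2[cbind(seq_len(n), max.col(AS2, ties.method = "first"))]
    Rnew <- s - max1
    Rnew[cbind(seq_len(n), max1_idx)] <- s[cbind(seq_len(n), max1_idx)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)                      # keep r(k,k) in the column sum
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)                         # a(k,k) = sum_{i'!=k} max(0, r)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    if (any(!is.finite(R)) || any(!is.finite(A)))
      stop("non-finite messages encountered")
    exemplars <- which(diag(R) + diag(A) > 0)
    if (length(exemplars) > 0 && identical(exemplars, exemplars_prev)) {
      stable <- stable + 1L
      if (stable >= conv_window) { converged <- TRUE; break }
    } else stable <- 0L
    exemplars_prev <- exemplars
  }
  exemplars <- which(diag(R) + diag(A) > 0)
  if (length(exemplars) == 0)
    stop("no exemplar emerged after ", it,
         " iterations; consider raising the preference")
  labels <- exemplars[max.col(s[, exemplars, drop = FALSE],
                              ties.method = "first")]
  labels[exemplars] <- exemplars
  structure(list(labels = labels, exemplars = exemplars,
                 n_clusters = length(exemplars), converged = converged,
                 n_iter = it, similarity = s, responsibility = R,
                 availability = A, preference = pref, damping = damping),
            class = "apc_result")
}

#' @export
print.apc_result <- function(x, ...) {
  cat("<apc_result>", x$n_clusters, "cluster(s) from",
      length(x$labels), "points in", x$n_iter, "iterations",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

# Net similarity of an exemplar assignment (used by tests and diagnostics):
# sum over non-exemplars of s(i, exemplar(i)) plus the exemplars' own
# preferences.
ap_energy <- function(s, exemplars, preference) {
  s <- as.matrix(s)
  diag(s) <- preference
  n <- nrow(s)
  non <- setdiff(seq_len(n), exemplars)
  e <- sum(s[cbind(exemplars, exemplars)])
  if (length(non))
    e <- e + sum(apply(s[non, exemplars, drop = FALSE], 1, max))
  e
}
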