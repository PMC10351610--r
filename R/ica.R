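# Equality-constrained negentropy-maximizing ICA on sparse coefficients.
#
# Per component w the problem is
#   maximize  J(w) = (E[G(w'z)] - E[G(v)])^2,  G = log cosh, v ~ N(0,1)
#   s.t.      h(w) = E[(w'z)^2] - 1 = 0
# solved by a fixed-point (quasi-Newton) update on the augmented Lagrangian
#   L(w) = J(w) - mu h(w) - (gamma/2) h(w)^2
# with symmetric decorrelation across components each sweep. An optional
# slack variable c converts an inequality form of the constraint into the
# equality  h(w) + c = 0.

# numerically stable log cosh
logcosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)

#' Expected log-cosh of a standard Gaussian
#'
#' The baseline E\[G(v)\], v ~ N(0,1), of the negentropy approximation,
#' computed once by adaptive quadrature and cached (about 0.3745672).
#'
#' @return Scalar.
#' @export
gauss_logcosh_baseline <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- stats::integrate(function(x) logcosh(x) * stats::dnorm(x),
                                 -Inf, Inf, rel.tol = 1e-12)$value
    cache
  }
})

#' Whiten the rows of a coefficient matrix
#'
#' Linear transform making the (already row-centered) data have identity
#' sample covariance: `Z = T %*% C`, with `Tinv %*% T = I` on the retained
#' subspace. Expectations use the 1/m convention.
#'
#' @param C Numeric matrix, d x m, rows centered.
#' @param n_components Minimum rank required (error if the numeric rank is
#'   lower).
#' @return List with `Z` (r x m, identity covariance), `T` (r x d),
#'   `Tinv` (d x r) and `rank`.
#' @export
whiten <- function(C, n_components = NULL) {
  C <- as.matrix(C)
  m <- ncol(C)
  sv <- svd(C)
  tol <- max(dim(C)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > max(tol, 1e-12 * sv$d[1]))
  if (!is.null(n_components) && r < n_components)
    stop("numeric rank ", r, " is below the requested ", n_components,
         " components")
  d_r <- sv$d[seq_len(r)]
  U <- sv$u[, seq_len(r), drop = FALSE]
  Tm <- diag(sqrt(m) / d_r, r) %*% t(U)
  Tinv <- U %*% diag(d_r / sqrt(m), r)
  list(Z = Tm %*% C, T = Tm, Tinv = Tinv, rank = r)
}

#' Negentropy contrast of a projection
#'
#' `J(w) = (mean(G(w'Z)) - E[G(v)])^2` with `G = log cosh` and `v`
#' standard Gaussian; non-negative, and zero exactly when the projection
#' matches the Gaussian baseline.
#'
#' @param w Unit-norm direction vector.
#' @param Z Whitened data matrix (rows = dimensions, columns = samples).
#' @param gauss_baseline Baseline `E[G(v)]`; defaults to
#'   [gauss_logcosh_baseline()].
#' @return Scalar `J(w) >= 0`.
#' @export
negentropy_contrast <- function(w, Z, gauss_baseline = gauss_logcosh_baseline()) {
  if (sum(w^2) == 0) stop("w must be a nonzero vector")
  y <- as.vector(crossprod(w, Z))
  (mean(logcosh(y)) - gauss_baseline)^2
}

# symmetric (parallel) decorrelation: W <- (W W')^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                     length(e$values)) %*% t(e$vectors) %*% W
}

#' Default configuration for the constrained ICA solver
#'
#' @param n_components Number of components k.
#' @param max_iter Maximum fixed-point sweeps.
#' @param tol Convergence tolerance on the unmixing-vector change
#'   (`1 - |<w_new, w_old>|`).
#' @param seed Integer seed for the random orthonormal initialization.
#' @param penalty_init,penalty_growth Augmented-Lagrangian penalty gamma and
#'   its growth factor (applied when the constraint violation fails to
#'   halve between sweeps).
#' @param slack_init Initial slack value c in the equality form
#'   `h(w) + c = 0`.
#' @return List of class `ica_config`.
#' @export
ica_config <- function(n_components, max_iter = 500, tol = 1e-6, seed = 1,
                       penalty_init = 1, penalty_growth = 2,
                       slack_init = 0) {
  stopifnot(n_components >= 1, max_iter >= 1, tol > 0, penalty_growth >= 1)
  structure(list(n_components = as.integer(n_components),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), contrast = "logcosh",
                 gauss_baseline = gauss_logcosh_baseline(),
                 penalty_init = penalty_init,
                 penalty_growth = penalty_growth,
                 slack_init = slack_init),
            class = "ica_config")
}

#' Fit the equality-constrained negentropy ICA
#'
#' Decomposes the coefficient matrix `C_X` (d x m) into a common basis `A`
#' (d x k) and unit-variance, pairwise-uncorrelated coefficient sources
#' `C_S` (k x m) with `C_X ~ A %*% C_S` (+ row means). Each component
#' maximizes the log-cosh negentropy approximation subject to the
#' unit-variance equality constraint, via an augmented-Lagrangian
#' fixed-point iteration with symmetric decorrelation. Components are
#' ordered by decreasing negentropy; each basis column's sign is fixed so
#' its largest-magnitude entry is positive.
#'
#' @param C_X Numeric matrix d x m (rows = reduced sample dimensions,
#'   columns = dictionary atoms or features).
#' @param config An [ica_config].
#' @param dictionary Optional `sparse_dictionary`; when supplied, the
#'   feature-space module matrix `S = reconstruct_sparse(C_S, dictionary)`
#'   is attached.
#' @return Object of class `cica` with elements `W` (k x d unmixing for
#'   centered `C_X`), `A` (d x k), `C_S` (k x m), `S` (k x signal_length or
#'   NULL), `Y` (alias of `C_S`, estimated sources), `row_means`,
#'   `negentropy` (per component), `converged` (per component), `n_iter`,
#'   `objective_trace`, `constraint_violation`, `seed`.
#' @export
cica_fit <- function(C_X, config, dictionary = NULL) {
  stopifnot(inherits(config, "ica_config"))
  C_X <- as.matrix(C_X)
  d <- nrow(C_X); m <- ncol(C_X)
  k <- config$n_components
  if (k > d) stop("n_components (", k, ") exceeds data dimension (", d, ")")
  if (m < d) stop("need at least as many columns as rows (m >= d)")
  mu_row <- rowMeans(C_X)
  Cc <- C_X - mu_row
  wh <- whiten(Cc, n_components = k)
  Z <- wh$Z
  g0 <- config$gauss_baseline

  rs <- local({ set.seed(config$seed); matrix(stats::rnorm(k * wh$rank), k) })
  W <- sym_decorrelate(rs)

  lag_mu <- rep(0, k)              # Lagrange multipliers
  gamma <- config$penalty_init     # shared penalty weight
  slack <- rep(config$slack_init, k)
  prev_viol <- Inf
  obj_trace <- numeric(0)
  n_iter <- config$max_iter
  converged <- rep(FALSE, k)

  for (it in seq_len(config$max_iter)) {
    Y <- W %*% Z                                  # k x m
    gy <- tanh(Y)
    rho <- rowMeans(logcosh(Y)) - g0              # signed negentropy root
    h <- rowMeans(Y^2) - 1 + slack                # constraint values
    Egp <- rowMeans(1 - gy^2)                     # E[g'(y)]
    EZg <- tcrossprod(gy, Z) / m                  # k x r: E[z g(y)] rows
    lam <- lag_mu + gamma * h
    # quasi-Newton step on the augmented Lagrangian; with lam the step
    # direction reduces to rho * (E[z g(y)] - E[g'(y)] w), the classical
    # negentropy fixed-point direction scaled by the signed negentropy root
    num <- rho * EZg - lam * W
    den <- rho * Egp - lam
    W_new <- num - den * W
    rn <- sqrt(rowSums(W_new^2))
    bad <- rn < 1e-12
    if (any(bad)) { W_new[bad, ] <- W[bad, , drop = FALSE]; rn[bad] <- 1 }
    W_new <- W_new / rn
    W_new <- sym_decorrelate(W_new)
    delta <- 1 - abs(rowSums(W_new * W))
    obj_trace <- c(obj_trace, sum(rho^2 - lag_mu * h - gamma / 2 * h^2))
    W <- W_new
    # multiplier / penalty schedule
    viol <- max(abs(h))
    lag_mu <- lag_mu + gamma * h
    if (is.finite(prev_viol) && viol > prev_viol / 2 && viol > config$tol)
      gamma <- gamma * config$penalty_growth
    prev_viol <- viol
    converged <- delta < config$tol
    if (all(converged)) {
      n_iter <- it
      break
    }
  }
  if (!all(converged))
    warning("constrained ICA did not converge in ", config$max_iter,
            " sweeps (max direction change ",
            format(max(delta), digits = 3), ")")

  C_S <- W %*% Z
  negent <- (rowMeans(logcosh(C_S)) - g0)^2
  ord <- order(negent, decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  C_S <- C_S[ord, , drop = FALSE]
  negent <- negent[ord]
  A <- wh$Tinv %*% t(W)                            # d x k
  flip <- vapply(seq_len(k), function(j)
    sign(A[which.max(abs(A[, j])), j]), numeric(1))
  flip[flip == 0] <- 1
  A <- sweep(A, 2, flip, "*")
  C_S <- C_S * flip
  W <- W * flip
  W_data <- W %*% wh$T                             # k x d, acts on centered C_X
  S <- if (!is.null(dictionary)) reconstruct_sparse(C_S, dictionary) else NULL
  structure(list(W = W_data, A = A, C_S = C_S, S = S, Y = C_S,
                 row_means = mu_row, negentropy = negent,
                 converged = converged, n_iter = n_iter,
                 objective_trace = obj_trace,
                 constraint_violation = max(abs(rowMeans(C_S^2) - 1)),
                 rank = wh$rank, seed = config$seed),
            class = "cica")
}

#' @export
print.cica <- function(x, ...) {
  cat("<cica> ", nrow(x$C_S), " components, ", x$n_iter, " sweeps, ",
      if (all(x$converged)) "converged" else "NOT converged",
      sprintf("; max |var-1| = %.2e\n", x$constraint_violation), sep = "")
  invisible(x)
}

#' Reconstruct per-block expression from a decomposition
#'
#' Computes `A %*% C_S` (+ stored coefficient row means) in the reduced
#' coefficient space, synthesizes back to the reduced feature space through
#' the dictionary, maps through the retained principal components (adding
#' back per-feature means), and slices the resulting samples x features
#' matrix per block.
#'
#' @param dec A [cica_fit] result (fitted with a dictionary).
#' @param ms The aligned [multi_omics] input.
#' @param pca The [pca_reduce] result used in the pipeline.
#' @param dictionary The `sparse_dictionary` used in the pipeline.
#' @return Named list of features x samples matrices, one per block.
#' @export
reconstruct_blocks <- function(dec, ms, pca, dictionary) {
  stopifnot(inherits(dec, "cica"), inherits(ms, "multi_omics"),
            inherits(pca, "pca_reduction"),
            inherits(dictionary, "sparse_dictionary"))
  C_hat <- dec$A %*% dec$C_S + dec$row_means
  if (nrow(C_hat) != pca$k)
    stop("decomposition dimension (", nrow(C_hat),
         ") does not match PCA dimension (", pca$k, ")")
  red_hat <- reconstruct_sparse(C_hat, dictionary)   # k x total_features
  full <- pca_backproject(pca, red_hat)              # samples x features
  out <- list()
  for (j in seq_len(nrow(ms$boundaries))) {
    b <- ms$boundaries[j, ]
    blk <- t(full[, b$start:b$end, drop = FALSE])
    dimnames(blk) <- list(ms$blocks[[j]]$feature_ids, ms$sample_ids)
    out[[b$block]] <- blk
  }
  out
}
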