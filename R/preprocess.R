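#' Normalize an expression block
#'
#' Count normalization applied per block before concatenation, so that
#' blocks with incomparable library scales (e.g. mRNA vs miRNA counts)
#' become comparable.
#'
#' @param block An [omics_block].
#' @param method `"log_cpm"` (per-sample scaling to a fixed library size of
#'   1e6 followed by log2(x + 1)), `"log1p"` (log2(x + 1) without library
#'   scaling), or `"none"` (identity).
#' @return A normalized [omics_block].
#' @export
normalize_block <- function(block, method = c("log_cpm", "log1p", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(block, "omics_block"))
  if (method == "none") return(block)
  v <- block$values
  if (any(v < 0))
    stop("negative values are incompatible with count normalization '",
         method, "'")
  if (method == "log_cpm") {
    libsize <- colSums(v)
    libsize[libsize == 0] <- 1  # all-zero sample stays all-zero
    v <- sweep(v, 2, libsize, "/") * 1e6
  }
  omics_block(log2(v + 1), name = block$name)
}

#' PCA reduction of the sample dimension
#'
#' Centers each feature, then takes the smallest number of principal
#' components whose cumulative variance contribution reaches `threshold`.
#' The components live in sample space, so the projection reduces the
#' sample dimension: the working matrix thereafter is k x total_features.
#' Component signs are fixed by making each component's largest-magnitude
#' entry positive, for reproducibility.
#'
#' @param X Numeric matrix, samples x total_features.
#' @param threshold Target cumulative variance fraction in (0, 1]. With
#'   `threshold = 1` the numeric rank of the centered matrix is selected.
#' @param max_k Optional cap on the selected component count.
#' @return An object of class `pca_reduction`: list with `components`
#'   (samples x k, orthonormal columns), `explained_ratio` (all nonzero
#'   components), `k`, `threshold`, `reduced` (k x total_features scores),
#'   `feature_means` and `n_samples`.
#' @export
pca_reduce <- function(X, threshold = 0.90, max_k = NULL) {
  X <- as.matrix(X)
  if (!(is.numeric(threshold) && length(threshold) == 1 &&
        threshold > 0 && threshold <= 1))
    stop("threshold must be a single value in (0, 1]")
  if (nrow(X) < 2) stop("at least 2 samples are required")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  tol <- max(tol, 1e-10 * sv$d[1])
  r <- sum(sv$d > tol)
  if (r == 0) stop("matrix has numeric rank 0 after centering")
  d2 <- sv$d[seq_len(r)]^2
  ratio <- d2 / sum(d2)
  k <- which(cumsum(ratio) >= threshold - 1e-9)[1]
  if (is.na(k)) k <- r
  if (!is.null(max_k)) k <- min(k, max_k)
  U <- sv$u[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading of each component positive
  flip <- vapply(seq_len(k), function(j) {
    u <- U[, j]
    sign(u[which.max(abs(u))])
  }, numeric(1))
  U <- sweep(U, 2, flip, "*")
  reduced <- t(U) %*% Xc
  structure(list(components = U, explained_ratio = ratio, k = k,
                 threshold = threshold, reduced = reduced,
                 feature_means = mu, n_samples = nrow(X)),
            class = "pca_reduction")
}

#' @export
print.pca_reduction <- function(x, ...) {
  cat("<pca_reduction> k =", x$k, "components at threshold", x$threshold,
      sprintf("(%.1f%% variance)\n",
              100 * sum(x$explained_ratio[seq_len(x$k)])))
  invisible(x)
}

#' Map a reduced-space matrix back to sample space
#'
#' @param pca A [pca_reduce] result.
#' @param reduced A k x total_features matrix in the reduced space
#'   (defaults to the stored scores).
#' @param add_means Whether to add back the per-feature means.
#' @return Samples x total_features matrix.
#' @export
pca_backproject <- function(pca, reduced = pca$reduced, add_means = TRUE) {
  stopifnot(inherits(pca, "pca_reduction"))
  out <- pca$components %*% reduced
  if (add_means) out <- sweep(out, 2, pca$feature_means, "+")
  out
}
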