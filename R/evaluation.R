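#' Sample-wise correlations between a block and its reconstruction
#'
#' One Pearson correlation per sample, computed across that sample's
#' features; the summary mirrors the histogram-style evaluation of
#' reconstruction fidelity per RNA block. Zero-variance samples yield `NA`.
#'
#' @param X Block matrix, features x samples.
#' @param X_hat Reconstruction, same shape.
#' @return List with `r` (per-sample correlations), `mean`, `sd`
#'   (`NA`-removed).
#' @export
sample_correlations <- function(X, X_hat) {
  X <- as.matrix(X); X_hat <- as.matrix(X_hat)
  if (!all(dim(X) == dim(X_hat)))
    stop("X and X_hat must have identical shapes")
  r <- vapply(seq_len(ncol(X)), function(j) {
    if (stats::sd(X[, j]) == 0 || stats::sd(X_hat[, j]) == 0)
      return(NA_real_)
    stats::cor(X[, j], X_hat[, j])
  }, numeric(1))
  names(r) <- colnames(X)
  list(r = r, mean = mean(r, na.rm = TRUE), sd = stats::sd(r[!is.na(r)]))
}

#' Amari index of a gain matrix
#'
#' Permutation- and scale-invariant distance of `P = W_est %*% M_true` from
#' a scaled permutation: `(sum_i (sum_j |p_ij| / max_j |p_ij| - 1) +
#' sum_j (sum_i |p_ij| / max_i |p_ij| - 1)) / (2 k^2)`. Zero exactly when
#' `P` is a scaled permutation; 0.5 for the all-ones 2 x 2 matrix.
#'
#' @param P Square gain matrix with no all-zero row or column.
#' @return Scalar >= 0.
#' @export
amari_index <- function(P) {
  P <- abs(as.matrix(P))
  k <- nrow(P)
  if (ncol(P) != k) stop("P must be square")
  if (any(apply(P, 1, max) == 0) || any(apply(P, 2, max) == 0))
    stop("P has an all-zero row or column")
  rowterm <- sum(rowSums(P / apply(P, 1, max)) - 1)
  colterm <- sum(colSums(sweep(P, 2, apply(P, 2, max), "/")) - 1)
  (rowterm + colterm) / (2 * k^2)
}

#' Precision / recall / F1 of recovered feature sets
#'
#' @param truth Named list of character vectors (per-block planted sets).
#' @param found Named list of character vectors (same block names).
#' @return Data frame with one row per block plus a `"pooled"` row:
#'   `block`, `precision`, `recall`, `f1`. Empty `found` has precision 1
#'   when `truth` is empty, else 0; empty truth and found give F1 = 1.
#' @export
set_recovery <- function(truth, found) {
  stopifnot(is.list(truth), is.list(found))
  blocks <- names(truth)
  score <- function(tr, fo) {
    tp <- length(intersect(tr, fo))
    prec <- if (length(fo) == 0) as.numeric(length(tr) == 0) else tp / length(fo)
    rec <- if (length(tr) == 0) 1 else tp / length(tr)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1)
  }
  per <- t(vapply(blocks, function(b) score(truth[[b]], found[[b]]),
                  numeric(3)))
  pooled <- score(unlist(lapply(blocks, function(b) paste0(b, ":", truth[[b]]))),
                  unlist(lapply(blocks, function(b) paste0(b, ":", found[[b]]))))
  out <- data.frame(block = c(blocks, "pooled"),
                    rbind(per, pooled), row.names = NULL)
  out
}
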