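#' Sparse consensus ICA co-module discovery
#'
#' The package's main fitting function. Runs the full pipeline on an
#' aligned multi-block expression set: per-block normalization, block
#' concatenation, PCA reduction of the sample dimension at a
#' variance-contribution threshold, wavelet-packet sparse approximation
#' along the feature axis, `n_runs` seeded constrained-ICA decompositions,
#' affinity-propagation clustering of the pooled basis columns,
#' sign-aligned signature aggregation per cluster, and two-sided z-score
#' selection of co-module members per RNA block.
#'
#' @param ms A [multi_omics] set (from [align_samples]), or a list of
#'   [omics_block] objects which is aligned first.
#' @param n_components Components per ICA run; default the PCA-selected
#'   dimension.
#' @param n_runs Number of seeded runs pooled into the consensus
#'   (default 20).
#' @param alpha Two-sided significance level for element selection
#'   (default 0.05; the z cut-off is `qnorm(1 - alpha/2)`, 1.96).
#' @param normalize Per-block normalization: `"log_cpm"`, `"log1p"` or
#'   `"none"`.
#' @param pca_threshold Cumulative variance-contribution target
#'   (default 0.90).
#' @param pca_max_k Optional cap on the PCA dimension.
#' @param sparse_kind `"wavelet_packet"` or `"identity"` (bypass).
#' @param sparse_family,sparse_level,sparse_quality Wavelet dictionary
#'   settings. The pipeline default is a shallow lossless transform (Haar,
#'   depth 1, energy retention 1.0): expression features carry no natural
#'   ordering, and deep packets or aggressive coefficient thresholding on
#'   an unordered axis degrade the non-Gaussianity the decomposition
#'   relies on (see the methods vignette). Deeper Daubechies dictionaries
#'   with `sparse_quality < 1` are appropriate when the feature axis is a
#'   genuinely ordered signal.
#' @param apc_preference,apc_damping,apc_max_iter Affinity-propagation
#'   settings (median preference, damping 0.9).
#' @param zscore_scope `"joint"` z-scoring across all features (default)
#'   or `"per_block"`.
#' @param combine Combine per-cluster selections across clusters by
#'   `"intersection"` (default, the literal consensus rule) or `"union"`.
#' @param max_iter,tol Constrained-ICA solver settings.
#' @param seed Base seed; run r uses `seed + r - 1`.
#' @return An object of class `scica`: list with `comodules`
#'   (`comodule_set` with `selected`/`final` stages filled), `apc`
#'   ([apc] result on the pooled columns), `decompositions`,
#'   `pooled_basis`, `prep` (`ms`, `pca`, `sparse`), `settings`, `call`.
#' @seealso [simulate_comodules] to generate inputs with known truth;
#'   [reconstruct_blocks] and [sample_correlations] for reconstruction
#'   fidelity.
#' @examples
#' sim <- simulate_comodules(n_samples = 30, block_sizes = c(60, 30),
#'                           k = 2, module_size = c(8, 5), seed = 1)
#' fit <- scica(sim$ms, n_components = 2, n_runs = 3, normalize = "none",
#'              sparse_kind = "identity", seed = 1)
#' print(fit)
#' @export
scica <- function(ms, n_components = NULL, n_runs = 20, alpha = 0.05,
                  normalize = c("log_cpm", "log1p", "none"),
                  pca_threshold = 0.90, pca_max_k = NULL,
                  sparse_kind = c("wavelet_packet", "identity"),
                  sparse_family = "haar", sparse_level = 1,
                  sparse_quality = 1,
                  apc_preference = "median", apc_damping = 0.9,
                  apc_max_iter = 1000,
                  zscore_scope = c("joint", "per_block"),
                  combine = c("intersection", "union"),
                  max_iter = 500, tol = 1e-6, seed = 1) {
  normalize <- match.arg(normalize)
  sparse_kind <- match.arg(sparse_kind)
  zscore_scope <- match.arg(zscore_scope)
  combine <- match.arg(combine)
  if (!inherits(ms, "multi_omics")) ms <- align_samples(ms)
  runs <- multi_run(ms, n_components = n_components, n_runs = n_runs,
                    base_seed = seed, normalize = normalize,
                    pca_threshold = pca_threshold, pca_max_k = pca_max_k,
                    sparse_kind = sparse_kind, sparse_family = sparse_family,
                    sparse_level = sparse_level,
                    sparse_quality = sparse_quality,
                    max_iter = max_iter, tol = tol)
  pooled <- pool_basis(runs$decompositions)
  sim <- similarity_matrix(pooled)
  ap <- apc(sim, preference = apc_preference, damping = apc_damping,
            max_iter = apc_max_iter, seed = seed)
  cms <- aggregate_comodules(runs$decompositions, ap, runs$prep$ms)
  cms <- select_elements(cms, alpha = alpha, zscore_scope = zscore_scope,
                         combine = combine)
  structure(list(comodules = cms, apc = ap,
                 decompositions = runs$decompositions,
                 pooled_basis = pooled, prep = runs$prep,
                 settings = list(n_components = runs$n_components,
                                 n_runs = n_runs, alpha = alpha,
                                 normalize = normalize,
                                 pca_threshold = pca_threshold,
                                 sparse_kind = sparse_kind,
                                 sparse_family = sparse_family,
                                 sparse_quality = sparse_quality,
                                 zscore_scope = zscore_scope,
                                 combine = combine, seed = seed),
                 call = match.call()),
            class = "scica")
}

#' @export
print.scica <- function(x, ...) {
  s <- x$settings
  cat("Sparse consensus ICA co-module fit\n")
  cat("  blocks:", paste(x$prep$ms$boundaries$block, collapse = ", "),
      "|", length(x$prep$ms$sample_ids), "samples,",
      n_features(x$prep$ms), "features\n")
  cat("  PCA dimension:", x$prep$pca$k, "of", x$prep$pca$n_samples,
      sprintf("samples (threshold %.2f)\n", s$pca_threshold))
  cat("  runs:", s$n_runs, "x", s$n_components, "components ->",
      ncol(x$pooled_basis), "pooled basis columns\n")
  cat("  consensus:", x$apc$n_clusters, "cluster(s) by affinity propagation\n")
  for (b in names(x$comodules$final))
    cat("  final co-module [", b, "]: ",
        length(x$comodules$final[[b]]), " features\n", sep = "")
  invisible(x)
}

#' @export
summary.scica <- function(object, ...) {
  rec <- reconstruct_blocks(object$decompositions[[1]], object$prep$ms,
                            object$prep$pca, object$prep$sparse$dictionary)
  # correlations are measured against the normalized (pipeline-input) data
  blocks <- lapply(object$prep$ms$blocks, `[[`, "values")
  names(blocks) <- object$prep$ms$boundaries$block
  cors <- lapply(names(blocks), function(b)
    sample_correlations(blocks[[b]], rec[[b]]))
  names(cors) <- names(blocks)
  out <- list(fit = object,
              reconstruction = data.frame(
                block = names(cors),
                mean_r = vapply(cors, `[[`, numeric(1), "mean"),
                sd_r = vapply(cors, `[[`, numeric(1), "sd"),
                row.names = NULL),
              negentropy = object$decompositions[[1]]$negentropy,
              cluster_sizes = object$comodules$cluster_sizes,
              sample_correlations = cors)
  class(out) <- "summary.scica"
  out
}

#' @export
print.summary.scica <- function(x, ...) {
  print(x$fit)
  cat("\nReconstruction (run 1), per-sample Pearson r vs pipeline input:\n")
  print(x$reconstruction, digits = 4)
  cat("\nCluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Extract consensus signatures (or basis) from a fit
#'
#' @param object An `scica` fit.
#' @param what `"signatures"` (clusters x total_features aggregated module
#'   signatures, the default) or `"basis"` (pooled d x (runs*k) basis
#'   columns).
#' @param ... Unused.
#' @return Numeric matrix.
#' @export
coef.scica <- function(object, what = c("signatures", "basis"), ...) {
  what <- match.arg(what)
  if (what == "signatures") object$comodules$signatures
  else object$pooled_basis
}

#' Fitted (reconstructed) expression per block
#'
#' Reconstruction `A %*% S_i` of the first run, mapped back to the original
#' samples-by-features geometry and sliced per block.
#'
#' @param object An `scica` fit.
#' @param run Which run's decomposition to use (default 1).
#' @param ... Unused.
#' @return Named list of features x samples matrices.
#' @export
fitted.scica <- function(object, run = 1, ...) {
  reconstruct_blocks(object$decompositions[[run]], object$prep$ms,
                     object$prep$pca, object$prep$sparse$dictionary)
}

#' Residuals of the reconstruction per block
#'
#' @param object An `scica` fit.
#' @param ... Passed to [fitted.scica].
#' @return Named list of features x samples matrices (pipeline-input data
#'   minus reconstruction).
#' @export
residuals.scica <- function(object, ...) {
  fit <- fitted(object, ...)
  out <- lapply(seq_along(fit), function(j)
    object$prep$ms$blocks[[j]]$values - fit[[j]])
  names(out) <- names(fit)
  out
}

#' Histogram of sample-wise reconstruction correlations
#'
#' One panel per block: the distribution over samples of the Pearson
#' correlation between original and reconstructed profiles.
#'
#' @param x An `scica` fit.
#' @param bins Number of histogram bins (over `[min r, 1]`).
#' @param ... Passed to [graphics::hist].
#' @return The fit, invisibly.
#' @export
plot.scica <- function(x, bins = 30, ...) {
  sm <- summary(x)
  old <- graphics::par(mfrow = c(1, length(sm$sample_correlations)))
  on.exit(graphics::par(old))
  for (b in names(sm$sample_correlations)) {
    r <- sm$sample_correlations[[b]]$r
    r <- r[!is.na(r)]
    graphics::hist(r, breaks = seq(min(r, 1 - 1e-9), 1, length.out = bins + 1),
                   main = b, xlab = "sample-wise Pearson r", ...)
  }
  invisible(x)
}
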