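# Multi-run consensus: pool basis columns over seeded ICA runs, cluster
# them by affinity propagation, aggregate sign-aligned module signatures
# per cluster, and select significant features per RNA block by z-score.

# Shared preprocessing for all runs: normalize per block, concatenate,
# transpose to samples x features, PCA-reduce the sample dimension,
# sparse-approximate the reduced matrix along the feature axis.
prepare_pipeline <- function(ms, normalize = "log_cpm", pca_threshold = 0.90,
                             pca_max_k = NULL, sparse_kind = "wavelet_packet",
                             sparse_family = "haar", sparse_level = 1,
                             sparse_quality = 1) {
  stopifnot(inherits(ms, "multi_omics"))
  blocks <- lapply(ms$blocks, normalize_block, method = normalize)
  ms_n <- align_samples(blocks)
  X <- concatenate_blocks(ms_n)                  # features x samples
  pca <- pca_reduce(t(X), threshold = pca_threshold, max_k = pca_max_k)
  sa <- sparse_approximate(pca$reduced, family = sparse_family,
                           level = sparse_level, quality = sparse_quality,
                           kind = sparse_kind)
  list(ms = ms_n, pca = pca, sparse = sa)
}

#' Run the constrained ICA repeatedly with consecutive seeds
#'
#' Preprocessing (normalization, PCA reduction, sparse approximation) is
#' computed once and shared; only the ICA initialization differs between
#' runs (seeds `base_seed ... base_seed + n_runs - 1`).
#'
#' @param ms Aligned [multi_omics] set.
#' @param n_components Components per run; default the PCA-selected
#'   dimension.
#' @param n_runs Number of runs (the consensus default is 20).
#' @param base_seed First seed.
#' @param normalize,pca_threshold,pca_max_k,sparse_kind,sparse_family,sparse_level,sparse_quality
#'   Pipeline settings, see [scica].
#' @param max_iter,tol ICA solver settings, see [ica_config].
#' @return List with `decompositions` (length `n_runs`), `prep` (shared
#'   preprocessing: `ms`, `pca`, `sparse`), `n_components`, `seeds`.
#' @export
multi_run <- function(ms, n_components = NULL, n_runs = 20, base_seed = 1,
                      normalize = "log_cpm", pca_threshold = 0.90,
                      pca_max_k = NULL, sparse_kind = "wavelet_packet",
                      sparse_family = "haar", sparse_level = 1,
                      sparse_quality = 1, max_iter = 500, tol = 1e-6) {
  stopifnot(n_runs >= 1)
  prep <- prepare_pipeline(ms, normalize, pca_threshold, pca_max_k,
                           sparse_kind, sparse_family, sparse_level,
                           sparse_quality)
  if (is.null(n_components)) n_components <- prep$pca$k
  seeds <- base_seed + seq_len(n_runs) - 1L
  decomps <- lapply(seeds, function(sd) {
    cfg <- ica_config(n_components, max_iter = max_iter, tol = tol, seed = sd)
    cica_fit(prep$sparse$coeffs, cfg, dictionary = prep$sparse$dictionary)
  })
  list(decompositions = decomps, prep = prep,
       n_components = as.integer(n_components), seeds = seeds)
}

#' Pool basis columns across decompositions
#'
#' @param decomps List of [cica_fit] results sharing a basis row dimension.
#' @return Matrix d x (n_runs * n_components) ordered by (run, component),
#'   with a `provenance` attribute (data frame of run and component
#'   indices).
#' @export
pool_basis <- function(decomps) {
  dims <- vapply(decomps, function(d) nrow(d$A), integer(1))
  if (length(unique(dims)) != 1)
    stop("decompositions have mismatched basis dimensions: ",
         paste(unique(dims), collapse = ", "))
  cols <- do.call(cbind, lapply(decomps, `[[`, "A"))
  ks <- vapply(decomps, function(d) ncol(d$A), integer(1))
  attr(cols, "provenance") <- data.frame(
    run = rep(seq_along(decomps), ks),
    component = unlist(lapply(ks, seq_len)))
  cols
}

#' Aggregate per-cluster co-module signatures
#'
#' For each affinity-propagation cluster of pooled basis columns, collects
#' the module-matrix row paired with each member column (same run, same
#' component), flips rows whose correlation with the exemplar's paired row
#' is negative (ICA sign indeterminacy would otherwise cancel signal), and
#' averages them into one signature over the concatenated feature axis.
#'
#' @param decomps List of [cica_fit] results (with `S` attached).
#' @param apc_result An [apc] result on the pooled columns.
#' @param ms The aligned [multi_omics] set (for feature bookkeeping).
#' @return Object of class `comodule_set` (signatures stage): `signatures`
#'   (clusters x total_features), `cluster_labels`, `cluster_sizes`,
#'   `exemplars`, `n_runs`, `n_components`, `boundaries`, `feature_ids`.
#' @export
aggregate_comodules <- function(decomps, apc_result, ms) {
  stopifnot(inherits(apc_result, "apc_result"), inherits(ms, "multi_omics"))
  prov <- data.frame(run = rep(seq_along(decomps),
                               vapply(decomps, function(d) ncol(d$A),
                                      integer(1))),
                     component = unlist(lapply(decomps, function(d)
                       seq_len(ncol(d$A)))))
  n_pool <- nrow(prov)
  stopifnot(length(apc_result$labels) == n_pool)
  srow <- function(j)
    decomps[[prov$run[j]]]$S[prov$component[j], ]
  exemplars <- apc_result$exemplars
  sigs <- t(vapply(exemplars, function(ex) {
    members <- which(apc_result$labels == ex)
    stopifnot(length(members) > 0)
    ref <- srow(ex)
    rows <- vapply(members, function(j) {
      r <- srow(j)
      cc <- sum(r * ref)
      if (cc < 0) -r else r
    }, numeric(length(ref)))
    rowMeans(matrix(rows, ncol = length(members)))
  }, numeric(length(srow(1)))))
  rownames(sigs) <- paste0("cluster", seq_along(exemplars))
  structure(list(signatures = sigs, cluster_labels = apc_result$labels,
                 cluster_sizes = as.vector(table(factor(apc_result$labels,
                                                        levels = exemplars))),
                 exemplars = exemplars,
                 n_runs = length(decomps),
                 n_components = ncol(decomps[[1]]$A),
                 boundaries = ms$boundaries,
                 feature_ids = feature_ids(ms)),
            class = "comodule_set")
}

#' Select significant co-module elements per block
#'
#' Standardizes each cluster signature to zero mean and unit variance
#' (jointly across all features by default, per block optionally; both give
#' the same behaviour on balanced signals) and selects features whose
#' two-sided standard-normal tail probability falls below `alpha`, i.e.
#' `|z| >= qnorm(1 - alpha/2)` (1.96 at alpha = 0.05). Per-cluster sets are
#' sliced by block; the final per-block sets combine clusters by
#' intersection (literal reading) or union.
#'
#' @param cms A `comodule_set` from [aggregate_comodules].
#' @param alpha Two-sided significance level in (0, 1).
#' @param zscore_scope `"joint"` (default) or `"per_block"`.
#' @param combine `"intersection"` (default) or `"union"` across clusters.
#' @return The `comodule_set` with `zscores` (clusters x features),
#'   `selected` (list: cluster -> block -> feature IDs), `final` (list:
#'   block -> feature IDs), `alpha`, `zscore_scope`, `combine`.
#' @export
select_elements <- function(cms, alpha = 0.05,
                            zscore_scope = c("joint", "per_block"),
                            combine = c("intersection", "union")) {
  stopifnot(inherits(cms, "comodule_set"), alpha > 0, alpha < 1)
  zscore_scope <- match.arg(zscore_scope)
  combine <- match.arg(combine)
  sigs <- cms$signatures
  bnd <- cms$boundaries
  zs <- matrix(0, nrow(sigs), ncol(sigs), dimnames = dimnames(sigs))
  standardize <- function(v) {
    sdv <- stats::sd(v)
    if (sdv == 0) {
      warning("constant signature: empty selection")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / sdv
  }
  for (i in seq_len(nrow(sigs))) {
    if (zscore_scope == "joint") {
      zs[i, ] <- standardize(sigs[i, ])
    } else {
      for (j in seq_len(nrow(bnd)))
        zs[i, bnd$start[j]:bnd$end[j]] <-
          standardize(sigs[i, bnd$start[j]:bnd$end[j]])
    }
  }
  zcut <- stats::qnorm(1 - alpha / 2)
  fids <- cms$feature_ids
  selected <- lapply(seq_len(nrow(sigs)), function(i) {
    hits <- abs(zs[i, ]) >= zcut
    out <- lapply(seq_len(nrow(bnd)), function(j)
      fids[bnd$start[j]:bnd$end[j]][hits[bnd$start[j]:bnd$end[j]]])
    names(out) <- bnd$block
    out
  })
  names(selected) <- rownames(sigs)
  final <- lapply(seq_len(nrow(bnd)), function(j) {
    sets <- lapply(selected, `[[`, j)
    if (combine == "intersection") Reduce(intersect, sets)
    else sort(unique(unlist(sets)))
  })
  names(final) <- bnd$block
  cms$zscores <- zs
  cms$selected <- selected
  cms$final <- final
  cms$alpha <- alpha
  cms$zscore_scope <- zscore_scope
  cms$combine <- combine
  cms
}

#' @export
print.comodule_set <- function(x, ...) {
  cat("<comodule_set> ", nrow(x$signatures), " cluster(s) from ",
      x$n_runs, " x ", x$n_components, " pooled basis columns\n", sep = "")
  if (!is.null(x$final)) {
    cat("final co-module sizes (", x$combine, " across clusters, alpha = ",
        x$alpha, "):\n", sep = "")
    for (b in names(x$final))
      cat("  ", b, ": ", length(x$final[[b]]), "\n", sep = "")
  }
  invisible(x)
}

#' Write co-module feature sets to disk
#'
#' Writes the per-cluster and final per-block sets in GMT-like format plus
#' a TSV of (feature, block, cluster, z-score, selected).
#'
#' @param cms A `comodule_set` after [select_elements].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of paths written, invisibly.
#' @export
write_comodules <- function(cms, dir, prefix = "comodule") {
  stopifnot(inherits(cms, "comodule_set"), !is.null(cms$final))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sets <- list()
  for (cl in names(cms$selected))
    for (b in names(cms$selected[[cl]]))
      sets[[paste(cl, b, sep = "_")]] <- cms$selected[[cl]][[b]]
  for (b in names(cms$final))
    sets[[paste("final", b, sep = "_")]] <- cms$final[[b]]
  gmt <- file.path(dir, paste0(prefix, "_sets.gmt"))
  write_gmt(sets, gmt)
  bnd <- cms$boundaries
  block_of <- rep(bnd$block, bnd$end - bnd$start + 1)
  rows <- do.call(rbind, lapply(names(cms$selected), function(cl) {
    z <- cms$zscores[cl, ]
    data.frame(feature = cms$feature_ids, block = block_of, cluster = cl,
               zscore = as.vector(z),
               selected = abs(z) >= stats::qnorm(1 - cms$alpha / 2))
  }))
  tsv <- file.path(dir, paste0(prefix, "_zscores.tsv"))
  utils::write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gmt, tsv))
}
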