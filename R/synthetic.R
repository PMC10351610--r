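#' Simulate multi-block expression data with planted co-modules
#'
#' Generates K feature blocks on a shared sample set from the generative
#' model the decomposition assumes: non-Gaussian (Laplace) module
#' activations times sparse block loadings plus Gaussian noise, i.e.
#' `X = A_true %*% S_true + E`, shifted to non-negative values per block
#' (and optionally rounded to counts). Each of the `k` modules owns a
#' disjoint planted feature set in every block; loadings outside planted
#' sets are exactly zero.
#'
#' Defaults define the package's reference fixture: 60 samples, blocks of
#' 400/80/200 features (mRNA/miRNA/lncRNA-like), 4 modules with 25/8/15
#' planted features per block, loading magnitudes uniform in
#' \[0.8, 1.2\], and noise scaled per block to a signal-to-noise ratio of
#' about 5 — small enough for seconds-scale runs while keeping the
#' modules identifiable.
#'
#' @param n_samples Number of shared samples.
#' @param block_sizes Integer vector of per-block feature counts.
#' @param k Number of planted modules.
#' @param module_size Per-block planted-set size (recycled to K blocks);
#'   `module_size[b] * k` must not exceed `block_sizes[b]`.
#' @param loading_range Magnitude range of the nonzero loadings (signs
#'   random).
#' @param snr Target per-block signal-to-noise ratio (variance ratio);
#'   ignored when `noise_sd` is given.
#' @param noise_sd Optional explicit noise SD (scalar or per block);
#'   `0` yields a noiseless rank-k matrix.
#' @param count_mode Round the shifted values to integer counts.
#' @param block_names Block labels (defaults to mRNA/miRNA/lncRNA for 3
#'   blocks).
#' @param seed Integer seed; the output is a deterministic function of it.
#' @return List with `ms` (a [multi_omics] set) and `truth`
#'   (`synthetic_truth`: `A_true` (samples x k), `S_true`
#'   (k x total_features), `planted` (module -> block -> feature IDs),
#'   `noise_sd` (per block), `snr` (realized, per block), `seed`).
#' @export
simulate_comodules <- function(n_samples = 60, block_sizes = c(400, 80, 200),
                               k = 4, module_size = c(25, 8, 15),
                               loading_range = c(0.8, 1.2), snr = 5,
                               noise_sd = NULL, count_mode = FALSE,
                               block_names = NULL, seed = 1) {
  K <- length(block_sizes)
  module_size <- rep_len(module_size, K)
  if (any(module_size * k > block_sizes))
    stop("infeasible module sizes: module_size * k must be <= block size ",
         "(block(s) ", paste(which(module_size * k > block_sizes),
                             collapse = ", "), ")")
  if (is.null(block_names))
    block_names <- if (K == 3) c("mRNA", "miRNA", "lncRNA")
                   else paste0("block", seq_len(K))
  set.seed(seed)
  sample_ids <- sprintf("s%0*d", nchar(as.character(n_samples)),
                        seq_len(n_samples))
  # Laplace(0, 1) activations: difference of unit-rate exponentials
  A_true <- matrix(stats::rexp(n_samples * k) - stats::rexp(n_samples * k),
                   n_samples, k)
  total <- sum(block_sizes)
  S_true <- matrix(0, k, total)
  offsets <- c(0L, cumsum(block_sizes))
  planted <- vector("list", k)
  fid <- unlist(lapply(seq_len(K), function(b)
    sprintf("%s_f%04d", block_names[b], seq_len(block_sizes[b]))))
  for (mod in seq_len(k)) planted[[mod]] <- vector("list", K)
  for (b in seq_len(K)) {
    pool <- sample.int(block_sizes[b], module_size[b] * k)
    for (mod in seq_len(k)) {
      idx <- pool[((mod - 1) * module_size[b] + 1):(mod * module_size[b])]
      gidx <- offsets[b] + idx
      mag <- stats::runif(length(idx), loading_range[1], loading_range[2])
      S_true[mod, gidx] <- mag * sample(c(-1, 1), length(idx), replace = TRUE)
      planted[[mod]][[b]] <- sort(fid[gidx])
      names(planted[[mod]])[b] <- block_names[b]
    }
  }
  names(planted) <- paste0("module", seq_len(k))
  signal <- A_true %*% S_true                     # samples x total_features
  sd_sig <- vapply(seq_len(K), function(b)
    stats::sd(as.vector(signal[, (offsets[b] + 1):offsets[b + 1]])),
    numeric(1))
  nsd <- if (is.null(noise_sd)) sd_sig / sqrt(snr) else rep_len(noise_sd, K)
  blocks <- vector("list", K)
  snr_real <- numeric(K)
  for (b in seq_len(K)) {
    cols <- (offsets[b] + 1):offsets[b + 1]
    noise <- matrix(stats::rnorm(n_samples * block_sizes[b], sd = nsd[b]),
                    n_samples, block_sizes[b])
    xb <- signal[, cols] + noise
    xb <- xb - min(xb)                            # shift to non-negative
    if (count_mode) xb <- round(xb)
    vb <- t(xb)                                   # features x samples
    dimnames(vb) <- list(fid[cols], sample_ids)
    blocks[[b]] <- omics_block(vb, name = block_names[b])
    snr_real[b] <- if (nsd[b] > 0)
      stats::var(as.vector(signal[, cols])) / stats::var(as.vector(noise))
    else Inf
  }
  truth <- structure(list(A_true = A_true, S_true = S_true,
                          planted = planted, noise_sd = nsd,
                          snr = snr_real, block_names = block_names,
                          feature_ids = fid, seed = as.integer(seed)),
                     class = "synthetic_truth")
  list(ms = align_samples(blocks), truth = truth)
}

#' Planted feature sets pooled across modules
#'
#' Convenience accessor: for each block, the union over modules of the
#' planted feature IDs (the ground truth that union-combined selections
#' are scored against).
#'
#' @param truth A `synthetic_truth`.
#' @return Named list, block -> feature IDs.
#' @export
planted_union <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  blocks <- names(truth$planted[[1]])
  out <- lapply(blocks, function(b)
    sort(unique(unlist(lapply(truth$planted, `[[`, b)))))
  names(out) <- blocks
  out
}
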