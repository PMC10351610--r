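make_sim <- function(seed = 1) simulate_comodules(seed = seed)

test_that("multi_run shares preprocessing and seeds runs consecutively", {
  sim <- make_sim()
  one <- multi_run(sim$ms, n_components = 4, n_runs = 1, base_seed = 5,
                   normalize = "none")
  single <- cica_fit(one$prep$sparse$coeffs,
                     ica_config(4, seed = 5),
                     dictionary = one$prep$sparse$dictionary)
  expect_equal(one$decompositions[[1]]$A, single$A)
  expect_equal(one$decompositions[[1]]$C_S, single$C_S)

  # identical base seeds give bit-identical decompositions
  r1 <- multi_run(sim$ms, n_components = 4, n_runs = 3, base_seed = 2,
                  normalize = "none")
  r2 <- multi_run(sim$ms, n_components = 4, n_runs = 3, base_seed = 2,
                  normalize = "none")
  for (j in 1:3)
    expect_identical(r1$decompositions[[j]]$A, r2$decompositions[[j]]$A)
  expect_equal(r1$seeds, c(2L, 3L, 4L))
})

test_that("pool_basis counts and orders columns by (run, component)", {
  sim <- make_sim()
  runs <- multi_run(sim$ms, n_components = 4, n_runs = 3, base_seed = 1,
                    normalize = "none")
  pooled <- pool_basis(runs$decompositions)
  expect_equal(ncol(pooled), 12)
  prov <- attr(pooled, "provenance")
  expect_equal(prov$run, rep(1:3, each = 4))
  expect_equal(prov$component, rep(1:4, 3))
  expect_equal(pooled[, 6], runs$decompositions[[2]]$A[, 2],
               ignore_attr = TRUE)
  # 1 run x 5 components -> 5 columns
  runs5 <- multi_run(sim$ms, n_components = 5, n_runs = 1,
                     normalize = "none")
  expect_equal(ncol(pool_basis(runs5$decompositions)), 5)
  # mismatched dimensions -> error
  bad <- c(runs$decompositions,
           list(list(A = matrix(0, 3, 4), S = matrix(0, 4, 10))))
  expect_error(pool_basis(bad), "mismatched")
})

test_that("aggregation sign-aligns rows before averaging", {
  sim <- make_sim()
  runs <- multi_run(sim$ms, n_components = 2, n_runs = 2, base_seed = 1,
                    normalize = "none")
  d1 <- runs$decompositions[[1]]
  # construct a mirrored twin: flipped basis and sources
  d2 <- d1
  d2$A <- -d1$A
  d2$S <- -d1$S
  decomps <- list(d1, d2)
  pooled <- pool_basis(decomps)
  ap <- apc(similarity_matrix(pooled))   # sign-free metric: pairs collapse
  cms <- aggregate_comodules(decomps, ap, runs$prep$ms)
  # each cluster signature equals the (sign-aligned) member row itself
  for (i in seq_along(cms$exemplars)) {
    ex <- cms$exemplars[i]
    comp <- ((ex - 1) %% 2) + 1
    ref <- decomps[[((ex - 1) %/% 2) + 1]]$S[comp, ]
    expect_equal(abs(cor(cms$signatures[i, ], ref)), 1, tolerance = 1e-12)
    expect_equal(unname(cms$signatures[i, ]), unname(ref),
                 tolerance = 1e-10)
  }
})

test_that("cluster signatures recover the planted loading directions", {
  sim <- make_sim(seed = 2)
  fit <- suppressWarnings(
    scica(sim$ms, n_components = 4, n_runs = 10, normalize = "none",
          combine = "union", seed = 7))
  sigs <- coef(fit, "signatures")
  best <- apply(abs(cor(t(sigs), t(sim$truth$S_true))), 2, max)
  expect_true(all(best > 0.9))
})

test_that("z-score selection is calibrated on null signatures", {
  # i.i.d. standard-normal signature, 1e5 features: selected fraction
  # 0.05 +/- 0.005 at alpha = 0.05
  set.seed(100)
  nf <- 1e5
  cms <- structure(list(
    signatures = matrix(rnorm(nf), 1,
                        dimnames = list("cluster1", NULL)),
    boundaries = data.frame(block = "b1", start = 1L, end = as.integer(nf)),
    feature_ids = sprintf("f%06d", seq_len(nf)),
    n_runs = 1, n_components = 1, exemplars = 1L, cluster_labels = 1L,
    cluster_sizes = 1L), class = "comodule_set")
  sel <- select_elements(cms, alpha = 0.05)
  frac <- length(sel$selected$cluster1$b1) / nf
  expect_gt(frac, 0.045)
  expect_lt(frac, 0.055)
  # alpha monotonicity
  sel01 <- select_elements(cms, alpha = 0.01)
  expect_true(all(sel01$selected$cluster1$b1 %in% sel$selected$cluster1$b1))
})

test_that("an extreme spike is always selected; flips leave selection fixed", {
  set.seed(8)
  nf <- 500
  sig <- rnorm(nf); sig[42] <- 10 * sd(sig)
  mk <- function(s) structure(list(
    signatures = matrix(s, 1, dimnames = list("cluster1", NULL)),
    boundaries = data.frame(block = "b1", start = 1L, end = as.integer(nf)),
    feature_ids = sprintf("f%03d", seq_len(nf)),
    n_runs = 1, n_components = 1, exemplars = 1L, cluster_labels = 1L,
    cluster_sizes = 1L), class = "comodule_set")
  sel <- select_elements(mk(sig), alpha = 0.05)
  expect_true("f042" %in% sel$selected$cluster1$b1)
  # global sign flip: identical selection (two-sided threshold)
  self <- select_elements(mk(-sig), alpha = 0.05)
  expect_identical(sel$selected, self$selected)
})

test_that("final sets follow the combine rule across clusters", {
  nf <- 40
  sig1 <- rep(0, nf); sig1[1:4] <- 30
  sig2 <- rep(0, nf); sig2[5:8] <- 30
  cms <- structure(list(
    signatures = rbind(cluster1 = sig1, cluster2 = sig2),
    boundaries = data.frame(block = "b1", start = 1L, end = as.integer(nf)),
    feature_ids = sprintf("f%02d", seq_len(nf)),
    n_runs = 2, n_components = 1, exemplars = c(1L, 2L),
    cluster_labels = c(1L, 2L), cluster_sizes = c(1L, 1L)),
    class = "comodule_set")
  inter <- select_elements(cms, alpha = 0.05, combine = "intersection")
  expect_length(inter$final$b1, 0)       # disjoint clusters -> empty final
  uni <- select_elements(cms, alpha = 0.05, combine = "union")
  expect_setequal(uni$final$b1, sprintf("f%02d", 1:8))
})

test_that("constant signatures warn and select nothing", {
  nf <- 10
  cms <- structure(list(
    signatures = matrix(1, 1, nf, dimnames = list("cluster1", NULL)),
    boundaries = data.frame(block = "b1", start = 1L, end = as.integer(nf)),
    feature_ids = sprintf("f%02d", seq_len(nf)),
    n_runs = 1, n_components = 1, exemplars = 1L, cluster_labels = 1L,
    cluster_sizes = 1L), class = "comodule_set")
  expect_warning(sel <- select_elements(cms, alpha = 0.05), "constant")
  expect_length(sel$selected$cluster1$b1, 0)
})

test_that("co-module outputs are written as GMT and TSV", {
  sim <- make_sim()
  fit <- suppressWarnings(
    scica(sim$ms, n_components = 2, n_runs = 2, normalize = "none",
          sparse_kind = "identity", seed = 1))
  dir <- tempfile()
  paths <- write_comodules(fit$comodules, dir)
  expect_true(all(file.exists(paths)))
  gmt <- readLines(paths[1])
  expect_gt(length(gmt), 0)
  tsv <- read.delim(paths[2])
  expect_equal(sort(unique(tsv$block)), sort(unique(fit$prep$ms$boundaries$block)))
  expect_equal(nrow(tsv), n_features(sim$ms) * fit$apc$n_clusters)
})
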