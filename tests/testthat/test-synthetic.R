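test_that("coordinate generator is deterministic, distinct, clustered", {
  c1 <- gen_coords(4, 1, "uniform_box")
  expect_identical(c1, gen_coords(4, 1, "uniform_box"))
  expect_identical(dim(c1), c(4L, 3L))
  expect_gt(min(dist(c1)), 0)
  expect_error(gen_coords(3, 1), "at least 4")
  # two_blobs: nearest-centroid audit recovers two balanced clusters
  cb <- gen_coords(50, 7, "two_blobs")
  centers <- rbind(c(-40, 0, 0), c(40, 0, 0))
  assign <- apply(cb, 1, function(p)
    which.min(colSums((t(centers) - p)^2)))
  expect_identical(as.integer(table(assign)), c(25L, 25L))
  expect_identical(assign, rep(1:2, each = 25))
})

test_that("structural generator plants recoverable labels", {
  coords <- gen_coords(30, 3, "uniform_box")
  # no perturbation: structural edge set equals the game edge set
  pl0 <- gen_structural(coords, p_extra = 0, p_drop = 0, seed = 2)
  expect_identical(unname(pl0$structural != 0),
                   unname(pl0$nng_truth$adjacency == 1L))
  wts <- pl0$structural[pl0$structural != 0]
  expect_true(all(wts > 0 & wts <= 1))
  # round trip: reclassification against a freshly rebuilt game matches the
  # planted labels exactly (deterministic construction), across seeds
  for (sd in 1:4) {
    pl <- gen_structural(coords, p_extra = 0.3, p_drop = 0, seed = sd)
    cls <- classify_edges(pl$structural, build_nng(pl$D))
    expect_identical(cls$optimal_mask, pl$optimal_mask)
    expect_identical(cls$nonoptimal_mask, pl$nonoptimal_mask)
    expect_identical(cls$F_count, 0L)
  }
  # dropped game edges come back as false positives, counted exactly
  pl_d <- gen_structural(coords, p_extra = 0.2, p_drop = 0.2, seed = 9)
  cls_d <- classify_edges(pl_d$structural, build_nng(pl_d$D))
  expect_identical(cls_d$F_count, pl_d$dropped_count)
})

test_that("forward model honours polynomial and rotation contracts", {
  S <- rand_sym(12, 4)
  expect_equal(gen_functional(S, c(0, 1), "identity", 0, 1), S)
  expect_equal(gen_functional(S, c(0, 0, 1), "identity", 0, 1), S %*% S)
  # similarity transform preserves the spectrum exactly
  a <- default_poly_coef(3)
  Fr <- gen_functional(S, a, "random", 0, 5)
  P <- a[1] * diag(12) + a[2] * S + a[3] * S %*% S + a[4] * S %*% S %*% S
  expect_equal(sort(eigen(Fr, symmetric = TRUE, only.values = TRUE)$values),
               sort(eigen(P, symmetric = TRUE, only.values = TRUE)$values),
               tolerance = 1e-10)
  expect_error(gen_functional(matrix(rnorm(9), 3, 3), c(0, 1)), "symmetric")
  expect_identical(gen_functional(S, a, "random", 0.2, 8),
                   gen_functional(S, a, "random", 0.2, 8))
})

test_that("rest/task pair is deterministic with the planted dissociation", {
  coords <- gen_coords(30, 11, "uniform_box")
  pl <- gen_structural(coords, 0.3, 0, seed = 6)
  fc <- gen_rest_task_pair(pl, noise_sd = 0, seed = 3)
  expect_identical(fc, gen_rest_task_pair(pl, noise_sd = 0, seed = 3))
  cls <- classify_edges(pl$structural, pl$nng_truth)
  S_opt <- mask_structural(pl$structural, cls, "optimal")
  S_non <- mask_structural(pl$structural, cls, "nonoptimal")
  sc <- function(Sm, Ff)
    score_correlation(predict_fc(fit_spectral_map(Sm, Ff, 5), Sm), Ff)
  # noiseless rest comes from the optimal core: near-perfect recovery
  expect_gte(sc(S_opt, fc$rest), 0.999)
  # the task state is nonoptimal-dominated by construction
  expect_gt(sc(S_non, fc$task), sc(S_opt, fc$task))
  # degenerate class: no nonoptimal edges
  pl0 <- gen_structural(coords, 0, 0, seed = 6)
  expect_error(gen_rest_task_pair(pl0), "nonoptimal")
})

test_that("expression generator plants signal columns", {
  ro <- seq(-1, 1, length.out = 40)
  X <- gen_expression(ro, n_genes = 100, n_signal = 10, noise_sd = 0, seed = 2)
  sig <- attr(X, "signal_genes")
  expect_length(sig, 10)
  for (g in sig)
    expect_equal(cor(X[, g], ro, method = "spearman"), 1)
  # byte-identical rerun
  expect_identical(X, gen_expression(ro, 100, 10, 0, 2))
  # n_signal = 0: pure noise, no planted attribute entries
  X0 <- gen_expression(ro, 50, 0, 0.5, 3)
  expect_length(attr(X0, "signal_genes"), 0)
})

test_that("partition generator uses every label", {
  expect_setequal(gen_partition(7, 7, 1), paste0("N", 1:7))
  p <- gen_partition(50, 7, 2)
  expect_length(p, 50)
  expect_identical(sort(unique(p)), sort(paste0("N", 1:7)))
  expect_identical(p, gen_partition(50, 7, 2))
  expect_error(gen_partition(3, 5, 1))
})
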