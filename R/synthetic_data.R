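#' Synthetic connectomes with planted ground truth
#'
#' Generators for every input the pipeline consumes: 3-D node layouts,
#' structural networks seeded from the navigation-game model (so edge labels
#' are known by construction), functional matrices from the rotated
#' matrix-polynomial forward model, rest/task pairs, gene-expression matrices
#' with a planted component, and node partitions. All generators are
#' deterministic under a fixed seed (they call \code{set.seed}).
#'
#' @name synthetic-data
NULL

#' Default forward-model polynomial coefficients
#'
#' Coefficients a_0..a_k for the forward model \eqn{R(\sum a_r S^r)R^T}. The
#' defaults decay quickly with the power so the polynomial is strictly
#' increasing over the spectral range of typical weighted structural
#' matrices; that keeps the eigenvalue ordering identifiable, so the
#' closed-form spectral fit can recover noiseless forward data exactly.
#'
#' @param k polynomial order (default 5)
#' @return numeric vector of length k + 1
#' @export
default_poly_coef <- function(k = 5) {
  stopifnot(k >= 1)
  c(0, 1, 0.2, 0.05, 0.01, 0.002, 0.0005, 0.0001, 2e-05)[seq_len(k + 1)]
}

#' Generate 3-D node coordinates
#'
#' @param n number of nodes (>= 4)
#' @param seed RNG seed
#' @param layout "uniform_box" (uniform in the unit cube, scaled x100 to
#'   mimic mm-scale ROI centroids) or "two_blobs" (two Gaussian clusters,
#'   n/2 nodes each, emulating two hemispheres)
#' @return n x 3 coordinate matrix
#' @export
gen_coords <- function(n, seed, layout = c("uniform_box", "two_blobs")) {
  layout <- match.arg(layout)
  if (n < 4) stop("need at least 4 nodes")
  set.seed(seed)
  coords <- switch(layout,
    uniform_box = matrix(stats::runif(3 * n, 0, 100), n, 3),
    two_blobs = {
      n1 <- n %/% 2
      centers <- rbind(c(-40, 0, 0), c(40, 0, 0))
      grp <- rep(1:2, c(n1, n - n1))
      centers[grp, ] + matrix(stats::rnorm(3 * n, sd = 12), n, 3)
    })
  # distinct-point invariant: resample any point duplicating another
  for (tries in 1:100) {
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    bad <- which(apply(d, 1, min) < 1e-9)
    if (length(bad) == 0) break
    coords[bad, ] <- coords[bad, , drop = FALSE] +
      matrix(stats::rnorm(3 * length(bad), sd = 1), length(bad), 3)
  }
  coords
}

#' Generate a structural network with planted optimal/nonoptimal labels
#'
#' Builds the navigation-game network over the coordinates, then perturbs it:
#' each game edge is dropped independently with probability \code{p_drop}
#' (dropped edges reappear downstream as false positives), and
#' \code{ceiling(p_extra * m)} non-game edges are added, sampled with
#' probability proportional to distance (long-range bias, mimicking direct
#' long-range tracts). Weights are GFA-like: \code{exp(-dist/d0)} plus
#' positive noise, clipped to (0, 1], with d0 the median pairwise distance.
#'
#' @param coords n x 3 coordinate matrix
#' @param p_extra fraction of game edges to add as planted nonoptimal edges
#' @param p_drop per-edge drop probability for game edges
#' @param seed RNG seed
#' @return object of class \code{planted_structural}: \code{structural}
#'   (weighted symmetric matrix), \code{nng_truth} (the seeding \code{nng}),
#'   \code{optimal_mask} / \code{nonoptimal_mask} (planted labels),
#'   \code{dropped_count}, \code{coords}, \code{D}
#' @export
gen_structural <- function(coords, p_extra = 0.3, p_drop = 0.1, seed = 1) {
  stopifnot(p_extra >= 0, p_extra < 1, p_drop >= 0, p_drop < 1)
  D <- dist_from_coords(coords)
  nng <- build_nng(D)
  n <- nrow(D)
  set.seed(seed)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  in_nng <- nng$adjacency[upper.tri(D)] > 0
  m <- sum(in_nng)

  keep <- rep(TRUE, m)
  if (p_drop > 0) keep <- stats::runif(m) >= p_drop
  n_extra <- ceiling(p_extra * m)
  cand <- which(!in_nng)
  extra <- integer(0)
  if (n_extra > 0 && length(cand) > 0) {
    n_extra <- min(n_extra, length(cand))
    w <- D[upper.tri(D)][cand]          # long-range bias: prob ~ dist^+1
    extra <- cand[sample.int(length(cand), n_extra, prob = w)]
  }

  present <- logical(length(in_nng))
  present[which(in_nng)[keep]] <- TRUE
  present[extra] <- TRUE

  d0 <- stats::median(D[upper.tri(D)])
  wts <- numeric(length(present))
  idx <- which(present)
  wts[idx] <- pmin(pmax(exp(-D[upper.tri(D)][idx] / d0) +
                          stats::runif(length(idx), 0, 0.1), 0.05), 1)
  S <- matrix(0, n, n)
  S[upper.tri(S)] <- wts
  S <- S + t(S)

  opt_mask <- matrix(FALSE, n, n)
  opt_mask[upper.tri(opt_mask)] <- present & in_nng
  non_mask <- matrix(FALSE, n, n)
  non_mask[upper.tri(non_mask)] <- present & !in_nng
  structure(list(structural = S,
                 nng_truth = nng,
                 optimal_mask = opt_mask | t(opt_mask),
                 nonoptimal_mask = non_mask | t(non_mask),
                 dropped_count = sum(!keep),
                 coords = coords, D = D),
            class = "planted_structural")
}

# Random special-orthogonal matrix: orthonormalize a Gaussian matrix, fix
# sign convention from the QR, then flip one column if det = -1.
.random_rotation <- function(n) {
  qrd <- qr(matrix(stats::rnorm(n * n), n, n))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))), n)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a functional matrix from the forward model
#'
#' Computes \eqn{R(\sum_{r=0}^{k} a_r S^r)R^T} plus symmetric Gaussian noise,
#' where R is the identity or a uniformly random rotation (special
#' orthogonal, det = +1).
#'
#' @param S symmetric structural matrix
#' @param a coefficients a_0..a_k (k = length(a) - 1 >= 1)
#' @param rotation_mode "identity" or "random"
#' @param noise_sd standard deviation of the additive symmetric noise
#' @param seed RNG seed
#' @return symmetric matrix
#' @export
gen_functional <- function(S, a = default_poly_coef(5),
                           rotation_mode = c("identity", "random"),
                           noise_sd = 0, seed = 1) {
  rotation_mode <- match.arg(rotation_mode)
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  stopifnot(length(a) >= 2, noise_sd >= 0)
  set.seed(seed)
  n <- nrow(S)
  P <- matrix(0, n, n)
  Sr <- diag(n)
  for (r in seq_along(a)) {          # r-1 is the power
    P <- P + a[r] * Sr
    Sr <- Sr %*% S
  }
  R <- if (rotation_mode == "random") .random_rotation(n) else diag(n)
  F_out <- R %*% P %*% t(R)
  if (noise_sd > 0) {
    E <- matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
    F_out <- F_out + (E + t(E)) / sqrt(2)
  }
  (F_out + t(F_out)) / 2
}

#' Generate a rest/task functional pair from a planted structural network
#'
#' The rest matrix is the forward model applied to the optimal-edges-only
#' submatrix (rest connectivity rides on the optimal core). The task matrix
#' applies the forward model to a reweighted matrix in which nonoptimal
#' edges are up-weighted (x2) and optimal edges damped (default x0.1),
#' emulating the recruitment of direct long-range connections under
#' cognitive load. The damping is chosen so the nonoptimal block dominates
#' the task matrix in Frobenius norm: optimal edges are several times more
#' numerous and carry larger distance-decayed weights, so a mild damping
#' would leave the task matrix optimal-dominated and the generator could
#' not guarantee that nonoptimal connections predict the task state best.
#'
#' @param planted a \code{planted_structural} object
#' @param a forward-model coefficients
#' @param noise_sd noise level for both matrices (independent draws)
#' @param seed RNG seed
#' @param task_weights multipliers (nonoptimal, optimal) building the
#'   task-state structural matrix
#' @return list with elements \code{rest} and \code{task}
#' @export
gen_rest_task_pair <- function(planted, a = default_poly_coef(5),
                               noise_sd = 0, seed = 1,
                               task_weights = c(2, 0.1)) {
  stopifnot(inherits(planted, "planted_structural"))
  S <- planted$structural
  if (!any(planted$optimal_mask) || !any(planted$nonoptimal_mask))
    stop("need at least one optimal and one nonoptimal planted edge")
  S_opt <- S * planted$optimal_mask
  S_task <- task_weights[2] * S_opt +
    task_weights[1] * S * planted$nonoptimal_mask
  rest <- gen_functional(S_opt, a, "identity", noise_sd, seed)
  task <- gen_functional(S_task, a, "identity", noise_sd, seed + 1L)
  list(rest = rest, task = task)
}

#' Generate a ROI x gene expression matrix with a planted component
#'
#' \code{n_signal} columns equal \code{ro} plus Gaussian noise (fixed
#' positive loading); the remaining columns are standard-normal noise.
#' Column order is shuffled under the seed so signal genes are not trivially
#' identifiable by position.
#'
#' @param ro per-node regional-optimality vector
#' @param n_genes total number of gene columns
#' @param n_signal number of columns carrying the planted signal
#' @param noise_sd noise added to signal columns
#' @param seed RNG seed
#' @return numeric matrix, rows = nodes, columns named g1..g<n_genes>, with
#'   attribute \code{signal_genes} naming the planted columns
#' @export
gen_expression <- function(ro, n_genes = 200, n_signal = 10,
                           noise_sd = 0.5, seed = 1) {
  stopifnot(n_signal <= n_genes, n_genes >= 1)
  set.seed(seed)
  n <- length(ro)
  X <- matrix(stats::rnorm(n * n_genes), n, n_genes)
  if (n_signal > 0)
    X[, seq_len(n_signal)] <- ro +
      matrix(stats::rnorm(n * n_signal, sd = noise_sd), n, n_signal)
  ord <- sample.int(n_genes)
  X <- X[, ord, drop = FALSE]
  colnames(X) <- paste0("g", seq_len(n_genes))
  attr(X, "signal_genes") <- colnames(X)[match(seq_len(n_signal), ord)]
  X
}

#' Generate a node partition into k networks
#'
#' Every label is used at least once (one random node is pinned to each
#' label, the rest drawn uniformly).
#'
#' @param n number of nodes
#' @param k_networks number of labels (1 <= k <= n)
#' @param seed RNG seed
#' @return character vector of labels N1..N<k>, one per node
#' @export
gen_partition <- function(n, k_networks = 7, seed = 1) {
  stopifnot(k_networks >= 1, k_networks <= n)
  set.seed(seed)
  lab <- sample.int(k_networks, n, replace = TRUE)
  pin <- sample.int(n, k_networks)
  lab[pin] <- seq_len(k_networks)
  paste0("N", lab)
}
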