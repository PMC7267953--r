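#' Betti-0 persistence scoring of predicted functional matrices
#'
#' Instead of comparing two fully connected matrices entry-wise, the
#' homology score compares their topology across all edge densities: at
#' density lambda the floor(lambda * E) strongest edges are kept
#' (E = n(n-1)/2 off-diagonal pairs) and the number of connected components
#' beta0 is counted. Density 0 is the empty graph (beta0 = n), density 1 the
#' complete one. The goodness-of-fit is the squared difference between the
#' two beta0 curves integrated over density and divided by n^2; smaller is
#' better, 0 means topologically identical at every threshold.
#'
#' @name homology
NULL

# Edge ranking: by weight descending (strongest correlations first), ties by
# (i, j) index; optionally by absolute weight.
.rank_edges <- function(M, absolute = FALSE) {
  n <- nrow(M)
  ij <- which(upper.tri(M), arr.ind = TRUE)
  w <- M[upper.tri(M)]
  if (absolute) w <- abs(w)
  ord <- order(-w, ij[, 1], ij[, 2])
  ij[ord, , drop = FALSE]
}

# beta0 after adding the first t ranked edges, for t = 0..E, by incremental
# union-find with path compression.
.beta0_by_rank <- function(M, absolute = FALSE) {
  n <- nrow(M)
  edges <- .rank_edges(M, absolute)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  comp <- n
  beta <- integer(nrow(edges) + 1L)
  beta[1] <- n
  for (t in seq_len(nrow(edges))) {
    a <- find(edges[t, 1]); b <- find(edges[t, 2])
    if (a != b) { parent[a] <- b; comp <- comp - 1L }
    beta[t + 1L] <- comp
  }
  beta
}

#' Betti-0 curve of a weighted matrix across edge densities
#'
#' @param M symmetric matrix, n >= 2
#' @param grid increasing density grid in [0, 1]; default one step per edge
#'   rank (exact piecewise-constant curve)
#' @param absolute rank edges by absolute weight instead of signed weight
#' @return object of class \code{betti_curve}: data.frame with columns
#'   \code{density} and \code{beta0}
#' @export
betti0_curve <- function(M, grid = NULL, absolute = FALSE) {
  n <- nrow(M)
  stopifnot(n >= 2)
  E <- n * (n - 1L) / 2L
  if (is.null(grid)) grid <- (0:E) / E
  stopifnot(all(diff(grid) > 0), min(grid) >= 0, max(grid) <= 1)
  beta_all <- .beta0_by_rank(M, absolute)
  beta <- beta_all[floor(grid * E + 1e-9) + 1L]  # guard float roundoff at grid knots
  structure(data.frame(density = grid, beta0 = beta),
            class = c("betti_curve", "data.frame"))
}

#' Betti-0 persistence goodness-of-fit between two matrices
#'
#' \eqn{SSE_\beta = (1/n^2)\int_0^1 (\beta_0(\lambda) -
#' \hat\beta_0(\lambda))^2 d\lambda}, evaluated by the trapezoidal rule on
#' the common density grid. With the default per-edge-rank grid the curves
#' are exact. Symmetric in its arguments; 0 iff the curves coincide on the
#' grid.
#'
#' @param F_real,F_pred symmetric matrices of equal dimension
#' @param grid density grid (default one step per edge rank)
#' @param absolute rank edges by absolute weight
#' @return nonnegative score
#' @export
sse_beta <- function(F_real, F_pred, grid = NULL, absolute = FALSE) {
  if (!all(dim(F_real) == dim(F_pred))) stop("dimension mismatch")
  n <- nrow(F_real)
  c1 <- betti0_curve(F_real, grid, absolute)
  c2 <- betti0_curve(F_pred, grid, absolute)
  dsq <- (c1$beta0 - c2$beta0)^2
  lam <- c1$density
  integral <- sum(diff(lam) * (utils::head(dsq, -1) + utils::tail(dsq, -1)) / 2)
  integral / n^2
}
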