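# Independent oracles used across test files. These deliberately use naive
# exhaustive / brute-force strategies so they stay independent of the
# implementation paths they check.

# Exhaustive minimum set cover: enumerate subsets by increasing size.
brute_min_cover_size <- function(sets, universe) {
  m <- length(sets)
  for (sz in seq_len(m)) {
    combs <- utils::combn(m, sz)
    for (c0 in seq_len(ncol(combs))) {
      if (all(universe %in% unlist(sets[combs[, c0]]))) return(sz)
    }
  }
  Inf
}

# Betti-0 via igraph at a single density, counting components after keeping
# the t strongest upper-triangle entries.
brute_beta0_at <- function(M, t_edges, absolute = FALSE) {
  n <- nrow(M)
  ij <- which(upper.tri(M), arr.ind = TRUE)
  w <- M[upper.tri(M)]
  if (absolute) w <- abs(w)
  ord <- order(-w, ij[, 1], ij[, 2])
  keep <- ij[ord[seq_len(t_edges)], , drop = FALSE]
  g <- igraph::graph_from_edgelist(keep, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::gorder(g))
  igraph::components(g)$no
}

# Dense brute-force homology score at one-step-per-edge resolution,
# trapezoidal rule, recomputing components from scratch at every rank.
brute_sse_beta <- function(F_real, F_pred) {
  n <- nrow(F_real)
  E <- n * (n - 1) / 2
  lam <- (0:E) / E
  b1 <- vapply(0:E, function(t) brute_beta0_at(F_real, t), numeric(1))
  b2 <- vapply(0:E, function(t) brute_beta0_at(F_pred, t), numeric(1))
  dsq <- (b1 - b2)^2
  sum(diff(lam) * (head(dsq, -1) + tail(dsq, -1)) / 2) / n^2
}

# Small random symmetric matrix with distinct entries.
rand_sym <- function(n, seed) {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n, n)
  (M + t(M)) / 2
}
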