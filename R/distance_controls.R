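#' Distance-penalized generative control networks and distance regression
#'
#' Controls for the possibility that structure-function prediction is driven
#' purely by spatial proximity: (i) synthetic networks grown with connection
#' probability \eqn{P(u,v) \propto dist(u,v)^{-\eta}}, with the exponent
#' fitted to a real network by a Kolmogorov-Smirnov energy and a 1-D
#' Voronoi-cell resampling search; (ii) projection of predicted functional
#' connectivity onto the orthogonal complement of the distance matrix's
#' column space.
#'
#' @name distance-controls
NULL

#' Sample a distance-penalized random network
#'
#' Adds m distinct undirected edges one at a time, each drawn with
#' probability proportional to \eqn{dist^{-\eta}} over pairs not yet present
#' (renormalizing after each addition; equivalently, weighted sampling
#' without replacement). eta = 0 gives a uniform random graph; large eta
#' concentrates on the shortest pairs.
#'
#' @param D distance matrix
#' @param m number of edges (<= n(n-1)/2)
#' @param eta distance-penalty exponent
#' @param seed RNG seed
#' @return binary symmetric adjacency matrix
#' @export
sample_distance_network <- function(D, m, eta, seed = 1) {
  n <- nrow(D)
  E <- n * (n - 1) / 2
  if (m > E) stop("m exceeds the number of node pairs")
  set.seed(seed)
  d <- D[upper.tri(D)]
  w <- d^(-eta)
  w <- w / max(w)                      # overflow guard for large |eta|
  picked <- sample.int(E, m, prob = w)
  A <- matrix(0L, n, n)
  sel <- logical(E)
  sel[picked] <- TRUE
  A[upper.tri(A)] <- as.integer(sel)
  A + t(A)
}

# Two-sample Kolmogorov-Smirnov statistic (max ECDF gap), tie-safe.
.ks_stat <- function(x, y) {
  v <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(v)
  Fy <- stats::ecdf(y)(v)
  max(abs(Fx - Fy))
}

# Topological + geometric summary distributions of a binary network.
.net_stats <- function(A, D) {
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  list(degree = igraph::degree(g),
       clustering = cc,
       betweenness = igraph::betweenness(g),
       edge_length = D[upper.tri(D) & A > 0])
}

#' Kolmogorov-Smirnov energy between a real and a synthetic network
#'
#' Maximum over the KS distances between the two networks' distributions of
#' degree, local clustering coefficient, node betweenness, and edge length.
#'
#' @param A_real,A_syn binary adjacency matrices
#' @param D distance matrix (for edge lengths)
#' @param stats which distributions to include
#' @return energy in [0, 1]
#' @export
network_energy <- function(A_real, A_syn, D,
                           stats = c("degree", "clustering", "betweenness",
                                     "edge_length")) {
  s1 <- .net_stats(A_real, D)
  s2 <- .net_stats(A_syn, D)
  max(vapply(stats, function(nm) .ks_stat(s1[[nm]], s2[[nm]]), numeric(1)))
}

#' Fit the distance-penalty exponent to a real network
#'
#' Samples \code{n_init} exponents uniformly over \code{eta_range} and scores
#' each by the KS energy of networks drawn at that exponent (mean over
#' \code{draws_per_cell} draws, matched edge count). The 1-D parameter space
#' is then partitioned into Voronoi cells (nearest-neighbour intervals of
#' the sampled exponents); for \code{n_rounds} rounds, cells are chosen with
#' probability inversely proportional to their energy, new exponents are
#' drawn uniformly inside the chosen cells and scored. The lowest-energy
#' draw wins.
#'
#' @param S_real structural matrix (nonzero = edge)
#' @param D distance matrix
#' @param eta_range search interval for the exponent
#' @param n_init initial uniform samples
#' @param n_rounds resampling rounds (default 2)
#' @param n_per_round new samples per round (default n_init / 2)
#' @param draws_per_cell synthetic draws averaged per candidate exponent
#' @param seed RNG seed
#' @return object of class \code{generative_fit}: \code{eta}, \code{energy},
#'   \code{network} (best synthetic adjacency), \code{trace} (data.frame of
#'   all sampled exponents, energies, round)
#' @export
fit_generative_model <- function(S_real, D, eta_range = c(-1, 10),
                                 n_init = 64, n_rounds = 2,
                                 n_per_round = NULL, draws_per_cell = 1,
                                 seed = 1) {
  if (!any(S_real != 0)) stop("real network has no edges")
  if (is.null(n_per_round)) n_per_round <- max(2L, n_init %/% 2L)
  set.seed(seed)
  A_real <- (S_real != 0) * 1L
  m <- sum(A_real[upper.tri(A_real)])
  score_eta <- function(eta) {
    mean(vapply(seq_len(draws_per_cell), function(i) {
      A <- sample_distance_network(D, m, eta,
                                   seed = sample.int(.Machine$integer.max, 1))
      network_energy(A_real, A, D)
    }, numeric(1)))
  }
  etas <- stats::runif(n_init, eta_range[1], eta_range[2])
  energies <- vapply(etas, score_eta, numeric(1))
  trace <- data.frame(eta = etas, energy = energies, round = 0L)
  for (rnd in seq_len(n_rounds)) {
    ord <- order(trace$eta)
    pts <- trace$eta[ord]
    en <- trace$energy[ord]
    # Voronoi cells in 1-D: midpoint intervals around each sampled eta
    mid <- c(eta_range[1], (pts[-1] + pts[-length(pts)]) / 2, eta_range[2])
    cells <- sample.int(length(pts), n_per_round, replace = TRUE,
                        prob = 1 / pmax(en, 1e-6))
    new_etas <- stats::runif(n_per_round, mid[cells], mid[cells + 1])
    new_en <- vapply(new_etas, score_eta, numeric(1))
    trace <- rbind(trace, data.frame(eta = new_etas, energy = new_en,
                                     round = rnd))
  }
  best <- which.min(trace$energy)
  net <- sample_distance_network(D, m, trace$eta[best],
                                 seed = sample.int(.Machine$integer.max, 1))
  structure(list(eta = trace$eta[best], energy = trace$energy[best],
                 network = net, trace = trace),
            class = "generative_fit")
}

#' @export
print.generative_fit <- function(x, ...) {
  cat(sprintf("generative distance model: eta = %.3f (energy %.4f, %d samples)\n",
              x$eta, x$energy, nrow(x$trace)))
  invisible(x)
}

#' Regress distance out of a predicted functional matrix
#'
#' Column-wise projection onto the orthogonal complement of the distance
#' matrix's column space: \code{F - D \%*\% (pinv(D) \%*\% F)} with pinv the
#' Moore-Penrose pseudoinverse. Idempotent; the residual is orthogonal to
#' every column of D.
#'
#' @param F_pred predicted functional matrix
#' @param D distance matrix
#' @param symmetrize average the residual with its transpose (the raw
#'   formula is column-wise and need not be symmetric)
#' @return residual matrix
#' @export
regress_out_distance <- function(F_pred, D, symmetrize = FALSE) {
  if (!all(dim(F_pred) == dim(D))) stop("dimension mismatch")
  res <- F_pred - D %*% (MASS::ginv(D) %*% F_pred)
  if (symmetrize) res <- (res + t(res)) / 2
  res
}
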