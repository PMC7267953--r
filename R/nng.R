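#' Nash-equilibrium network game (NNG) over a node geometry
#'
#' The navigation game treats each node as a player choosing which other nodes
#' to connect to. A node u can hand information to a neighbour v, which then
#' forwards it greedily; the set of targets reachable that way is
#' \eqn{S_v^u = \{w : dist(v,w) < dist(u,w)\}}. Each player picks the minimum
#' number of neighbours whose navigation sets jointly cover all targets (an
#' exact minimum set cover). Pooling every player's choice and symmetrising
#' yields the equilibrium network: maximal greedy navigability with a minimum
#' number of edges.
#'
#' @name nng
NULL

#' Euclidean distance matrix from 3-D node coordinates
#'
#' @param coords n x 3 numeric matrix
#' @return symmetric n x n distance matrix with zero diagonal
#' @export
dist_from_coords <- function(coords) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, nrow(coords) >= 2)
  as.matrix(stats::dist(coords))
}

.check_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance matrix must be square")
  if (any(abs(diag(D)) > 1e-12))
    stop("distance matrix must have zero diagonal")
  if (max(abs(D - t(D))) > 1e-8)
    stop("distance matrix must be symmetric")
  off <- D[upper.tri(D)]
  if (any(off <= 0))
    stop("off-diagonal distances must be strictly positive (duplicate points?)")
  invisible(TRUE)
}

#' Navigation set of a candidate first hop
#'
#' Targets w (other than u) that are strictly closer to v than to u, i.e. the
#' nodes u can reach by handing off to v and continuing greedily.
#'
#' @param u,v node indices (1-based), u != v
#' @param D distance matrix
#' @return integer vector of member nodes (always contains v)
#' @export
navigation_set <- function(u, v, D) {
  if (u == v) stop("u and v must differ")
  w <- seq_len(nrow(D))
  members <- w[D[v, ] < D[u, ] & w != u]
  members
}

#' Optimal navigation vector of one node
#'
#' The minimum-cardinality set of first hops v whose navigation sets jointly
#' cover every other node. Solved exactly; ties between distinct minimum
#' covers are broken by taking the lexicographically smallest neighbour set.
#'
#' @param u node index
#' @param D distance matrix
#' @return integer vector of chosen neighbours
#' @export
optimal_navigation_vector <- function(u, D) {
  n <- nrow(D)
  if (n < 2) stop("need at least 2 nodes")
  others <- setdiff(seq_len(n), u)
  sets <- lapply(others, function(v) navigation_set(u, v, D))
  idx <- min_set_cover(sets, others)
  sort(others[idx])
}

#' Build the Nash-equilibrium navigation-game network
#'
#' Runs the minimum-cover choice independently for every node and pools all
#' chosen connections into one undirected graph. With \code{blocks}, the game
#' is played separately inside each block (e.g. per hemisphere, as needed for
#' geodesic distances that are only defined within a hemisphere) and the
#' results are assembled block-diagonally.
#'
#' @param D symmetric distance matrix (Euclidean from coordinates, or any
#'   user-supplied metric such as geodesic distances)
#' @param blocks optional vector of block labels, one per node
#' @return object of class \code{nng}: list with \code{adjacency} (binary
#'   symmetric matrix), \code{chosen} (per-node neighbour sets), and
#'   \code{M} (number of undirected edges)
#' @export
build_nng <- function(D, blocks = NULL) {
  .check_distance_matrix(D)
  n <- nrow(D)
  adj <- matrix(0L, n, n)
  chosen <- vector("list", n)
  if (is.null(blocks)) {
    for (u in seq_len(n)) {
      nb <- optimal_navigation_vector(u, D)
      chosen[[u]] <- nb
      adj[u, nb] <- 1L
      adj[nb, u] <- 1L
    }
  } else {
    stopifnot(length(blocks) == n)
    for (b in unique(blocks)) {
      ix <- which(blocks == b)
      sub <- build_nng(D[ix, ix, drop = FALSE])
      adj[ix, ix] <- sub$adjacency
      for (k in seq_along(ix)) chosen[[ix[k]]] <- ix[sub$chosen[[k]]]
    }
  }
  structure(list(adjacency = adj, chosen = chosen,
                 M = sum(adj[upper.tri(adj)] > 0)),
            class = "nng")
}

#' @export
print.nng <- function(x, ...) {
  cat("NNG network:", nrow(x$adjacency), "nodes,", x$M, "undirected edges\n")
  invisible(x)
}

#' Greedy routing between two nodes
#'
#' Hop-by-hop navigation: from the current node, move to the connected
#' neighbour closest to the target, requiring strict progress (each hop must
#' be strictly closer to the target than the current node, which guarantees
#' termination). Returns the visited node sequence, or NULL on failure.
#'
#' @param adj binary adjacency matrix
#' @param D distance matrix
#' @param s,t source and target nodes, s != t
#' @return integer path vector from s to t, or NULL if routing fails
#' @export
greedy_route <- function(adj, D, s, t) {
  if (s == t) stop("source and target must differ")
  path <- s
  cur <- s
  while (cur != t) {
    nb <- which(adj[cur, ] > 0)
    if (length(nb) == 0) return(NULL)
    d <- D[nb, t]
    j <- nb[which.min(d)]          # ties: smallest index via which.min
    if (D[j, t] >= D[cur, t]) return(NULL)  # no strict progress
    cur <- j
    path <- c(path, cur)
  }
  path
}

#' Fraction of node pairs connected by greedy routing
#'
#' @param adj binary adjacency matrix
#' @param D distance matrix
#' @return fraction in [0, 1] of ordered pairs (s, t) with a greedy path
#' @export
navigability <- function(adj, D) {
  n <- nrow(adj)
  stopifnot(n >= 2)
  ok <- 0L
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    if (!is.null(greedy_route(adj, D, s, t))) ok <- ok + 1L
  }
  ok / (n * (n - 1L))
}

#' Classify structural edges against the navigation-game network
#'
#' An edge is optimal (T) if present in both the structural network (nonzero
#' weight) and the NNG; nonoptimal if structural only; a false positive (F)
#' if NNG only. Optimality is |T| / |M| where |M| is the NNG edge count, so
#' |T| + |F| = |M| always.
#'
#' @param S symmetric weighted structural matrix (zero = no tract)
#' @param nng an \code{nng} object or a binary adjacency matrix
#' @return object of class \code{edge_classification}: masks
#'   (\code{optimal_mask}, \code{nonoptimal_mask}, \code{fp_mask}, symmetric
#'   logical), edge lists (2-column matrices, i < j), counts and the
#'   optimality ratio
#' @export
classify_edges <- function(S, nng) {
  adj <- if (inherits(nng, "nng")) nng$adjacency else nng
  if (!all(dim(S) == dim(adj))) stop("dimension mismatch between S and NNG")
  if (max(abs(S - t(S))) > 1e-8) stop("structural matrix must be symmetric")
  has_s <- S != 0
  has_m <- adj > 0
  diag(has_s) <- FALSE
  diag(has_m) <- FALSE
  opt <- has_s & has_m
  non <- has_s & !has_m
  fp  <- !has_s & has_m
  ut <- upper.tri(S)
  edges <- function(mask) {
    ij <- which(mask & ut, arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    colnames(ij) <- c("i", "j")
    ij
  }
  M <- sum(has_m & ut)
  Tn <- sum(opt & ut)
  structure(list(
    optimal_mask = opt, nonoptimal_mask = non, fp_mask = fp,
    optimal_edges = edges(opt), nonoptimal_edges = edges(non),
    false_positive_edges = edges(fp),
    T_count = Tn, F_count = M - Tn, M_count = M,
    nonoptimal_count = sum(non & ut),
    optimality = if (M > 0) Tn / M else NA_real_),
    class = "edge_classification")
}

#' @export
print.edge_classification <- function(x, ...) {
  cat(sprintf(
    "edge classification: |T|=%d optimal, %d nonoptimal, |F|=%d false positive; |M|=%d; optimality=%.4f\n",
    x$T_count, x$nonoptimal_count, x$F_count, x$M_count, x$optimality))
  invisible(x)
}

#' Mask a structural matrix by edge class
#'
#' Produces the optimal-only / nonoptimal-only / full structural matrix used
#' as input to the structure-to-function prediction.
#'
#' @param S structural matrix
#' @param cls an \code{edge_classification}
#' @param mask one of "all", "optimal", "nonoptimal"
#' @return masked copy of S
#' @export
mask_structural <- function(S, cls, mask = c("all", "optimal", "nonoptimal")) {
  mask <- match.arg(mask)
  switch(mask,
         all = S,
         optimal = S * cls$optimal_mask,
         nonoptimal = S * cls$nonoptimal_mask)
}
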