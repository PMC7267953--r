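# Exact minimum set cover by branch and bound with dominance reductions.
# Instances here are small (one per node, candidate sets = other nodes), so an
# exact combinatorial search with a greedy upper bound is fast and verifiable
# against exhaustive enumeration.

# Greedy cover size: upper bound for the branch and bound.
.greedy_cover <- function(L, uncovered, allowed) {
  chosen <- integer(0)
  while (any(uncovered)) {
    gain <- rowSums(L[, uncovered, drop = FALSE]) * allowed
    j <- which.max(gain)
    if (gain[j] == 0) return(NULL)  # infeasible
    chosen <- c(chosen, j)
    uncovered <- uncovered & !L[j, ]
    allowed[j] <- FALSE
  }
  chosen
}

# Minimum number of allowed sets covering `uncovered`; Inf if it cannot be
# done within `budget`. Branches on the element with fewest covering sets.
.min_cover_size <- function(L, uncovered, allowed, budget) {
  if (!any(uncovered)) return(0L)
  if (budget <= 0) return(Inf)
  cover_counts <- colSums(L[allowed, , drop = FALSE])  # per element
  cover_counts[!uncovered] <- NA
  if (any(cover_counts[uncovered] == 0)) return(Inf)
  # lower bound: even the largest set covers at most max_gain elements
  gains <- rowSums(L[, uncovered, drop = FALSE])
  gains[!allowed] <- 0
  if (ceiling(sum(uncovered) / max(gains)) > budget) return(Inf)
  e <- which.min(cover_counts)                 # hardest uncovered element
  cands <- which(allowed & L[, e])
  cands <- cands[order(-gains[cands])]
  best <- Inf
  for (j in cands) {
    al <- allowed; al[j] <- FALSE
    sub <- .min_cover_size(L, uncovered & !L[j, ], al,
                           min(budget, best) - 1)
    if (sub + 1 < best) best <- sub + 1
    if (best == 1) break
  }
  best
}

#' Exact minimum set cover
#'
#' Finds a minimum-cardinality subfamily of \code{sets} whose union contains
#' \code{universe}, by exact branch and bound (no approximation). Among all
#' minimum covers the lexicographically smallest index set is returned, which
#' makes the result deterministic when several optima exist.
#'
#' @param sets list of integer vectors (the candidate sets)
#' @param universe integer vector of elements that must be covered
#' @return integer vector of indices into \code{sets} (sorted ascending)
#' @export
min_set_cover <- function(sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) return(integer(0))
  elems <- sort(unique(c(universe, unlist(sets))))
  m <- length(sets)
  L <- matrix(FALSE, m, length(elems))
  for (i in seq_len(m)) L[i, match(sets[[i]], elems)] <- TRUE
  uncovered <- elems %in% universe
  if (any(uncovered & colSums(L) == 0))
    stop("set cover infeasible: some elements are uncovered by every set")
  allowed <- rep(TRUE, m)
  ub <- length(.greedy_cover(L, uncovered, allowed))
  kstar <- .min_cover_size(L, uncovered, allowed, ub)
  # lexicographic refinement: pick the smallest index whose choice still
  # admits a completion of total size kstar using only larger indices
  chosen <- integer(0)
  unc <- uncovered
  lo <- 0L
  while (any(unc)) {
    need <- kstar - length(chosen)
    for (j in seq_len(m)) {
      if (j <= lo || !L[j, ] %*% unc) next
      al <- rep(FALSE, m); al[seq_len(m) > j] <- TRUE
      if (.min_cover_size(L, unc & !L[j, ], al, need - 1) <= need - 1) {
        chosen <- c(chosen, j); unc <- unc & !L[j, ]; lo <- j
        break
      }
    }
  }
  chosen
}
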