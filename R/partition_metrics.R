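#' Optimal-connection ratios over a node partition, and regional optimality
#'
#' These metrics distribute the optimal/nonoptimal edge classes over a
#' partition of nodes into canonical networks and over individual nodes.
#' False-positive edges are excluded throughout: they do not exist in the
#' real structural network, so they enter no denominator.
#'
#' @name partition-metrics
NULL

.check_partition <- function(partition, n) {
  if (length(partition) != n || any(is.na(partition)))
    stop("every node must carry a partition label")
  as.character(partition)
}

#' Intra-network optimal-connection ratios
#'
#' For each label L: (number of optimal edges with both ends in L) divided by
#' (number of structural edges with both ends in L). Labels with no
#' intra-network structural edge get NA (no edges is not the same as no
#' optimal edges).
#'
#' @param cls an \code{edge_classification}
#' @param S structural matrix (defines the denominator edge set)
#' @param partition per-node labels
#' @return named numeric vector, one entry per label
#' @export
intra_ratios <- function(cls, S, partition) {
  partition <- .check_partition(partition, nrow(S))
  ut <- upper.tri(S)
  labs <- sort(unique(partition))
  res <- stats::setNames(rep(NA_real_, length(labs)), labs)
  struct <- (cls$optimal_mask | cls$nonoptimal_mask) & ut
  opt <- cls$optimal_mask & ut
  for (L in labs) {
    inL <- partition == L
    block <- outer(inL, inL, `&`)
    denom <- sum(struct & block)
    if (denom > 0) res[L] <- sum(opt & block) / denom
  }
  res
}

#' Inter-network optimal-connection ratios
#'
#' For each unordered pair of labels (A, B), A != B: optimal cross edges over
#' structural cross edges; NA when no structural cross edge exists. Also
#' returns each label's mean ratio over its k-1 partners (NA partners
#' dropped).
#'
#' @inheritParams intra_ratios
#' @return list with \code{pairs} (symmetric label x label matrix, diagonal
#'   NA) and \code{per_label_mean}
#' @export
inter_ratios <- function(cls, S, partition) {
  partition <- .check_partition(partition, nrow(S))
  ut <- upper.tri(S)
  labs <- sort(unique(partition))
  k <- length(labs)
  pairs <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  struct <- (cls$optimal_mask | cls$nonoptimal_mask) & ut
  opt <- cls$optimal_mask & ut
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      inA <- partition == labs[i]
      inB <- partition == labs[j]
      cross <- outer(inA, inB, `&`) | outer(inB, inA, `&`)
      denom <- sum(struct & cross)
      if (denom > 0) pairs[i, j] <- pairs[j, i] <- sum(opt & cross) / denom
    }
  }
  per_label_mean <- apply(pairs, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) mean(r) else NA_real_
  })
  list(pairs = pairs, per_label_mean = per_label_mean)
}

#' Regional optimality (RO)
#'
#' Per node: degree of optimal connections minus degree of nonoptimal
#' connections (raw), normalized by the node's total structural degree so
#' normalized RO lies in [-1, 1]. Nodes with zero structural degree get NA.
#'
#' @param cls an \code{edge_classification}
#' @param S structural matrix (unused beyond dimension check; the
#'   classification masks already carry the degrees)
#' @return data.frame with columns \code{node}, \code{raw}, \code{normalized}
#' @export
regional_optimality <- function(cls, S) {
  stopifnot(all(dim(S) == dim(cls$optimal_mask)))
  d_opt <- rowSums(cls$optimal_mask)
  d_non <- rowSums(cls$nonoptimal_mask)
  total <- d_opt + d_non
  raw <- d_opt - d_non
  normalized <- ifelse(total > 0, raw / total, NA_real_)
  data.frame(node = seq_len(nrow(S)), raw = raw, normalized = normalized)
}
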