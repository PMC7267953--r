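#' Partial least squares between gene expression and regional optimality
#'
#' PLS1 regression of a per-node response (normalized regional optimality)
#' on a ROI x gene expression matrix, extracting components that maximize
#' predictor-response covariance. Significance of the top component's
#' variance explained comes from a permutation null over the row (label)
#' assignment; predictive performance is reported by k-fold cross-validated
#' R-squared.
#'
#' @name gene-pls
NULL

# One NIPALS PLS1 pass; X and y already centered (and X scaled). Returns the
# pieces needed for variance accounting and deflation.
.pls1_component <- function(X, y) {
  w <- drop(crossprod(X, y))
  nw <- sqrt(sum(w^2))
  if (nw < .Machine$double.eps) stop("predictor block has no covariance with y")
  w <- w / nw
  t_ <- drop(X %*% w)
  tt <- sum(t_^2)
  p <- drop(crossprod(X, t_)) / tt
  q <- sum(y * t_) / tt
  list(w = w, scores = t_, p = p, q = q)
}

#' Fit a PLS1 model of a response on an expression matrix
#'
#' Columns of X are mean-centered (and z-scored unless \code{scale =
#' FALSE}); y is centered. Components are extracted by iterative deflation.
#'
#' @param X numeric matrix, rows = nodes/ROIs, columns = genes
#' @param y numeric response, one value per row of X
#' @param n_components number of components (<= min(nrow - 1, ncol))
#' @param scale z-score the predictor columns (default TRUE; microarray
#'   scales are heterogeneous)
#' @return object of class \code{pls_result}: per-component x-scores,
#'   gene weights and loadings, % variance explained in X and in y
#'   (cumulative <= 100), component-1 Spearman rho against y
#' @export
pls_fit <- function(X, y, n_components = 2, scale = TRUE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0) stop("constant response")
  stopifnot(n_components >= 1,
            n_components <= min(nrow(X) - 1L, ncol(X)))
  Xc <- base::scale(X, center = TRUE, scale = scale)
  if (scale) Xc[, attr(Xc, "scaled:scale") == 0] <- 0  # constant genes
  yc <- y - mean(y)
  ss_x <- sum(Xc^2)
  ss_y <- sum(yc^2)
  Xd <- Xc; yd <- yc
  scores <- matrix(NA_real_, nrow(X), n_components)
  weights <- matrix(NA_real_, ncol(X), n_components,
                    dimnames = list(colnames(X), NULL))
  loadings <- matrix(NA_real_, ncol(X), n_components)
  q <- numeric(n_components)
  varexp_x <- varexp_y <- numeric(n_components)
  for (h in seq_len(n_components)) {
    cmp <- .pls1_component(Xd, yd)
    scores[, h] <- cmp$scores
    weights[, h] <- cmp$w
    loadings[, h] <- cmp$p
    q[h] <- cmp$q
    tt <- sum(cmp$scores^2)
    varexp_x[h] <- 100 * tt * sum(cmp$p^2) / ss_x
    varexp_y[h] <- 100 * cmp$q^2 * tt / ss_y
    Xd <- Xd - tcrossprod(cmp$scores, cmp$p)
    yd <- yd - cmp$q * cmp$scores
  }
  structure(list(n_components = n_components,
                 scores = scores, weights = weights, loadings = loadings,
                 q = q, varexp_x = varexp_x, varexp_y = varexp_y,
                 spearman_rho = stats::cor(scores[, 1], y,
                                           method = "spearman"),
                 scale = scale),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf(
    "PLS1: %d component(s); %% var in y: %s; component-1 Spearman rho = %.4f\n",
    x$n_components, paste(sprintf("%.1f", x$varexp_y), collapse = ", "),
    x$spearman_rho))
  invisible(x)
}

#' Rank genes by their weight on the first PLS component
#'
#' @param fit a \code{pls_result}
#' @return data.frame (gene, weight) sorted by decreasing |weight|
#' @export
pls_gene_ranking <- function(fit) {
  w <- fit$weights[, 1]
  genes <- rownames(fit$weights)
  if (is.null(genes)) genes <- paste0("g", seq_along(w))
  df <- data.frame(gene = genes, weight = w)
  df[order(-abs(df$weight)), ]
}

#' Permutation test for the top PLS component
#'
#' Null statistic: variance explained in y by component 1 after permuting
#' the row order of y. The add-one estimator p = (1 + #{null >= observed}) /
#' (1 + n_perm) is never exactly zero.
#'
#' @inheritParams pls_fit
#' @param n_perm number of permutations (>= 100; 1000 in the standard run)
#' @param seed RNG seed
#' @return list: \code{p}, \code{observed} (% var in y), \code{null} vector
#' @export
pls_permutation_test <- function(X, y, n_perm = 1000, seed = 1,
                                 scale = TRUE) {
  stopifnot(n_perm >= 100)
  set.seed(seed)
  obs <- pls_fit(X, y, 1, scale)$varexp_y[1]
  null <- vapply(seq_len(n_perm), function(i) {
    pls_fit(X, sample(y), 1, scale)$varexp_y[1]
  }, numeric(1))
  list(p = (1 + sum(null >= obs)) / (1 + n_perm), observed = obs, null = null)
}

#' Cross-validated predictive R-squared per component count
#'
#' k-fold cross-validation of the PLS1 regression, reported per number of
#' components. Used only to report predictive performance; component 1 is
#' always the component carried forward to the permutation test.
#'
#' @inheritParams pls_fit
#' @param max_components largest component count to evaluate
#' @param n_folds folds (default 10)
#' @param seed RNG seed
#' @return data.frame (n_components, r2)
#' @export
pls_cv_r2 <- function(X, y, max_components = 3, n_folds = 10, seed = 1,
                      scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  out <- data.frame(n_components = seq_len(max_components), r2 = NA_real_)
  for (k in seq_len(max_components)) {
    pred <- numeric(n)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- pls_fit(X[tr, , drop = FALSE], y[tr], k, scale)
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- if (scale) apply(X[tr, , drop = FALSE], 2, stats::sd) else
        rep(1, ncol(X))
      sdv[sdv == 0] <- 1
      Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdv, `/`)
      # regression coefficients in the centered/scaled space
      W <- fit$weights; P <- fit$loadings
      B <- W %*% solve(crossprod(P, W), fit$q)
      pred[!tr] <- mean(y[tr]) + Xte %*% B
    }
    out$r2[k] <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }
  out
}
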