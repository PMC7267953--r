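#' Spectral structure-to-function mapping
#'
#' Predicted functional connectivity is modelled as a rotated matrix
#' polynomial of the structural matrix, \eqn{\hat F = R(\sum_{r=0}^k a_r
#' S^r)R^T} with R special orthogonal. Minimizing the Frobenius distance to
#' the observed F over (a, R) has a closed-form structure for symmetric
#' matrices: align the eigenvectors of S to those of F (both spectra sorted
#' descending) to get R, then regress F's eigenvalues on powers of S's
#' eigenvalues to get a. Longer paths (higher powers of S) enter through
#' higher polynomial orders; accuracy plateaus beyond order ~5, the default.
#'
#' @name spectral-prediction
NULL

.vandermonde <- function(x, k) outer(x, 0:k, `^`)

#' Fit the rotated matrix-polynomial map from S to F
#'
#' @param S,F symmetric matrices of equal dimension
#' @param k polynomial order (>= 1; default 5)
#' @return object of class \code{spectral_map}: coefficients \code{a}
#'   (length k+1), rotation \code{R} (orthogonal, det +1), \code{k}, and the
#'   achieved Frobenius residual \code{residual}
#' @export
fit_spectral_map <- function(S, F, k = 5) {
  if (max(abs(S - t(S))) > 1e-8 || max(abs(F - t(F))) > 1e-8)
    stop("S and F must be symmetric")
  if (!all(dim(S) == dim(F))) stop("dimension mismatch")
  stopifnot(k >= 1)
  n <- nrow(S)
  eS <- eigen(S, symmetric = TRUE)   # eigenvalues sorted descending
  eF <- eigen(F, symmetric = TRUE)
  R <- eF$vectors %*% t(eS$vectors)
  if (det(R) < 0) {
    j <- which.min(abs(eS$values))   # flip the least informative pair
    R <- eF$vectors %*% t(eS$vectors * rep(c(1, -1)[(seq_len(n) == j) + 1],
                                           each = n))
  }
  V <- .vandermonde(eS$values, k)
  if (k >= n) {
    warning("polynomial order >= matrix dimension; rank-deficient fit regularized")
    a <- qr.coef(qr(V, LAPACK = TRUE), eF$values)
    a[is.na(a)] <- 0
  } else {
    a <- stats::lm.fit(V, eF$values)$coefficients
    a[is.na(a)] <- 0
  }
  model <- structure(list(k = k, a = unname(a), R = R), class = "spectral_map")
  model$residual <- norm(predict_fc(model, S) - F, "F")
  model
}

#' @export
print.spectral_map <- function(x, ...) {
  cat("spectral map: order", x$k, "| a =",
      paste(signif(x$a, 4), collapse = ", "),
      "| residual", signif(x$residual, 5), "\n")
  invisible(x)
}

#' Predict functional connectivity from a fitted spectral map
#'
#' @param model a \code{spectral_map}
#' @param S structural matrix
#' @return predicted symmetric matrix \eqn{R(\sum a_r S^r)R^T}
#' @export
predict_fc <- function(model, S) {
  stopifnot(inherits(model, "spectral_map"))
  n <- nrow(S)
  if (nrow(model$R) != n) stop("dimension mismatch")
  P <- matrix(0, n, n)
  Sr <- diag(n)
  for (r in seq_along(model$a)) {
    P <- P + model$a[r] * Sr
    Sr <- Sr %*% S
  }
  out <- model$R %*% P %*% t(model$R)
  (out + t(out)) / 2
}

#' Upper-triangle correlation between predicted and observed matrices
#'
#' Pearson correlation over the strictly upper triangular entries (diagonal
#' excluded). Returns NA if either triangle is constant.
#'
#' @param F_pred,F_real symmetric matrices, n >= 3
#' @return correlation in [-1, 1], or NA
#' @export
score_correlation <- function(F_pred, F_real) {
  if (!all(dim(F_pred) == dim(F_real))) stop("dimension mismatch")
  stopifnot(nrow(F_real) >= 3)
  x <- F_pred[upper.tri(F_pred)]
  y <- F_real[upper.tri(F_real)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
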