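#' Standardise columns to zero mean and unit sum of squares
#'
#' @param X numeric matrix or data frame with at least two rows.
#' @return matrix whose columns have mean 0 and sum of squares 1.
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows")
  Xc <- sweep(X, 2L, colMeans(X))
  ss <- colSums(Xc^2)
  bad <- which(ss < .Machine$double.eps * nrow(X))
  if (length(bad))
    stop("constant column cannot be standardised: ",
         paste(colnames(X)[bad] %||% bad, collapse = ", "))
  sweep(Xc, 2L, sqrt(ss), `/`)
}

#' Canonical correlation analysis with Bartlett significance tests
#'
#' Finds paired linear combinations of two multivariate sets maximising
#' correlation, via singular value decomposition of the whitened
#' cross-covariance of the standardised data. Dimensionality is assessed
#' sequentially with Bartlett's chi-squared statistic
#' `chi2_k = -(n - 1 - (p + q + 1)/2) * sum_{i >= k} log(1 - r_i^2)` on
#' `(p - k + 1)(q - k + 1)` degrees of freedom; log p-values are reported
#' in nats. The sign of each canonical pair is fixed by making the
#' largest-magnitude loading of the x-vector positive.
#'
#' @param X n x p matrix (e.g. model parameters per subject).
#' @param Y n x q matrix (e.g. behavioural measures per subject).
#' @param ridge added to the within-set covariances when they are
#'   rank-deficient (with a warning).
#' @return object of class `cva_result`: `correlations`, `x_vectors`,
#'   `y_vectors` (canonical vectors / weights), `x_loadings`, `y_loadings`
#'   (structure loadings: correlations of each variable with its canonical
#'   variate), `x_variates`, `y_variates`, `chi2`, `df`, `log_p`,
#'   `p_values`, `n`.
#' @export
cva <- function(X, Y, ridge = 1e-8) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (n <= p + q)
    warning("n <= p + q; canonical correlations will be unstable")
  Xs <- standardize(X); Ys <- standardize(Y)
  Sxx <- crossprod(Xs); Syy <- crossprod(Ys); Sxy <- crossprod(Xs, Ys)
  safe_chol <- function(S) {
    tryCatch(chol(S), error = function(e) {
      warning("within-set covariance rank deficient; ridge added")
      chol(S + diag(ridge, nrow(S)))
    })
  }
  Rx <- safe_chol(Sxx); Ry <- safe_chol(Syy)
  # whitened cross-covariance: Rx^-T Sxy Ry^-1
  M <- backsolve(Rx, t(backsolve(Ry, t(Sxy), transpose = TRUE)),
                 transpose = TRUE)
  sv <- svd(M)
  k <- min(p, q)
  r <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  A <- backsolve(Rx, sv$u[, seq_len(k), drop = FALSE])
  B <- backsolve(Ry, sv$v[, seq_len(k), drop = FALSE])
  # sign convention
  for (j in seq_len(k)) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) { A[, j] <- -A[, j]; B[, j] <- -B[, j] }
  }
  U <- Xs %*% A; V <- Ys %*% B
  # structure loadings: correlation of each variable with its canonical
  # variate (sign-stable under collinearity, unlike the weights)
  Lx <- stats::cor(Xs, U)
  Ly <- stats::cor(Ys, V)
  lam <- log(pmax(1 - r^2, .Machine$double.eps))
  coef <- -(n - 1 - (p + q + 1) / 2)
  chi2 <- coef * rev(cumsum(rev(lam)))
  df <- (p - seq_len(k) + 1) * (q - seq_len(k) + 1)
  log_p <- stats::pchisq(chi2, df, lower.tail = FALSE, log.p = TRUE)
  rownames(A) <- colnames(X); rownames(B) <- colnames(Y)
  rownames(Lx) <- colnames(X); rownames(Ly) <- colnames(Y)
  structure(list(correlations = r, x_vectors = A, y_vectors = B,
                 x_loadings = Lx, y_loadings = Ly,
                 x_variates = U, y_variates = V,
                 chi2 = chi2, df = df, log_p = log_p,
                 p_values = exp(log_p), n = n),
            class = "cva_result")
}

#' @export
print.cva_result <- function(x, ...) {
  cat("<cva_result> n =", x$n, "\n")
  print(round(data.frame(r = x$correlations, chi2 = x$chi2, df = x$df,
                         p = x$p_values), 4))
  invisible(x)
}
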