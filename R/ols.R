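#' Ordinary least squares with complete-case handling
#'
#' The workhorse fit behind every association model. Rows with any missing
#' value in the response or the design matrix are dropped; estimates come
#' from the QR decomposition; the coefficient covariance is
#' sigma2 * (X'X)^-1 with sigma2 = RSS / (n - p). Rank deficiency is an
#' error naming the offending column rather than a silently dropped
#' coefficient.
#'
#' @param X numeric design matrix with column names (include the intercept
#'   column explicitly).
#' @param y numeric response.
#' @return list with `coefficients`, `vcov`, `residuals`, `fitted`,
#'   `sigma2`, `n`, `df_residual`, `rows_used` (logical over input rows)
#'   and the `qr` object for reuse in resampling.
#' @export
fit_ols <- function(X, y) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("n (", n, ") must exceed the number of columns (", p, ")")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("rank-deficient design: column '", bad[1], "' is collinear")
  }
  coef <- qr.coef(qx, y)
  fitted <- as.numeric(X %*% coef)
  res <- y - fitted
  sigma2 <- sum(res^2) / (n - p)
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  piv <- qx$pivot
  vcov <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  vcov[piv, piv] <- sigma2 * xtx_inv
  list(coefficients = coef, vcov = vcov, residuals = res, fitted = fitted,
       sigma2 = sigma2, n = n, df_residual = n - p, rows_used = ok, qr = qx)
}

# Precompute what repeated t tests of one coefficient need for a fixed
# design: the thin orthonormal basis Q of col(X) (for residual sums of
# squares), the extractor a with a'y = beta_j, and (X'X)^-1[j, j].
.tfast_prep <- function(X, test_col) {
  stopifnot(test_col %in% colnames(X))
  qx <- qr(X)
  p <- ncol(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("rank-deficient design: column '", bad[1], "' is collinear")
  }
  xtx_inv <- matrix(NA_real_, p, p)
  xtx_inv[qx$pivot, qx$pivot] <- chol2inv(qr.R(qx))
  j <- match(test_col, colnames(X))
  list(Q = qr.Q(qx),
       a = as.numeric(X %*% xtx_inv[, j]),
       var_jj = xtx_inv[j, j],
       n = nrow(X), p = p)
}

# t statistics of the prepared coefficient for many responses (Y is n x B):
# beta = a'Y; RSS = |Y|^2 - |Q'Y|^2; t = beta / sqrt(var_jj * RSS/(n-p)).
.tfast <- function(prep, Y) {
  beta <- as.numeric(crossprod(prep$a, Y))
  rss <- colSums(Y^2) - colSums(crossprod(prep$Q, Y)^2)
  beta / sqrt(prep$var_jj * rss / (prep$n - prep$p))
}
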