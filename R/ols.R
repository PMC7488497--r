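# Core least-squares helper used by every regression path in the package.
# Returns coefficient table, residuals and fit summaries from a QR
# decomposition; aliased columns get NA coefficients.
ols_stats <- function(y, X) {
  stopifnot(nrow(X) == length(y))
  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  piv <- fit$qr$pivot[seq_len(r)]
  R <- fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]
  R[lower.tri(R)] <- 0
  xtx_inv <- chol2inv(R)
  df <- length(y) - r
  rss <- sum(fit$residuals^2)
  sigma2 <- if (df > 0) rss / df else NA_real_
  se <- rep(NA_real_, ncol(X))
  se[piv] <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  names(se) <- colnames(X)
  tss <- sum((y - mean(y))^2)
  list(coef = fit$coefficients, se = se, df = df, rank = r,
       residuals = fit$residuals, rss = rss,
       r_squared = if (tss > 0) 1 - rss / tss else 0)
}

# Drop constant columns from a design-matrix block; returns the reduced
# matrix plus the names of dropped columns.
drop_constant_cols <- function(X, tol = 0) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  keep <- apply(X, 2L, function(col) {
    col <- col[!is.na(col)]
    length(col) > 0L && diff(range(col)) > tol
  })
  list(x = X[, keep, drop = FALSE],
       dropped = colnames(X)[!keep])
}
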