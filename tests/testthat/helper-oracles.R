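# Independent oracles, kept separate from the implementation paths they check.

# Numeric RSS minimizer: BFGS with analytic gradient on unit-scaled
# predictors (a different algorithm and code path from the QR fitter).
ols_oracle <- function(X, y) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  M <- cbind(1, Z)
  rss <- function(b) sum((y - M %*% b)^2)
  grad <- function(b) as.numeric(-2 * crossprod(M, y - M %*% b))
  opt <- stats::optim(rep(0, ncol(M)), rss, grad,
    method = "BFGS", control = list(maxit = 5000, reltol = 1e-16)
  )
  b <- opt$par
  list(
    beta = b[-1] / scl,
    intercept = b[1] - sum(b[-1] * ctr / scl),
    rss = opt$value
  )
}

# Upper-tail F p-value through the incomplete-beta identity.
f_pvalue_ref <- function(f, df1, df2) {
  stats::pbeta(df2 / (df2 + df1 * f), df2 / 2, df1 / 2)
}

# Two-sided t p-value through the incomplete-beta identity.
t_pvalue_ref <- function(t, df) {
  stats::pbeta(df / (df + t^2), df / 2, 0.5)
}
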