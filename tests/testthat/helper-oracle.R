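# Independent oracles used to check the package's estimators.

# Brute-force restricted-likelihood oracle for the one-random-intercept
# model y = X beta + Z b + e, b ~ N(0, sf2 I), e ~ N(0, se2 I).
# Profiles the REML criterion over the variance ratio theta = sf2/se2 on a
# coarse grid, then refines with golden-section search. Dense linear
# algebra only; intended for small balanced instances.
oracle_reml <- function(y, X, family_id, beta_col = 2) {
  fam <- factor(family_id)
  Z <- model.matrix(~ fam - 1)
  n <- length(y); p <- ncol(X)
  ZZt <- tcrossprod(Z)

  profile <- function(theta) {
    V <- diag(n) + theta * ZZt
    W <- solve(V)
    XtWX <- crossprod(X, W %*% X)
    beta <- solve(XtWX, crossprod(X, W %*% y))
    r <- y - X %*% beta
    rss <- drop(crossprod(r, W %*% r))
    se2 <- rss / (n - p)
    ll <- -0.5 * (determinant(V)$modulus + determinant(XtWX)$modulus +
                    (n - p) * log(se2) + (n - p))
    list(ll = as.numeric(ll), beta = drop(beta), se2 = se2, XtWX = XtWX)
  }

  grid <- c(0, exp(seq(log(1e-4), log(1e3), length.out = 300)))
  lls <- vapply(grid, function(t) profile(t)$ll, 0)
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  theta <- if (i == 1) 0 else
    optimize(function(t) profile(t)$ll, c(lo, hi), maximum = TRUE,
             tol = 1e-10)$maximum
  best <- profile(theta)
  se <- sqrt(best$se2 * solve(best$XtWX)[beta_col, beta_col])
  list(beta = unname(best$beta[beta_col]), se = unname(se), theta = theta)
}

# Standard-normal quantile through the inverse error function, independent
# of qnorm (requires pracma).
erfinv_quantile <- function(p) sqrt(2) * pracma::erfinv(2 * p - 1)

# Blom scores computed from first principles with the erfinv-based quantile.
oracle_blom <- function(x) {
  r <- rank(x, ties.method = "average")
  erfinv_quantile((r - 0.375) / (length(x) + 0.25))
}
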