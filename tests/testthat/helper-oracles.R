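# Independent oracles used to cross-check the package's numerics. These
# deliberately use naive dense-matrix formulas (O(n^3) per evaluation)
# rather than the package's computational routes.

# Textbook restricted log-likelihood of y ~ N(X b, Va*K + Ve*I), dense.
dense_restricted_loglik <- function(y, X, K, Va, Ve) {
  n <- length(y)
  p <- ncol(X)
  V <- Va * K + Ve * diag(n)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  b <- solve(XVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  quad <- drop(t(r) %*% Vi %*% r)
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
            determinant(V, logarithm = TRUE)$modulus +
            determinant(XVX, logarithm = TRUE)$modulus -
            determinant(t(X) %*% X, logarithm = TRUE)$modulus +
            quad))
}

# Henderson mixed-model-equation solution for u in
# y = X b + Z u + e, u ~ N(0, Va K), e ~ N(0, Ve I).
henderson_blup <- function(y, X, Z, K, Va, Ve) {
  lambda_inv <- Ve / Va
  Ki <- solve(K)
  lhs <- rbind(
    cbind(crossprod(X), crossprod(X, Z)),
    cbind(crossprod(Z, X), crossprod(Z) + lambda_inv * Ki)
  )
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(lhs, rhs)
  sol[(ncol(X) + 1):length(sol)]
}

# Brute-force Benjamini-Hochberg step-up rejections.
brute_force_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) {
    if (ps[i] <= i * q / m) k <- i
  }
  rej <- logical(m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# Hudson-style FST estimator between two subpopulation allele-frequency
# vectors with sample sizes n1, n2 (haploid allele counts).
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Small cached simulation shared by several test files.
small_sim <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- simulate_met(sim_config(
        n_entries = 80, n_snps = 600, n_locations = 8, n_years = 6,
        entries_per_year_range = c(16, 40),
        locations_per_year_range = c(4, 8), seed = 42
      ))
    }
    memo
  }
})
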