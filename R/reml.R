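# Single-random-effect REML engine.
#
# Model: y ~ N(X beta, Va * Z K Z' + Ve * I). Two computational routes,
# both exact:
#  * entry-level (Z = I): one spectral decomposition of K diagonalizes the
#    covariance for every variance ratio lambda = Va/Ve;
#  * record-level (Z = incidence matrix mapping records to entries): all
#    likelihood pieces reduce to entry-dimension sufficient statistics via
#    the Woodbury identity, so each lambda evaluation costs O(m^3) in the
#    number of entries, not records.
# The restricted likelihood is profiled over Ve and maximized over lambda
# on a log grid followed by Brent refinement.

#' Fit a kinship mixed model by REML
#'
#' Maximizes the restricted likelihood of
#' `y ~ N(X beta, Va * Z K Z' + Ve * I)` over the variance ratio
#' `lambda = Va/Ve` by a one-dimensional search (log-spaced grid plus
#' Brent refinement), with the `Va = 0` boundary checked explicitly.
#'
#' @param y Response vector (entry-level values, or record-level when `Z`
#'   is supplied).
#' @param X Fixed-effect design matrix (full column rank; include the
#'   intercept).
#' @param K A `kinship_matrix` (or plain symmetric matrix) over entries.
#' @param Z Optional records x entries incidence matrix; `NULL` means
#'   `y` is already entry-level (`Z = I`).
#' @param lambda_range Search range for `Va/Ve`.
#' @param n_grid Number of log-spaced grid points.
#' @return A `reml_fit`: `Va`, `Ve`, `lambda`, `beta`,
#'   `log_restricted_likelihood`, `ml_loglik`, `bic`
#'   (`-2 * ml_loglik + p * log(n)`), `n`, `p`, plus solver internals used
#'   by [fit_blup()].
#' @export
reml_fit <- function(y, X, K, Z = NULL,
                     lambda_range = c(1e-5, 1e5), n_grid = 41) {
  Km <- kinship_values(K)
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) {
    stop_sparsemet("`y` and `X` have different numbers of rows.",
                   "sparsemet_dimension_error")
  }
  p <- ncol(X)
  if (qr(X)$rank < p) {
    stop_sparsemet("`X` is rank deficient; drop aliased columns first.",
                   "sparsemet_rank_error")
  }
  if (n <= p) {
    stop_sparsemet("Need more observations than fixed-effect columns.",
                   "sparsemet_dimension_error")
  }

  if (is.null(Z)) {
    if (nrow(Km) != n) {
      stop_sparsemet("`K` does not conform to `y`.", "sparsemet_dimension_error")
    }
    ev <- kinship_eigen(K)
    ctx <- list(kind = "spectral", d = pmax(ev$values, 0),
                yt = as.numeric(crossprod(ev$vectors, y)),
                Xt = crossprod(ev$vectors, X),
                U = ev$vectors, n = n, p = p,
                ldXX = 2 * sum(log(abs(diag(qr.R(qr(X)))))))
  } else {
    Z <- as.matrix(Z)
    if (nrow(Z) != n || ncol(Z) != nrow(Km)) {
      stop_sparsemet("`Z` does not conform to `y` and `K`.",
                     "sparsemet_dimension_error")
    }
    ctx <- list(kind = "woodbury", K = Km, C = crossprod(Z),
                Zy = as.numeric(crossprod(Z, y)), ZX = crossprod(Z, X),
                XX = crossprod(X), Xy = as.numeric(crossprod(X, y)),
                yy = sum(y^2), n = n, p = p,
                ldXX = 2 * sum(log(abs(diag(qr.R(qr(X)))))))
  }

  obj <- function(log_lambda) profiled_reml(exp(log_lambda), ctx)$loglik
  grid <- seq(log(lambda_range[1]), log(lambda_range[2]), length.out = n_grid)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(n_grid, i + 1)]
  opt <- optimize(obj, interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
  lambda <- exp(opt$maximum)
  best <- profiled_reml(lambda, ctx)

  # Va = 0 boundary (pure-noise likelihood)
  null0 <- profiled_reml(0, ctx)
  if (null0$loglik >= best$loglik) {
    lambda <- 0
    best <- null0
  }

  Ve <- best$Ve
  Va <- lambda * Ve
  ml <- ml_loglik_at(lambda, ctx)
  fit <- structure(
    list(Va = Va, Ve = Ve, lambda = lambda,
         beta = best$beta,
         log_restricted_likelihood = best$loglik,
         ml_loglik = ml,
         bic = -2 * ml + p * log(n),
         n = n, p = p, ctx = ctx),
    class = "reml_fit"
  )
  fit
}

kinship_values <- function(K) {
  if (inherits(K, "kinship_matrix")) K$values else as.matrix(K)
}
kinship_eigen <- function(K) {
  if (inherits(K, "kinship_matrix")) K$eigen
  else eigen(as.matrix(K), symmetric = TRUE)
}

# Profiled restricted log-likelihood at a fixed variance ratio.
# Returns the GLS beta and the profiled Ve as by-products.
profiled_reml <- function(lambda, ctx) {
  n <- ctx$n; p <- ctx$p
  if (ctx$kind == "spectral") {
    w <- lambda * ctx$d + 1
    Xw <- ctx$Xt / w
    A <- crossprod(ctx$Xt, Xw)            # X' W^-1 X
    b <- solve(A, crossprod(Xw, ctx$yt))
    r <- ctx$yt - ctx$Xt %*% b
    quad <- sum(r^2 / w)
    ldV <- sum(log(w))
    ldA <- determinant(A, logarithm = TRUE)$modulus
  } else {
    pieces <- woodbury_pieces(lambda, ctx)
    A <- pieces$XVX
    b <- solve(A, pieces$XVy)
    quad <- pieces$yVy - 2 * sum(b * pieces$XVy) +
      sum(b * (A %*% b))
    ldV <- pieces$ldV
    ldA <- determinant(A, logarithm = TRUE)$modulus
  }
  Ve <- quad / (n - p)
  loglik <- -0.5 * ((n - p) * log(2 * pi * Ve) + (n - p) +
                      ldV + ldA - ctx$ldXX)
  list(loglik = as.numeric(loglik), Ve = Ve, beta = as.numeric(b))
}

# Maximum (unrestricted) log-likelihood at the same variance ratio,
# used for BIC-based covariate selection where REML values are not
# comparable across fixed-effect sets.
ml_loglik_at <- function(lambda, ctx) {
  n <- ctx$n
  if (ctx$kind == "spectral") {
    w <- lambda * ctx$d + 1
    Xw <- ctx$Xt / w
    A <- crossprod(ctx$Xt, Xw)
    b <- solve(A, crossprod(Xw, ctx$yt))
    r <- ctx$yt - ctx$Xt %*% b
    quad <- sum(r^2 / w)
    ldV <- sum(log(w))
  } else {
    pieces <- woodbury_pieces(lambda, ctx)
    b <- solve(pieces$XVX, pieces$XVy)
    quad <- pieces$yVy - 2 * sum(b * pieces$XVy) +
      sum(b * (pieces$XVX %*% b))
    ldV <- pieces$ldV
  }
  Ve <- quad / n
  as.numeric(-0.5 * (n * log(2 * pi * Ve) + n + ldV))
}

# Entry-dimension sufficient statistics for V*^-1 = (I + lambda Z K Z')^-1
# via (I + lambda Z K Z')^-1 = I - lambda Z (I + lambda K Z'Z)^-1 K Z'.
woodbury_pieces <- function(lambda, ctx) {
  m <- nrow(ctx$K)
  if (lambda == 0) {
    return(list(XVX = ctx$XX, XVy = ctx$Xy, yVy = ctx$yy, ldV = 0,
                MiK = matrix(0, m, m)))
  }
  M <- diag(m) + lambda * ctx$K %*% ctx$C
  MiK <- solve(M, ctx$K)                  # (K^-1/lambda ... ) stable form
  ldV <- as.numeric(determinant(M, logarithm = TRUE)$modulus)
  XVX <- ctx$XX - lambda * crossprod(ctx$ZX, MiK %*% ctx$ZX)
  XVy <- ctx$Xy - lambda * as.numeric(crossprod(ctx$ZX, MiK %*% ctx$Zy))
  yVy <- ctx$yy - lambda * sum(ctx$Zy * (MiK %*% ctx$Zy))
  list(XVX = XVX, XVy = XVy, yVy = yVy, ldV = ldV, MiK = MiK)
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the exact (unprofiled) restricted log-likelihood of
#' `y ~ N(X beta, Va * K + Ve * I)` using the spectral route; useful for
#' checking the solver against independent dense-matrix computations.
#'
#' @inheritParams reml_fit
#' @param Va,Ve Variance components (`Ve > 0`).
#' @return The restricted log-likelihood (includes the `+ 0.5 log|X'X|`
#'   convention so values are comparable with textbook dense formulas).
#' @export
reml_loglik <- function(y, X, K, Va, Ve) {
  ev <- kinship_eigen(K)
  y <- as.numeric(y); X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  d <- pmax(ev$values, 0)
  yt <- as.numeric(crossprod(ev$vectors, y))
  Xt <- crossprod(ev$vectors, X)
  w <- Va * d + Ve
  Xw <- Xt / w
  A <- crossprod(Xt, Xw)
  b <- solve(A, crossprod(Xw, yt))
  r <- yt - Xt %*% b
  quad <- sum(r^2 / w)
  ldXX <- 2 * sum(log(abs(diag(qr.R(qr(X))))))
  as.numeric(-0.5 * ((n - p) * log(2 * pi) + sum(log(w)) +
                       determinant(A, logarithm = TRUE)$modulus -
                       ldXX + quad))
}

#' Narrow-sense heritability from variance components
#'
#' `h2 = Va / (Va + Ve)`: the additive genetic variance as a fraction of
#' the total of additive and residual variance.
#'
#' @param Va Additive genetic variance (>= 0).
#' @param Ve Residual variance (>= 0).
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' narrow_sense_h2(53173, 222409)   # 0.193
#' narrow_sense_h2(2340, 1076)      # 0.685
narrow_sense_h2 <- function(Va, Ve) {
  if (any(Va < 0) || any(Ve < 0)) {
    stop_sparsemet("Variance components must be non-negative.",
                   "sparsemet_parameter_error")
  }
  if (any(Va + Ve == 0)) {
    stop_sparsemet("h2 is undefined when Va + Ve = 0.",
                   "sparsemet_degenerate_error")
  }
  Va / (Va + Ve)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> Va = ", signif(x$Va, 4), ", Ve = ", signif(x$Ve, 4),
      " (h2 = ", sprintf("%.3f", narrow_sense_h2(x$Va + 1e-300, x$Ve)),
      "), logRL = ", sprintf("%.3f", x$log_restricted_likelihood),
      ", n = ", x$n, ", p = ", x$p, "\n", sep = "")
  invisible(x)
}

#' @rdname tidiers
#' @method tidy reml_fit
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble(term = c("Va", "Ve", paste0("beta", seq_along(x$beta))),
         estimate = c(x$Va, x$Ve, x$beta))
}

#' @rdname tidiers
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble(Va = x$Va, Ve = x$Ve,
         h2 = x$Va / (x$Va + x$Ve),
         log_restricted_likelihood = x$log_restricted_likelihood,
         bic = x$bic, n = x$n, p = x$p)
}
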