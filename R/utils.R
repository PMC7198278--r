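# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All exported stochastic functions route their randomness
# through this, so same-seed calls are byte-identical.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed; keeps values inside 32-bit range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

stop_sparsemet <- function(msg, class) {
  abort(msg, class = c(class, "sparsemet_error"))
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop_sparsemet(
      sprintf("`%s` must be a number in %s%s, %s%s.", name,
              if (lo_open) "(" else "[", format(lo), format(hi),
              if (hi_open) ")" else "]"),
      "sparsemet_parameter_error"
    )
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min &&
    x == round(x)
  if (!ok) {
    stop_sparsemet(sprintf("`%s` must be an integer >= %d.", name, min),
                   "sparsemet_parameter_error")
  }
  invisible(as.integer(x))
}

# Symmetrize and clamp tiny negative eigenvalues so a matrix is PSD.
make_psd <- function(m, tol = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < -tol) {
    vals <- pmax(e$values, 0)
    m <- e$vectors %*% (vals * t(e$vectors))
    m <- (m + t(m)) / 2
  }
  m
}

# log N(x; 0, V) for a vector x and covariance V, via Cholesky with a
# small ridge fallback for semi-definite V.
ldmvnorm0 <- function(x, V) {
  d <- length(x)
  ch <- tryCatch(chol(V), error = function(e) chol(V + diag(1e-10, d)))
  z <- backsolve(ch, x, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
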