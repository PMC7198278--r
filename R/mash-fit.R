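# Covariance-mixture prior for SNP effects across phenotypes:
# b_j ~ pi_0 delta_0 + sum_{k,l} pi_{k,l} N(0, omega_l U_k),
# observed bhat_j ~ N(b_j, S_j) with S_j diagonal from the per-phenotype
# standard errors. Mixture weights are fitted by EM on a random SNP set;
# component covariances are fixed (canonical + data-driven), as in
# standard multivariate adaptive shrinkage practice.

#' Learn covariance components from strong effects
#'
#' Returns the canonical components (identity, one singleton matrix per
#' phenotype, the all-ones equal-effects matrix) plus data-driven
#' components: the empirical covariance of the strong standardized effects
#' and its rank-`rank` truncated eigen-reconstruction. Every component is
#' normalized to unit maximum diagonal and projected to PSD.
#'
#' @param bhat Strong-set SNP x phenotype standardized effects.
#' @param shat Matching standard errors (unused by the PCA truncation but
#'   kept for interface symmetry).
#' @param rank Rank of the truncated eigen-reconstruction.
#' @return Named list of phenotype x phenotype PSD matrices.
#' @export
learn_covariances <- function(bhat, shat = NULL, rank = 5) {
  bhat <- as.matrix(bhat)
  t_ <- ncol(bhat)
  phen <- colnames(bhat) %||% paste0("P", seq_len(t_))
  norm1 <- function(m) {
    m <- make_psd(m)
    d <- max(diag(m))
    if (d > 0) m / d else m
  }
  comps <- list(identity = diag(t_))
  for (i in seq_len(t_)) {
    m <- matrix(0, t_, t_)
    m[i, i] <- 1
    comps[[paste0("singleton_", phen[i])]] <- m
  }
  comps$equal_effects <- matrix(1, t_, t_)
  if (nrow(bhat) >= t_) {
    emp <- crossprod(bhat) / nrow(bhat)
    comps$empirical <- norm1(emp)
    r <- min(rank, t_)
    e <- eigen(emp, symmetric = TRUE)
    vals <- pmax(e$values, 0)
    vals[-seq_len(r)] <- 0
    comps$pca <- norm1(e$vectors %*% (vals * t(e$vectors)))
  } else {
    warn("Fewer strong SNPs than phenotypes; data-driven components skipped.")
  }
  lapply(comps, function(m) {
    dimnames(m) <- list(phen, phen)
    m
  })
}

#' Scale grid for the covariance mixture
#'
#' Geometric grid, sqrt(2)-spaced, spanning
#' `[(min shat)^2 / 4, 4 * max(bhat)^2]`: brackets effects much smaller
#' than the measurement noise up to several times the largest observed
#' effect.
#'
#' @param bhat,shat Effect and SE matrices (standardized scale).
#' @return Increasing vector of prior variances.
#' @export
omega_grid <- function(bhat, shat) {
  lo <- (min(shat[shat > 0], na.rm = TRUE))^2 / 4
  hi <- 4 * max(bhat^2, na.rm = TRUE)
  if (!is.finite(lo) || lo <= 0) lo <- 1e-6
  if (hi <= lo) hi <- lo * 2
  n <- ceiling(log(hi / lo) / log(2) * 2) + 1
  lo * 2^(seq(0, (n - 1) / 2, by = 0.5))
}

# Log-likelihood matrix: rows = SNPs, columns = null then each
# (component, scale) pair.
mixture_loglik_matrix <- function(bhat, shat, components, scales) {
  j_n <- nrow(bhat)
  t_ <- ncol(bhat)
  grid <- expand.grid(k = seq_along(components), l = seq_along(scales))
  n_c <- nrow(grid)
  L <- matrix(0, j_n, n_c + 1)
  colnames(L) <- c("null", paste0(names(components)[grid$k],
                                  ":omega", signif(scales[grid$l], 3)))
  s2 <- shat^2
  # null: independent normals with the observation SEs
  L[, 1] <- rowSums(dnorm(bhat, 0, shat, log = TRUE))
  for (c in seq_len(n_c)) {
    V <- scales[grid$l[c]] * components[[grid$k[c]]]
    for (j in seq_len(j_n)) {
      L[j, c + 1] <- ldmvnorm0(bhat[j, ], V + diag(s2[j, ], t_))
    }
  }
  attr(L, "grid") <- grid
  L
}

#' Fit the covariance-mixture weights by EM
#'
#' Maximizes `sum_j log sum_c pi_c N(bhat_j; 0, S_j + omega_l U_k)` over
#' the mixture weights `pi` (component covariances fixed), including a
#' point-mass null component. The log-likelihood is non-decreasing at
#' every iteration.
#'
#' @param bhat,shat Random-set SNP x phenotype effects and SEs
#'   (standardized scale).
#' @param components Named list of PSD covariance matrices (see
#'   [learn_covariances()]).
#' @param scales Prior-variance grid (see [omega_grid()]).
#' @param max_iter,tol EM stopping rule (log-likelihood gain below `tol`).
#' @return A `mixture_model`: `components`, `scales`, `weights` (named,
#'   first element `null`), `grid`, `loglik_trace`, `converged`.
#' @export
fit_mixture_em <- function(bhat, shat, components, scales = NULL,
                           max_iter = 500, tol = 1e-6) {
  bhat <- as.matrix(bhat); shat <- as.matrix(shat)
  for (m in components) {
    ev <- min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      stop_sparsemet("Covariance components must be PSD.",
                     "sparsemet_parameter_error")
    }
  }
  if (any(!is.finite(shat)) || any(shat <= 0)) {
    stop_sparsemet("`shat` must be positive and finite.",
                   "sparsemet_parameter_error")
  }
  scales <- scales %||% omega_grid(bhat, shat)
  if (any(scales <= 0)) {
    stop_sparsemet("Scales must be positive.", "sparsemet_parameter_error")
  }
  L <- mixture_loglik_matrix(bhat, shat, components, scales)
  n_c <- ncol(L)
  lmax <- apply(L, 1, max)
  E <- exp(L - lmax)  # rescaled likelihoods, row-wise stable

  pi_ <- rep(1 / n_c, n_c)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    num <- E * rep(pi_, each = nrow(E))
    rs <- rowSums(num)
    ll <- sum(log(rs) + lmax)
    trace <- c(trace, ll)
    if (ll - ll_old < tol && it > 1) { converged <- TRUE; break }
    ll_old <- ll
    gam <- num / rs
    pi_ <- colMeans(gam)
  }
  structure(
    list(components = components, scales = scales,
         weights = setNames(pi_, colnames(L)),
         grid = attr(L, "grid"),
         loglik_trace = trace, converged = converged),
    class = "mixture_model"
  )
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("<mixture_model> ", length(x$components), " components x ",
      length(x$scales), " scales (+ null); null weight ",
      sprintf("%.3f", x$weights[1]), "; ", length(x$loglik_trace),
      " EM iterations\n", sep = "")
  invisible(x)
}

#' @rdname tidiers
#' @method tidy mixture_model
#' @export
tidy.mixture_model <- function(x, ...) {
  grid <- x$grid
  tibble(
    component = names(x$weights),
    covariance = c("null", names(x$components)[grid$k]),
    omega = c(0, x$scales[grid$l]),
    weight = unname(x$weights)
  )
}

#' @rdname tidiers
#' @method glance mixture_model
#' @export
glance.mixture_model <- function(x, ...) {
  tibble(null_weight = unname(x$weights[1]),
         n_components = length(x$components),
         n_scales = length(x$scales),
         loglik = x$loglik_trace[length(x$loglik_trace)],
         iterations = length(x$loglik_trace),
         converged = x$converged)
}
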