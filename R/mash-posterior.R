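# Posterior summaries under the fitted covariance mixture: shrunken
# effects, local false sign rates, and per-SNP Bayes factors against the
# point-mass null.

#' Posterior effects and local false sign rates
#'
#' For each SNP, forms the mixture posterior of the true effect vector
#' given `bhat_j ~ N(b_j, S_j)` and the fitted prior. Per component
#' `V = omega U`: posterior covariance `V - V (V + S_j)^-1 V` and mean
#' `V (V + S_j)^-1 bhat_j` (no inverse of a possibly singular `V` is
#' taken). The local false sign rate per phenotype is
#' `min(P(b <= 0), P(b >= 0))` under the full mixture, including the null
#' point mass (which contributes to both sides).
#'
#' @param panel An `effect_panel` (typically the strong set, see
#'   [panel_subset()]).
#' @param model A `mixture_model` from [fit_mixture_em()].
#' @return A `mash_posterior`: matrices `post_mean`, `post_sd`, `lfsr`
#'   (SNP x phenotype), vector `null_prob` (posterior weight on the exact
#'   null per SNP), plus `snp_ids`, `phenotypes`.
#' @export
compute_posteriors <- function(panel, model) {
  bhat <- panel$bhat
  shat <- panel$shat
  j_n <- nrow(bhat)
  t_ <- ncol(bhat)
  L <- mixture_loglik_matrix(bhat, shat, model$components, model$scales)
  grid <- attr(L, "grid")
  n_c <- ncol(L)
  # responsibilities
  lpost <- sweep(L, 2, log(pmax(model$weights, 1e-300)), "+")
  lmax <- apply(lpost, 1, max)
  gam <- exp(lpost - lmax)
  gam <- gam / rowSums(gam)

  post_mean <- matrix(0, j_n, t_, dimnames = dimnames(bhat))
  post_m2 <- post_mean     # second moment E[b^2]
  p_neg <- post_mean       # P(b < 0)
  p_pos <- post_mean       # P(b > 0)
  # null component: b = 0 exactly, contributes to neither strict side
  for (c in seq_len(n_c - 1)) {
    V <- model$scales[grid$l[c]] * model$components[[grid$k[c]]]
    g_c <- gam[, c + 1]
    if (max(g_c) < 1e-12) next
    for (j in seq_len(j_n)) {
      if (g_c[j] < 1e-12) next
      A <- V + diag(shat[j, ]^2, t_)
      W <- V %*% solve(A)
      mu <- drop(W %*% bhat[j, ])
      Sg <- V - W %*% V
      sdv <- sqrt(pmax(diag(Sg), 0))
      post_mean[j, ] <- post_mean[j, ] + g_c[j] * mu
      post_m2[j, ] <- post_m2[j, ] + g_c[j] * (mu^2 + sdv^2)
      zero_sd <- sdv < 1e-12
      pn <- ifelse(zero_sd, as.numeric(mu < 0), pnorm(0, mu, sdv))
      pp <- ifelse(zero_sd, as.numeric(mu > 0),
                   pnorm(0, mu, sdv, lower.tail = FALSE))
      p_neg[j, ] <- p_neg[j, ] + g_c[j] * pn
      p_pos[j, ] <- p_pos[j, ] + g_c[j] * pp
    }
  }
  post_sd <- sqrt(pmax(post_m2 - post_mean^2, 0))
  null_prob <- gam[, 1]
  # lfsr = min over sign of P(wrong or zero sign) = 1 - max(P(b>0), P(b<0))
  lfsr <- 1 - pmax(p_neg, p_pos)
  lfsr <- pmin(pmax(lfsr, 0), 1)
  structure(
    list(post_mean = post_mean, post_sd = post_sd, lfsr = lfsr,
         null_prob = unname(null_prob),
         snp_ids = panel$snp_ids, phenotypes = panel$phenotypes),
    class = "mash_posterior"
  )
}

#' @export
print.mash_posterior <- function(x, ...) {
  cat("<mash_posterior> ", length(x$snp_ids), " SNPs x ",
      length(x$phenotypes), " phenotypes; ",
      sum(apply(x$lfsr, 1, min) <= 0.05),
      " SNPs with lfsr <= 0.05 in some phenotype\n", sep = "")
  invisible(x)
}

#' @rdname tidiers
#' @method tidy mash_posterior
#' @export
tidy.mash_posterior <- function(x, ...) {
  tibble(
    snp = rep(x$snp_ids, times = length(x$phenotypes)),
    phenotype = rep(x$phenotypes, each = length(x$snp_ids)),
    post_mean = as.vector(x$post_mean),
    post_sd = as.vector(x$post_sd),
    lfsr = as.vector(x$lfsr)
  )
}

#' Per-SNP Bayes factor against the point-mass null
#'
#' `BF_j = sum_{c != null} w_c L_jc / L_j,null`, with the fitted non-null
#' weights renormalized to sum to one. Following Jeffreys' scale, evidence
#' is flagged "decisive" above `10^2`.
#'
#' @param panel An `effect_panel`.
#' @param model A `mixture_model` whose first weight is the null point
#'   mass.
#' @param decisive_threshold Bayes-factor cutoff for the `decisive` flag.
#' @return Tibble with `snp`, `log10_bf`, `bf`, `decisive`.
#' @export
bayes_factor <- function(panel, model, decisive_threshold = 100) {
  if (names(model$weights)[1] != "null") {
    stop_sparsemet("The mixture model has no null component.",
                   "sparsemet_parameter_error")
  }
  w <- model$weights[-1]
  if (sum(w) <= 0) {
    stop_sparsemet("All non-null mixture weights are zero.",
                   "sparsemet_degenerate_error")
  }
  w <- w / sum(w)
  L <- mixture_loglik_matrix(panel$bhat, panel$shat,
                             model$components, model$scales)
  l_null <- L[, 1]
  l_alt <- L[, -1, drop = FALSE]
  m <- apply(l_alt, 1, max)
  log_alt <- m + log(rowSums(exp(l_alt - m) * rep(w, each = nrow(l_alt))))
  log10_bf <- unname((log_alt - l_null) / log(10))
  tibble(
    snp = panel$snp_ids,
    log10_bf = log10_bf,
    bf = 10^log10_bf,
    decisive = log10_bf > log10(decisive_threshold)
  )
}

#' Pairwise sharing of significant effects
#'
#' For each phenotype pair, restricts to SNPs significant
#' (`lfsr <= lfsr_max`) in at least one of the two phenotypes and reports
#' the fraction whose posterior means have the same sign and magnitudes
#' within a factor `magnitude_factor` of each other.
#'
#' @param posterior A `mash_posterior`.
#' @param lfsr_max Significance cutoff.
#' @param magnitude_factor Allowed magnitude ratio for "shared".
#' @return Symmetric phenotype x phenotype matrix with unit diagonal; `NA`
#'   where no SNP is significant in either phenotype.
#' @export
pairwise_sharing <- function(posterior, lfsr_max = 0.05,
                             magnitude_factor = 2) {
  pm <- posterior$post_mean
  lf <- posterior$lfsr
  t_ <- ncol(pm)
  out <- diag(1, t_)
  dimnames(out) <- list(posterior$phenotypes, posterior$phenotypes)
  for (a in seq_len(t_ - 1)) {
    for (b in (a + 1):t_) {
      sig <- which(lf[, a] <= lfsr_max | lf[, b] <= lfsr_max)
      if (length(sig) == 0) {
        out[a, b] <- out[b, a] <- NA_real_
        next
      }
      x <- pm[sig, a]; y <- pm[sig, b]
      ratio <- abs(x) / abs(y)
      shared <- sign(x) == sign(y) & sign(x) != 0 &
        ratio <= magnitude_factor & ratio >= 1 / magnitude_factor
      out[a, b] <- out[b, a] <- mean(shared)
    }
  }
  out
}

#' Full multivariate shrinkage analysis
#'
#' Convenience wrapper over the shrinkage stage: covariance learning on
#' the strong set, weight fitting by EM on the random set, posteriors and
#' Bayes factors on the strong set.
#'
#' @param panel A full `effect_panel` from [build_effect_panel()].
#' @param random_ids,strong_ids SNP-id vectors (see [build_snp_sets()]).
#' @param rank Rank passed to [learn_covariances()].
#' @param ... Passed to [fit_mixture_em()].
#' @return A `mash_result`: `model`, `posterior`, `bayes_factors`,
#'   `sharing`.
#' @export
run_mash <- function(panel, random_ids, strong_ids, rank = 5, ...) {
  strong <- panel_subset(panel, strong_ids)
  random <- panel_subset(panel, random_ids)
  comps <- learn_covariances(strong$bhat, strong$shat, rank = rank)
  model <- fit_mixture_em(random$bhat, random$shat, comps, ...)
  posterior <- compute_posteriors(strong, model)
  structure(
    list(model = model,
         posterior = posterior,
         bayes_factors = bayes_factor(strong, model),
         sharing = pairwise_sharing(posterior)),
    class = "mash_result"
  )
}

#' @export
print.mash_result <- function(x, ...) {
  print(x$model)
  print(x$posterior)
  cat(sum(x$bayes_factors$decisive), " SNPs with decisive Bayes factors\n",
      sep = "")
  invisible(x)
}
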