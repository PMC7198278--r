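# Bridge from per-phenotype association scans to the multivariate
# shrinkage stage: effect standardization, the Hedges' G standard-error
# fallback, and the random / strong SNP-set construction.

#' Standardize effects for multivariate shrinkage
#'
#' Centers a phenotype's effect column to mean zero and divides by the
#' maximum absolute centered value, so effects fall in `[-1, 1]`; standard
#' errors are divided by the same factor, so z-scores are unchanged. The
#' scale factor is recorded for back-transformation.
#'
#' @param beta Effect estimates for one phenotype (across SNPs).
#' @param se Matching standard errors.
#' @return List with `beta`, `se`, `center`, `scale`.
#' @export
#' @examples
#' standardize_effects(c(1, 2, 3), c(1, 1, 1))$beta  # -1 0 1
standardize_effects <- function(beta, se) {
  ok <- !is.na(beta)
  if (sum(ok) < 2 || sd(beta[ok]) == 0) {
    stop_sparsemet("Effects are constant or too few; cannot standardize.",
                   "sparsemet_degenerate_error")
  }
  ctr <- mean(beta[ok])
  b <- beta - ctr
  sc <- max(abs(b), na.rm = TRUE)
  list(beta = b / sc, se = se / sc, center = ctr, scale = sc)
}

#' Hedges' G standard error
#'
#' Standard error of the bias-corrected standardized mean difference
#' between two allele groups:
#' `sqrt((n0 + n1)/(n0 * n1) + g^2 / (2 (n0 + n1)))`. Used as the
#' per-phenotype SE fallback when the primary scan yields SEs for 95% or
#' fewer of the SNPs.
#'
#' @param n0,n1 Group sizes (both >= 2).
#' @param g Bias-corrected standardized mean difference (see
#'   [hedges_g()]).
#' @return The standard error.
#' @export
#' @examples
#' hedges_g_se(10, 10, 0)  # sqrt(0.2)
hedges_g_se <- function(n0, n1, g) {
  if (any(n0 < 2) || any(n1 < 2)) {
    stop_sparsemet("Both groups need at least 2 observations.",
                   "sparsemet_parameter_error")
  }
  sqrt((n0 + n1) / (n0 * n1) + g^2 / (2 * (n0 + n1)))
}

#' Hedges' G standardized mean difference
#'
#' Cohen's d corrected by `J(df) = 1 - 3 / (4 df - 1)`, `df = n0 + n1 - 2`.
#'
#' @param mean0,mean1 Group means.
#' @param sd0,sd1 Group standard deviations.
#' @param n0,n1 Group sizes.
#' @return The bias-corrected standardized mean difference.
#' @export
hedges_g <- function(mean0, mean1, sd0, sd1, n0, n1) {
  df <- n0 + n1 - 2
  s_pool <- sqrt(((n0 - 1) * sd0^2 + (n1 - 1) * sd1^2) / df)
  d <- (mean1 - mean0) / s_pool
  d * (1 - 3 / (4 * df - 1))
}

#' Assemble a SNP x phenotype effect panel
#'
#' Joins per-phenotype association scans on their shared SNP universe and
#' standardizes each phenotype with [standardize_effects()]. Phenotypes
#' whose scan produced standard errors for 95% or fewer of the SNPs get the
#' Hedges' G fallback SE computed from allele-group sizes.
#'
#' @param scans Named list of association tibbles from [mlm_scan()], all on
#'   the same SNP universe.
#' @param geno The `genotype_matrix` the scans used (for allele counts in
#'   the SE fallback).
#' @return An `effect_panel`: `bhat` and `shat` (SNP x phenotype matrices,
#'   standardized), `snp_ids`, `phenotypes`, `scales` (per-phenotype
#'   center/scale records), `se_fallback` (logical per phenotype).
#' @export
build_effect_panel <- function(scans, geno = NULL) {
  stopifnot(length(scans) >= 1, !is.null(names(scans)))
  snps <- scans[[1]]$snp
  for (s in scans) {
    if (!identical(s$snp, snps)) {
      stop_sparsemet("All scans must share one SNP universe (same order).",
                     "sparsemet_id_error")
    }
  }
  nph <- length(scans)
  bhat <- matrix(NA_real_, length(snps), nph,
                 dimnames = list(snps, names(scans)))
  shat <- bhat
  fallback <- logical(nph)
  for (j in seq_len(nph)) {
    sc <- scans[[j]]
    se_j <- sc$se
    ok_rate <- mean(!is.na(se_j) & se_j > 0)
    if (ok_rate <= 0.95) {
      fallback[j] <- TRUE
      if (is.null(geno)) {
        stop_sparsemet("SE fallback needs the genotype matrix.",
                       "sparsemet_parameter_error")
      }
      dos <- round(mean_impute_dosages(geno$dosages))
      n1 <- colSums(dos >= 1)
      n0 <- nrow(dos) - n1
      n0 <- pmax(n0, 2); n1 <- pmax(n1, 2)
      g_std <- sc$beta / stats::sd(sc$beta, na.rm = TRUE)
      se_j <- hedges_g_se(n0, n1, g_std)
    }
    std <- standardize_effects(sc$beta, se_j)
    bhat[, j] <- std$beta
    shat[, j] <- std$se
  }
  shat[!is.finite(shat) | shat <= 0] <- max(shat[is.finite(shat) & shat > 0])
  structure(
    list(bhat = bhat, shat = shat, snp_ids = snps,
         phenotypes = names(scans),
         scales = lapply(scans, function(s) NULL),
         se_fallback = setNames(fallback, names(scans))),
    class = "effect_panel"
  )
}

#' @export
print.effect_panel <- function(x, ...) {
  cat("<effect_panel> ", nrow(x$bhat), " SNPs x ", ncol(x$bhat),
      " phenotypes\n", sep = "")
  invisible(x)
}

#' Random and strong SNP sets for shrinkage
#'
#' The random set (used to fit the mixture prior) is drawn without
#' replacement from the LD-pruned SNP universe; the strong set (on which
#' posteriors are reported) is the union, over phenotypes, of each
#' phenotype's `n_strong_per_trait` smallest-p SNPs.
#'
#' @param scans Named list of association tibbles on one SNP universe.
#' @param geno The shared `genotype_matrix`.
#' @param n_random Random-set size (capped at the pruned universe with a
#'   warning).
#' @param n_strong_per_trait Top SNPs per phenotype for the strong set.
#' @param r2_max,window_bp LD-pruning parameters for the random set.
#' @param seed Seed for the random draw.
#' @return List with character vectors `random` and `strong` (SNP ids).
#' @export
build_snp_sets <- function(scans, geno, n_random = 5000,
                           n_strong_per_trait = 400,
                           r2_max = 0.2, window_bp = 50000, seed = 1) {
  pruned <- ld_prune(geno, r2_max = r2_max, window_bp = window_bp)
  universe <- pruned$snp_map$snp
  if (n_random > length(universe)) {
    warn(sprintf("n_random (%d) exceeds the pruned universe (%d); capped.",
                 n_random, length(universe)))
    n_random <- length(universe)
  }
  random <- with_seed(child_seed(seed, 101L),
                      sample(universe, n_random))
  strong <- unique(unlist(lapply(scans, function(s) {
    s$snp[order(s$p)][seq_len(min(n_strong_per_trait, nrow(s)))]
  })))
  list(random = random, strong = strong)
}

# Subset an effect panel to a set of SNP ids.
panel_subset <- function(panel, snp_ids) {
  ix <- match(snp_ids, panel$snp_ids)
  if (anyNA(ix)) {
    stop_sparsemet("Some requested SNPs are not in the panel.",
                   "sparsemet_id_error")
  }
  structure(
    list(bhat = panel$bhat[ix, , drop = FALSE],
         shat = panel$shat[ix, , drop = FALSE],
         snp_ids = panel$snp_ids[ix],
         phenotypes = panel$phenotypes,
         scales = panel$scales,
         se_fallback = panel$se_fallback),
    class = "effect_panel"
  )
}
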