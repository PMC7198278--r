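#' GWAS configuration
#'
#' @param max_pcs Maximum number of structure principal components offered
#'   to BIC selection.
#' @param fdr_q Benjamini-Hochberg false-discovery-rate level.
#' @param window_bp Window for candidate intervals and top-SNP thinning.
#' @param compression Cluster entries into kinship groups before scanning
#'   (off by default at panel scale).
#' @return A `gwas_config` list.
#' @export
gwas_config <- function(max_pcs = 10, fdr_q = 0.1, window_bp = 20000,
                        compression = FALSE) {
  check_fraction(fdr_q, "fdr_q", 0, 1, lo_open = TRUE, hi_open = TRUE)
  if (window_bp <= 0) {
    stop_sparsemet("`window_bp` must be positive.", "sparsemet_parameter_error")
  }
  structure(list(max_pcs = max_pcs, fdr_q = fdr_q, window_bp = window_bp,
                 compression = compression),
            class = "gwas_config")
}

#' Select the number of structure PCs by BIC
#'
#' Fits the null mixed model `y ~ 1 + PC1..PCk + g` for `k = 0..max_pcs`
#' and returns the count whose Bayesian information criterion is best
#' (maximum-likelihood BIC: `-2 logL + p log n`); ties break toward fewer
#' PCs.
#'
#' @param y Entry-level phenotype (e.g. BLUPs), aligned with `pcs` and `K`.
#' @param pcs Entry x PC score matrix (see [genotype_pca()]).
#' @param K A `kinship_matrix` over the same entries.
#' @param max_pcs Largest PC count to consider (capped at `ncol(pcs)`).
#' @return The selected PC count (integer, possibly 0).
#' @export
select_pcs_bic <- function(y, pcs, K, max_pcs = 10) {
  max_pcs <- min(max_pcs, ncol(pcs))
  bic <- vapply(0:max_pcs, function(k) {
    X <- cbind(1, pcs[, seq_len(k), drop = FALSE])
    reml_fit(y, X, K)$bic
  }, numeric(1))
  as.integer(which(bic <= min(bic) + 1e-9)[1] - 1L)
}

#' Mixed-linear-model association scan
#'
#' Estimates variance components once on the null model
#' (`y ~ 1 + PCs + g`, `g ~ N(0, Va K)`), then tests every SNP by
#' generalized least squares in the rotated eigenspace of `K`, holding
#' `(Va, Ve)` fixed (the standard population-parameters-previously-
#' determined shortcut). Two-sided p-values use the t distribution with
#' `n - p - 1` degrees of freedom; effects are reported for the alternate
#' allele. Optionally entries are first clustered into kinship groups
#' ([compress_kinship()]).
#'
#' @param y Named entry-level phenotype vector (names = entry ids);
#'   entries absent from the genotypes, or with `NA` values, are dropped.
#' @param geno A `genotype_matrix`.
#' @param K A `kinship_matrix` over (at least) the same entries.
#' @param n_pcs Number of structure PCs as covariates (see
#'   [select_pcs_bic()]).
#' @param config A [gwas_config()].
#' @return A tibble with one row per SNP: `snp`, `chrom`, `pos`, `ref`,
#'   `alt`, `maf`, `beta`, `se`, `p`, `fdr_significant`; attributes
#'   `n_pcs`, `Va`, `Ve`, `n_entries`.
#' @export
mlm_scan <- function(y, geno, K, n_pcs = 0, config = gwas_config()) {
  ids <- intersect(geno$entry_ids, names(y))
  ids <- ids[!is.na(y[ids])]
  if (length(ids) < 3) {
    stop_sparsemet("Too few entries shared between phenotype and genotypes.",
                   "sparsemet_dimension_error")
  }
  yv <- as.numeric(y[ids])
  if (sd(yv) == 0) {
    stop_sparsemet("Phenotype is constant.", "sparsemet_degenerate_error")
  }
  gsub <- subset_entries(geno, ids)
  Km <- kinship_values(K)
  kid <- if (inherits(K, "kinship_matrix")) K$entry_ids else rownames(Km)
  Km <- Km[match(ids, kid), match(ids, kid), drop = FALSE]
  n <- length(ids)

  if (isTRUE(config$compression)) {
    cmp <- compress_kinship(new_kinship(Km))
    Km <- cmp$expanded
  }

  X0 <- matrix(1, n, 1, dimnames = list(NULL, "Intercept"))
  if (n_pcs > 0) X0 <- cbind(X0, genotype_pca(gsub, n_pcs))
  fit <- reml_fit(yv, X0, Km)
  ev <- eigen(Km, symmetric = TRUE)
  w <- fit$Va * pmax(ev$values, 0) + fit$Ve
  U <- ev$vectors
  yt <- as.numeric(crossprod(U, yv))
  X0t <- crossprod(U, X0)
  Gt <- crossprod(U, mean_impute_dosages(gsub$dosages))

  p0 <- ncol(X0)
  X0w <- X0t / w
  A00 <- crossprod(X0t, X0w)
  A00i <- solve(A00)
  x0y <- as.numeric(crossprod(X0w, yt))
  rss0 <- sum(yt^2 / w) - sum(x0y * (A00i %*% x0y))

  a0 <- crossprod(X0w, Gt)                      # p0 x m
  sy <- as.numeric(crossprod(Gt, yt / w))       # m
  ss <- colSums(Gt^2 / w)                       # m
  Ai_a0 <- A00i %*% a0
  denom <- ss - colSums(a0 * Ai_a0)
  num <- sy - as.numeric(crossprod(Ai_a0, x0y))

  df <- n - p0 - 1
  beta <- ifelse(denom > 1e-10, num / denom, 0)
  rss <- pmax(rss0 - ifelse(denom > 1e-10, num^2 / denom, 0), 1e-300)
  sigma2 <- rss / df
  se <- rep(NA_real_, length(denom))
  ok <- denom > 1e-10
  se[ok] <- sqrt(sigma2[ok] / denom[ok])
  tval <- ifelse(denom > 1e-10, beta / se, 0)
  pval <- ifelse(denom > 1e-10, 2 * pt(-abs(tval), df), 1)

  p_alt <- colMeans(gsub$dosages, na.rm = TRUE) / 2
  out <- tibble(
    snp = gsub$snp_map$snp,
    chrom = gsub$snp_map$chrom,
    pos = gsub$snp_map$pos,
    ref = gsub$snp_map$ref,
    alt = gsub$snp_map$alt,
    maf = unname(pmin(p_alt, 1 - p_alt)),
    beta = unname(beta),
    se = unname(se),
    p = unname(pmin(pmax(pval, .Machine$double.xmin), 1)),
    fdr_significant = unname(bh_fdr(
      pmin(pmax(pval, .Machine$double.xmin), 1), q = config$fdr_q))
  )
  attr(out, "n_pcs") <- n_pcs
  attr(out, "Va") <- fit$Va
  attr(out, "Ve") <- fit$Ve
  attr(out, "n_entries") <- n
  out
}

subset_entries <- function(geno, ids) {
  ix <- match(ids, geno$entry_ids)
  structure(
    list(dosages = geno$dosages[ix, , drop = FALSE],
         snp_map = geno$snp_map,
         entry_ids = ids,
         alt_freq = colMeans(geno$dosages[ix, , drop = FALSE],
                             na.rm = TRUE) / 2,
         subpop = geno$subpop[ix]),
    class = "genotype_matrix"
  )
}

#' Compress a kinship matrix into entry groups
#'
#' Clusters entries by average linkage on the `max(K) - K` distance and
#' replaces within/between-group kinship by block means; the group count
#' maximizing the null-model restricted likelihood is selected. Used to
#' trade resolution for speed in large panels.
#'
#' @param K A `kinship_matrix`.
#' @param candidate_group_counts Group counts to try (defaults to
#'   `n, n/2, n/4, n/8`).
#' @param y,X Optional phenotype/design for likelihood-based selection;
#'   without them the finest grouping is returned.
#' @return List with `kinship` (group-level `kinship_matrix`), `groups`
#'   (entry -> group map), `expanded` (entry-level block-mean matrix) and
#'   `group_count`.
#' @export
compress_kinship <- function(K, candidate_group_counts = NULL,
                             y = NULL, X = NULL) {
  Km <- kinship_values(K)
  n <- nrow(Km)
  counts <- sort(unique(pmax(1, pmin(n, round(
    candidate_group_counts %||% c(n, n / 2, n / 4, n / 8)
  )))), decreasing = TRUE)
  hc <- hclust(as.dist(max(Km) - Km), method = "average")

  build <- function(k) {
    grp <- if (k >= n) seq_len(n) else cutree(hc, k = k)
    Kg <- matrix(0, max(grp), max(grp))
    cnt <- table(grp)
    for (a in seq_len(max(grp))) {
      for (b in seq_len(a)) {
        Kg[a, b] <- Kg[b, a] <- mean(Km[grp == a, grp == b, drop = FALSE])
      }
    }
    Kg <- make_psd(Kg)
    list(groups = grp, Kg = Kg, expanded = Kg[grp, grp])
  }

  if (is.null(y)) {
    chosen <- build(counts[1])
    k_sel <- counts[1]
  } else {
    X <- X %||% matrix(1, length(y), 1)
    ll <- -Inf
    chosen <- NULL
    k_sel <- NA
    for (k in counts) {
      cand <- build(k)
      fit <- reml_fit(y, X, cand$expanded)
      if (fit$log_restricted_likelihood > ll + 1e-9) {
        ll <- fit$log_restricted_likelihood
        chosen <- cand
        k_sel <- k
      }
    }
  }
  ids <- if (inherits(K, "kinship_matrix")) K$entry_ids else rownames(Km)
  list(kinship = new_kinship(chosen$Kg),
       groups = setNames(chosen$groups, ids),
       expanded = chosen$expanded,
       group_count = k_sel)
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up FDR control: flags the `k` smallest p-values where `k` is the
#' largest index with `p_(k) <= k q / m`.
#'
#' @param pvals P-values in `(0, 1]`.
#' @param q FDR level.
#' @return Logical vector of rejections, aligned with `pvals`.
#' @export
bh_fdr <- function(pvals, q = 0.1) {
  if (length(pvals) == 0) return(logical(0))
  if (any(is.na(pvals) | pvals <= 0 | pvals > 1)) {
    stop_sparsemet("P-values must lie in (0, 1].", "sparsemet_parameter_error")
  }
  p.adjust(pvals, method = "BH") <= q
}

#' Candidate interval around a peak SNP
#'
#' @param chrom,pos Peak SNP coordinates (1-based bp).
#' @param window_bp Total interval width centered on the peak.
#' @return One-row tibble `chrom`, `start`, `end` (start clamped at 1).
#' @export
candidate_window <- function(chrom, pos, window_bp = 20000) {
  if (any(pos < 1)) {
    stop_sparsemet("Positions are 1-based.", "sparsemet_parameter_error")
  }
  tibble(chrom = chrom,
         start = pmax(1, pos - window_bp / 2),
         end = pos + window_bp / 2)
}

#' Thin top associations to one SNP per window
#'
#' Scans SNPs in order of ascending p-value and keeps a SNP only if no
#' already-kept SNP lies within `window_bp` on the same chromosome,
#' stopping after `n_top` SNPs.
#'
#' @param results Association tibble (needs `chrom`, `pos`, `p`).
#' @param n_top Maximum SNPs kept.
#' @param window_bp Exclusion window.
#' @return The thinned subset of `results`, sorted by p-value.
#' @export
thin_top_snps <- function(results, n_top = 10, window_bp = 20000) {
  res <- arrange(results, p)
  kept <- integer(0)
  for (i in seq_len(nrow(res))) {
    if (length(kept) >= n_top) break
    close_by <- any(res$chrom[kept] == res$chrom[i] &
                      abs(res$pos[kept] - res$pos[i]) <= window_bp)
    if (!isTRUE(close_by)) kept <- c(kept, i)
  }
  res[kept, ]
}

#' Earliest trial year per entry
#'
#' The first year each entry appears in the trial network; used as a proxy
#' phenotype for entry age, analogous to an environmental GWAS covariate.
#'
#' @param table Phenotype or design tibble with `entry` and `year`.
#' @return Named numeric vector: earliest year per entry.
#' @export
earliest_year_phenotype <- function(table) {
  agg <- table %>%
    group_by(entry) %>%
    summarise(year = min(year), .groups = "drop")
  setNames(as.numeric(agg$year), agg$entry)
}
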