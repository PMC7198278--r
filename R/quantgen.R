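#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs whose minor allele frequency exceeds `threshold`
#' (strictly), matching the usual "MAF > 5%" convention for association
#' panels.
#'
#' @param geno A `genotype_matrix`.
#' @param threshold MAF threshold in `[0, 0.5]`.
#' @return The filtered `genotype_matrix`.
#' @export
maf_filter <- function(geno, threshold = 0.05) {
  check_fraction(threshold, "threshold", 0, 0.5)
  p <- colMeans(geno$dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  subset_snps(geno, which(maf > threshold))
}

# Per-SNP mean imputation of missing dosages.
mean_impute_dosages <- function(dos) {
  nas <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    mns <- colMeans(dos, na.rm = TRUE)
    dos[nas] <- mns[nas[, 2]]
  }
  dos
}

#' VanRaden genomic relationship matrix
#'
#' `K = Z Z' / (2 * sum_j p_j (1 - p_j))` where `Z` is the dosage matrix
#' column-centered by twice the alt-allele frequency. Missing dosages are
#' mean-imputed per SNP first. The spectral decomposition is computed once
#' and cached on the object, since every downstream mixed-model fit reuses
#' it.
#'
#' @param geno A `genotype_matrix`, or a plain entries x SNPs dosage matrix.
#' @return A `kinship_matrix`: list with `values` (symmetric matrix),
#'   `eigen` (cached decomposition), `entry_ids`.
#' @export
#' @examples
#' dos <- rbind(A = c(0, 2), B = c(0, 2), C = c(2, 0))
#' vanraden_kinship(dos)$values
vanraden_kinship <- function(geno) {
  dos <- if (inherits(geno, "genotype_matrix")) geno$dosages else as.matrix(geno)
  if (nrow(dos) < 2 || ncol(dos) < 1) {
    stop_sparsemet("Kinship needs >= 2 entries and >= 1 SNP.",
                   "sparsemet_dimension_error")
  }
  dos <- mean_impute_dosages(dos)
  p <- colMeans(dos) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) {
    stop_sparsemet("All SNPs are monomorphic; kinship denominator is zero.",
                   "sparsemet_degenerate_error")
  }
  Z <- sweep(dos, 2, 2 * p)
  K <- tcrossprod(Z) / denom
  K <- (K + t(K)) / 2
  new_kinship(K)
}

new_kinship <- function(K) {
  structure(
    list(values = K,
         eigen = eigen(K, symmetric = TRUE),
         entry_ids = rownames(K) %||% sprintf("E%03d", seq_len(nrow(K)))),
    class = "kinship_matrix"
  )
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("<kinship_matrix> ", nrow(x$values), " entries; eigenvalue range [",
      sprintf("%.3g", min(x$eigen$values)), ", ",
      sprintf("%.3g", max(x$eigen$values)), "]\n", sep = "")
  invisible(x)
}

#' Principal components of the genotype matrix
#'
#' PCs of the column-centered dosage matrix, ordered by decreasing
#' variance explained, with a deterministic sign convention (the
#' largest-magnitude loading of each component is positive).
#'
#' @param geno A `genotype_matrix`.
#' @param n_pcs Number of leading components to return.
#' @return Entries x `n_pcs` score matrix with attribute
#'   `"variance_explained"`.
#' @export
genotype_pca <- function(geno, n_pcs) {
  dos <- mean_impute_dosages(geno$dosages)
  if (n_pcs <= 0) {
    out <- matrix(0, nrow(dos), 0)
    rownames(out) <- geno$entry_ids
    attr(out, "variance_explained") <- numeric(0)
    return(out)
  }
  if (n_pcs >= min(dim(dos))) {
    stop_sparsemet("`n_pcs` must be smaller than both dimensions.",
                   "sparsemet_parameter_error")
  }
  Z <- scale(dos, center = TRUE, scale = FALSE)
  sv <- svd(Z, nu = n_pcs, nv = n_pcs)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  # sign convention from loadings
  for (j in seq_len(n_pcs)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- geno$entry_ids
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  attr(scores, "variance_explained") <-
    sv$d[seq_len(n_pcs)]^2 / sum(sv$d^2)
  scores
}

#' Greedy LD pruning
#'
#' Scans SNPs left to right within each chromosome and drops a SNP whose
#' squared Pearson correlation with any retained SNP closer than
#' `window_bp` exceeds `r2_max`.
#'
#' @param geno A `genotype_matrix`.
#' @param r2_max Maximum allowed squared correlation, in `(0, 1]`.
#' @param window_bp Window in base pairs within which correlations are
#'   checked.
#' @return The pruned `genotype_matrix`.
#' @export
ld_prune <- function(geno, r2_max = 0.2, window_bp = 50000) {
  check_fraction(r2_max, "r2_max", 0, 1, lo_open = TRUE)
  dos <- mean_impute_dosages(geno$dosages)
  map <- geno$snp_map
  keep <- logical(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    idx <- idx[order(map$pos[idx])]
    kept <- integer(0)
    kept_pos <- numeric(0)
    for (j in idx) {
      near <- kept[abs(kept_pos - map$pos[j]) <= window_bp]
      ok <- TRUE
      if (length(near) > 0) {
        x <- dos[, j]
        if (sd(x) == 0) {
          ok <- FALSE
        } else {
          for (k in near) {
            y <- dos[, k]
            r <- if (sd(y) == 0) 0 else cor(x, y)
            if (r^2 > r2_max) { ok <- FALSE; break }
          }
        }
      }
      if (ok) {
        kept <- c(kept, j)
        kept_pos <- c(kept_pos, map$pos[j])
      }
    }
    keep[kept] <- TRUE
  }
  subset_snps(geno, which(keep))
}
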