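#' Simulate genotypes for a structured inbred panel
#'
#' Draws biallelic SNP dosages for a panel of `n_entries` inbred lines in
#' `n_subpops` subpopulations. Ancestral allele frequencies are uniform on
#' (0.1, 0.9); subpopulation frequencies follow the Balding-Nichols Beta
#' model at divergence `fst`; heterozygote frequency is deflated by the
#' `inbreeding` coefficient. Linkage disequilibrium is blockwise: within a
#' block of `ld_block_size` consecutive SNPs each SNP copies the block head,
#' re-drawn per entry with probability `flip_prob`, so within-block
#' r-squared is near 1 and between-block r-squared is near 0.
#'
#' @param config A [sim_config()].
#' @return A `genotype_matrix`: list with `dosages` (entries x SNPs matrix
#'   of 0/1/2 alt-allele counts), `snp_map` (tibble: `snp`, `chrom` in
#'   Pv01..Pv11, `pos` 1-based bp, `ref`, `alt`), `entry_ids`, `alt_freq`,
#'   and `subpop` labels per entry.
#' @export
#' @examples
#' g <- simulate_genotypes(sim_config(n_entries = 40, n_snps = 200, seed = 3))
#' dim(g$dosages)
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 11L), {
    n <- config$n_entries
    m <- config$n_snps
    k <- config$n_subpops
    fst <- config$fst
    f <- config$inbreeding

    # roughly equal subpopulation sizes
    subpop <- sort(rep_len(seq_len(k), n))
    entry_ids <- sprintf("E%03d", seq_len(n))

    blocks <- split(seq_len(m),
                    ceiling(seq_len(m) / config$ld_block_size))
    dos <- matrix(0L, n, m)

    draw_snp <- function(p_sub) {
      # genotype frequencies with inbreeding f at subpop frequency p
      vapply(seq_len(n), function(i) {
        p <- p_sub[subpop[i]]
        probs <- c((1 - p)^2 + f * p * (1 - p),
                   2 * p * (1 - p) * (1 - f),
                   p^2 + f * p * (1 - p))
        sample(0:2, 1, prob = probs)
      }, integer(1))
    }

    for (b in blocks) {
      p_anc <- runif(1, 0.1, 0.9)
      p_sub <- if (fst == 0) {
        rep(p_anc, k)
      } else {
        a <- p_anc * (1 - fst) / fst
        bb <- (1 - p_anc) * (1 - fst) / fst
        rbeta(k, a, bb)
      }
      head_geno <- draw_snp(p_sub)
      dos[, b[1]] <- head_geno
      if (length(b) > 1) {
        for (j in b[-1]) {
          flip <- runif(n) < config$flip_prob
          g <- head_geno
          if (any(flip)) g[flip] <- draw_snp(p_sub)[flip]
          dos[, j] <- g
        }
      }
    }

    dimnames(dos) <- list(entry_ids, sprintf("S%05d", seq_len(m)))
    new_genotype_matrix(dos, subpop = subpop)
  })
}

# Construct the genotype container: positions are laid out over 11
# chromosomes (Pv01..Pv11) in contiguous stretches, ~1 kb median spacing.
new_genotype_matrix <- function(dos, subpop = NULL, snp_map = NULL) {
  n <- nrow(dos)
  m <- ncol(dos)
  if (m < 1) {
    stop_sparsemet("At least one SNP is required.", "sparsemet_dimension_error")
  }
  if (is.null(snp_map)) {
    n_chrom <- 11L
    chrom_of <- ceiling(seq_len(m) / ceiling(m / n_chrom))
    pos <- unlist(lapply(split(seq_len(m), chrom_of), function(ix) {
      cumsum(sample(500:1500, length(ix), replace = TRUE))
    }), use.names = FALSE)
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
    snp_map <- tibble(
      snp = colnames(dos) %||% sprintf("S%05d", seq_len(m)),
      chrom = sprintf("Pv%02d", chrom_of),
      pos = pos, ref = unname(ref), alt = unname(alt)
    )
  }
  structure(
    list(
      dosages = dos,
      snp_map = snp_map,
      entry_ids = rownames(dos) %||% sprintf("E%03d", seq_len(n)),
      alt_freq = unname(colMeans(dos, na.rm = TRUE) / 2),
      subpop = subpop
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$entry_ids), " entries x ",
      nrow(x$snp_map), " SNPs on ", length(unique(x$snp_map$chrom)),
      " chromosomes\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Subset a genotype_matrix by SNP column index, keeping the map aligned.
subset_snps <- function(geno, keep) {
  structure(
    list(
      dosages = geno$dosages[, keep, drop = FALSE],
      snp_map = geno$snp_map[keep, , drop = FALSE],
      entry_ids = geno$entry_ids,
      alt_freq = geno$alt_freq[keep],
      subpop = geno$subpop
    ),
    class = "genotype_matrix"
  )
}
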