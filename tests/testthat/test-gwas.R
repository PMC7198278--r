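gwas_fixture <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      geno <- simulate_genotypes(sim_config(
        n_entries = 120, n_snps = 800, ld_block_size = 1,
        entries_per_year_range = c(10, 50),
        locations_per_year_range = c(2, 5), n_locations = 6, seed = 77))
      memo <<- list(geno = geno, kin = vanraden_kinship(geno))
    }
    memo
  }
})

test_that("mlm_scan output is well-formed", {
  fx <- gwas_fixture()
  y <- sparsemet:::with_seed(1, {
    setNames(rnorm(120), fx$geno$entry_ids)
  })
  sc <- mlm_scan(y, fx$geno, fx$kin, n_pcs = 2)
  expect_identical(nrow(sc), 800L)
  expect_identical(sc$snp, fx$geno$snp_map$snp)
  expect_true(all(sc$p > 0 & sc$p <= 1))
  expect_true(all(sc$maf >= 0 & sc$maf <= 0.5))
  expect_true(all(is.finite(sc$beta)))
  expect_identical(attr(sc, "n_pcs"), 2)
  expect_identical(attr(sc, "n_entries"), 120L)
})

test_that("p-values are calibrated under the null", {
  fx <- gwas_fixture()
  base <- sparsemet:::with_seed(2, rnorm(120))
  pooled <- unlist(lapply(1:5, function(i) {
    y <- setNames(sparsemet:::with_seed(100 + i, sample(base)),
                  fx$geno$entry_ids)
    mlm_scan(y, fx$geno, fx$kin)$p
  }))
  ks <- suppressWarnings(ks.test(pooled, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  expect_lt(mean(pooled < 0.05), 0.08)
})

test_that("a strong planted QTL is detected at top rank", {
  fx <- gwas_fixture()
  maf <- pmin(fx$geno$alt_freq, 1 - fx$geno$alt_freq)
  snp <- which(maf > 0.3)[5]
  y <- sparsemet:::with_seed(9, {
    x <- fx$geno$dosages[, snp]
    g <- as.numeric(sparsemet:::make_psd(fx$kin$values) %*% rnorm(120)) * 0.2
    setNames(x * 0.8 + g + rnorm(120, sd = 0.6), fx$geno$entry_ids)
  })
  sc <- mlm_scan(y, fx$geno, fx$kin)
  expect_true(fx$geno$snp_map$snp[snp] %in%
                sc$snp[order(sc$p)][1:10])
  expect_gt(sc$beta[snp], 0)  # alternate-allele orientation
})

test_that("monomorphic SNPs get null statistics, constant y errors", {
  fx <- gwas_fixture()
  geno <- fx$geno
  geno$dosages[, 3] <- 2
  y <- setNames(sparsemet:::with_seed(3, rnorm(120)), geno$entry_ids)
  sc <- mlm_scan(y, geno, fx$kin)
  expect_identical(sc$beta[3], 0)
  expect_identical(sc$p[3], 1)
  expect_error(mlm_scan(setNames(rep(1, 120), geno$entry_ids), geno, fx$kin),
               class = "sparsemet_degenerate_error")
  expect_error(mlm_scan(setNames(1:2, geno$entry_ids[1:2]), geno, fx$kin),
               class = "sparsemet_dimension_error")
})

test_that("select_pcs_bic prefers fewer PCs on unstructured phenotypes", {
  fx <- gwas_fixture()
  pcs <- genotype_pca(fx$geno, 6)
  y_null <- sparsemet:::with_seed(4, rnorm(120))
  k0 <- select_pcs_bic(y_null, pcs, fx$kin$values, 6)
  expect_lte(k0, 2)
  # a phenotype that is literally PC2 demands at least two PCs
  y_pc <- pcs[, 2] + sparsemet:::with_seed(5, rnorm(120, sd = 0.05))
  k2 <- select_pcs_bic(y_pc, pcs, fx$kin$values, 6)
  expect_gte(k2, 2)
})

test_that("bh_fdr equals the brute-force step-up oracle", {
  for (i in 1:200) {
    p <- sparsemet:::with_seed(i, {
      n <- sample(5:80, 1)
      p <- runif(n)
      hits <- sample(n, sample(0:3, 1))
      p[hits] <- p[hits] / 1000
      p
    })
    expect_identical(bh_fdr(p, 0.1), brute_force_bh(p, 0.1))
  }
  expect_identical(bh_fdr(numeric(0)), logical(0))
  expect_error(bh_fdr(c(0.5, 0)), class = "sparsemet_parameter_error")
  expect_error(bh_fdr(c(0.5, NA)), class = "sparsemet_parameter_error")
})

test_that("compress_kinship builds block means and selects by likelihood", {
  fx <- gwas_fixture()
  K <- fx$kin
  cmp <- compress_kinship(K, candidate_group_counts = c(120, 30))
  expect_identical(cmp$group_count, 120)
  y <- sparsemet:::with_seed(6, rnorm(120))
  cmp2 <- compress_kinship(K, candidate_group_counts = c(120, 30), y = y)
  expect_true(cmp2$group_count %in% c(120, 30))
  expect_identical(dim(cmp2$expanded), c(120L, 120L))
  grp <- cmp2$groups
  # expanded matrix is constant within group blocks
  a <- which(grp == grp[1])
  if (length(a) > 1) {
    expect_equal(cmp2$expanded[a[1], ], cmp2$expanded[a[2], ])
  }
})

test_that("candidate_window and thin_top_snps behave geometrically", {
  w <- candidate_window("Pv03", c(5000, 8000), 20000)
  expect_equal(w$start, c(1, 1))  # clamped at chromosome start
  expect_equal(w$end, c(15000, 18000))
  expect_error(candidate_window("Pv01", 0), class = "sparsemet_parameter_error")

  res <- tibble::tibble(
    snp = paste0("S", 1:4),
    chrom = c("Pv01", "Pv01", "Pv01", "Pv02"),
    pos = c(100, 150, 50000, 100),
    p = c(1e-8, 1e-7, 1e-6, 1e-5)
  )
  thin <- thin_top_snps(res, n_top = 10, window_bp = 1000)
  expect_identical(thin$snp, c("S1", "S3", "S4"))  # S2 shadowed by S1
  expect_identical(nrow(thin_top_snps(res, n_top = 2, window_bp = 1000)), 2L)
})

test_that("earliest_year_phenotype returns the first trial year per entry", {
  tab <- tibble::tibble(entry = c("A", "A", "B"),
                        year = c(2005L, 2001L, 2003L))
  ey <- earliest_year_phenotype(tab)
  expect_identical(ey, c(A = 2001, B = 2003))
})
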