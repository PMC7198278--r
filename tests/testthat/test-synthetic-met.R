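cfg_small <- function(seed = 42) {
  sim_config(n_entries = 80, n_snps = 600, n_locations = 8, n_years = 6,
             entries_per_year_range = c(16, 40),
             locations_per_year_range = c(4, 8), seed = seed)
}

test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(fst = 1), class = "sparsemet_parameter_error")
  expect_error(sim_config(inbreeding = -0.1),
               class = "sparsemet_parameter_error")
  expect_error(sim_config(n_entries = 10, entries_per_year_range = c(5, 20)),
               class = "sparsemet_parameter_error")
  expect_error(sim_config(locations_per_year_range = c(10, 5)),
               class = "sparsemet_parameter_error")
  bad <- default_specs <- sparsemet:::default_trait_specs()
  bad$h2_target[1] <- 1.5
  expect_error(sim_config(trait_specs = bad),
               class = "sparsemet_parameter_error")
  one <- default_specs[1, ]
  one$h2_target <- 1
  expect_error(sim_config(trait_specs = one, var_error = 2),
               class = "sparsemet_parameter_error")
})

test_that("defaults describe the sparse nursery panel", {
  cfg <- sim_config()
  expect_identical(cfg$n_entries, 327L)
  expect_identical(cfg$n_subpops, 3L)
  expect_identical(cfg$entries_per_year_range, c(16L, 61L))
  expect_identical(cfg$locations_per_year_range, c(10L, 28L))
  expect_identical(cfg$years_per_entry_median, 2L)
  expect_identical(nrow(cfg$trait_specs), 8L)
  expect_equal(range(cfg$trait_specs$h2_target), c(0.067, 0.733))
})

test_that("simulated genotypes are valid inbred dosages", {
  geno <- small_sim()$genotypes
  dos <- geno$dosages
  expect_identical(dim(dos), c(80L, 600L))
  expect_true(all(dos %in% 0:2))
  expect_identical(rownames(dos), geno$entry_ids)
  expect_identical(nrow(geno$snp_map), 600L)
  expect_identical(sort(unique(geno$snp_map$chrom)),
                   sprintf("Pv%02d", 1:11))
  # positions strictly increasing within each chromosome
  by_chr <- split(geno$snp_map$pos, geno$snp_map$chrom)
  expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
  # heterozygosity far below Hardy-Weinberg under strong inbreeding
  p <- colMeans(dos) / 2
  poly <- p > 0.05 & p < 0.95
  het <- colMeans(dos == 1)
  expect_lt(mean(het[poly]), 0.25 * mean(2 * p[poly] * (1 - p[poly])))
})

test_that("subpopulations are genetically differentiated", {
  geno <- small_sim()$genotypes
  sp <- geno$subpop
  expect_identical(length(sp), 80L)
  expect_identical(length(unique(sp)), 3L)
  pair <- sort(unique(sp))[1:2]
  g1 <- geno$dosages[sp == pair[1], ]
  g2 <- geno$dosages[sp == pair[2], ]
  fst <- hudson_fst(colMeans(g1) / 2, colMeans(g2) / 2,
                    2 * nrow(g1), 2 * nrow(g2))
  expect_gt(fst, 0.1)  # configured divergence 0.25, estimator is noisy
  expect_lt(fst, 0.5)
})

test_that("linkage blocks induce high within-block correlation", {
  geno <- small_sim()$genotypes
  dos <- geno$dosages
  # adjacent pairs inside a 10-SNP block vs pairs across block boundaries
  idx <- seq_len(ncol(dos) - 1)
  same_block <- (idx %% 10) != 0
  r <- vapply(idx, function(j) {
    if (sd(dos[, j]) == 0 || sd(dos[, j + 1]) == 0) return(NA_real_)
    cor(dos[, j], dos[, j + 1])^2
  }, numeric(1))
  expect_gt(mean(r[same_block], na.rm = TRUE),
            mean(r[!same_block], na.rm = TRUE) + 0.3)
})

test_that("the trial design is sparse within the configured ranges", {
  sim <- small_sim()
  s <- design_summary(sim$design)
  expect_gte(s$min_entries_per_year, 16)
  expect_lte(s$max_entries_per_year, 40)
  expect_gte(s$min_locations_per_year, 4)
  expect_lte(s$max_locations_per_year, 8)
  # the small panel saturates, so only the full-size config (covered in the
  # carry-over test below) pins the median at exactly 2
  expect_gte(s$median_years_per_entry, 1)
  expect_true(all(sim$design$entry %in% sim$genotypes$entry_ids))
  # every tested entry visits all of its year's locations
  cells <- dplyr::distinct(sim$design)
  expect_identical(nrow(cells), nrow(sim$design))
})

test_that("carry-over continuation gives a median of two years per entry", {
  # larger design so the median is stable
  cfg <- sim_config(n_entries = 327, n_snps = 10, seed = 3)
  d <- simulate_design(cfg)
  yrs <- dplyr::count(dplyr::distinct(d, entry, year), entry)
  expect_identical(as.integer(median(yrs$n)), 2L)
})

test_that("phenotypes carry additive signal at the configured heritability", {
  sim <- small_sim()
  ph <- sim$phenotypes
  expect_identical(sort(unique(ph$trait)),
                   sort(sim$config$trait_specs$name))
  expect_false(anyNA(ph$value))
  # ordinal traits are integers on their scales
  specs <- sim$config$trait_specs
  for (i in which(specs$scale_type == "ordinal")) {
    v <- ph$value[ph$trait == specs$name[i]]
    expect_true(all(v == round(v)))
    expect_gte(min(v), specs$lo[i])
    expect_lte(max(v), specs$hi[i])
  }
  # realized latent-scale heritability tracks the target
  expect_equal(unname(sim$truth$realized_h2),
               specs$h2_target, tolerance = 0.15)
})

test_that("planted QTL effects are group-restricted with shared signs", {
  sim <- small_sim()
  q <- sim$truth$qtl_effects
  specs <- sim$config$trait_specs
  expect_identical(nrow(q), 6L)  # 3 per group x 2 groups
  for (i in seq_len(nrow(q))) {
    g <- q$group_id[i]
    inside <- as.numeric(q[i, specs$name[specs$group_id == g]])
    outside <- as.numeric(q[i, specs$name[specs$group_id != g]])
    expect_true(all(outside == 0))
    nz <- inside[inside != 0]
    expect_true(length(nz) > 0)
    expect_identical(length(unique(sign(nz))), 1L)
  }
})

test_that("the generator is deterministic in the seed", {
  a <- simulate_met(cfg_small(7))
  b <- simulate_met(cfg_small(7))
  c <- simulate_met(cfg_small(8))
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_false(identical(a$genotypes$dosages, c$genotypes$dosages))
})

test_that("emit_scale handles constant and percent inputs", {
  expect_identical(sparsemet:::emit_scale(rep(2, 5), "ordinal", 1, 5),
                   rep(2, 5))
  x <- rnorm(100)
  v <- sparsemet:::emit_scale(x, "percent", 0, 100)
  expect_gte(min(v), 0)
  expect_lte(max(v), 100)
  expect_error(sparsemet:::emit_scale(x, "nope", 0, 1),
               class = "sparsemet_parameter_error")
})
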