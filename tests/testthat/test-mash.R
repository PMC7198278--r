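# Hand-constructable 1-D mixture model.
model_1d <- function(weights, omega = 1) {
  structure(
    list(components = list(identity = matrix(1, 1, 1,
                                             dimnames = list("t1", "t1"))),
         scales = omega,
         weights = weights,
         grid = data.frame(k = 1, l = 1),
         loglik_trace = 0, converged = TRUE),
    class = "mixture_model"
  )
}

panel_1d <- function(bhat, shat = 1) {
  structure(
    list(bhat = matrix(bhat, ncol = 1, dimnames = list(NULL, "t1")),
         shat = matrix(shat, length(bhat), 1, dimnames = list(NULL, "t1")),
         snp_ids = paste0("S", seq_along(bhat)), phenotypes = "t1",
         scales = list(), se_fallback = c(t1 = FALSE)),
    class = "effect_panel"
  )
}

test_that("standardize_effects centers, unit-scales, and keeps z-scores", {
  std <- standardize_effects(c(1, 2, 3), c(1, 1, 1))
  expect_equal(std$beta, c(-1, 0, 1))
  expect_equal(std$center, 2)
  expect_equal(std$scale, 1)
  b <- sparsemet:::with_seed(1, rnorm(50, mean = 3, sd = 2))
  se <- runif(50, 0.5, 2)
  std <- standardize_effects(b, se)
  expect_equal(mean(std$beta), 0, tolerance = 1e-12)
  expect_equal(max(abs(std$beta)), 1)
  expect_equal(std$beta / std$se, (b - mean(b)) / se, tolerance = 1e-12)
  expect_error(standardize_effects(c(2, 2, 2), c(1, 1, 1)),
               class = "sparsemet_degenerate_error")
})

test_that("Hedges' G and its standard error match the closed forms", {
  expect_equal(hedges_g_se(10, 10, 0), sqrt(0.2))
  expect_equal(hedges_g_se(4, 6, 1), sqrt(10 / 24 + 1 / 20))
  expect_error(hedges_g_se(1, 10, 0), class = "sparsemet_parameter_error")
  # equal-variance groups: d = 1, J = 1 - 3/(4*18 - 1)
  g <- hedges_g(mean0 = 0, mean1 = 1, sd0 = 1, sd1 = 1, n0 = 10, n1 = 10)
  expect_equal(g, 1 - 3 / 71)
})

test_that("the conjugate 1-D posterior and lfsr match closed forms", {
  # bhat = 2, s = 1, prior N(0, 1): posterior N(1, 1/2),
  # lfsr = P(b <= 0) = pnorm(-1 / sqrt(0.5))
  model <- model_1d(weights = c(null = 0, alt = 1), omega = 1)
  post <- compute_posteriors(panel_1d(2), model)
  expect_equal(unname(post$post_mean[1, 1]), 1, tolerance = 1e-10)
  expect_equal(unname(post$post_sd[1, 1]), sqrt(0.5), tolerance = 1e-10)
  expect_equal(unname(post$lfsr[1, 1]), pnorm(-1 / sqrt(0.5)), tolerance = 1e-10)
  expect_equal(round(unname(post$lfsr[1, 1]), 4), 0.0786)
})

test_that("the Bayes factor matches the closed form", {
  # bhat = 3, s = 1, prior N(0, 9): BF = N(3; 0, 10) / N(3; 0, 1)
  model <- model_1d(weights = c(null = 0.5, alt = 0.5), omega = 9)
  bf <- bayes_factor(panel_1d(3), model)
  expect_equal(bf$bf[1], sqrt(1 / 10) * exp(9 / 2 - 9 / 20),
               tolerance = 1e-10)
  expect_equal(round(bf$bf[1], 2), 18.15)
  expect_false(bf$decisive[1])
  strong <- bayes_factor(panel_1d(6), model)
  expect_true(strong$decisive[1])
  no_null <- model_1d(weights = c(alt = 1))
  expect_error(bayes_factor(panel_1d(1), no_null),
               class = "sparsemet_parameter_error")
})

test_that("omega_grid is geometric and spans the prescribed range", {
  bhat <- matrix(c(-1, 0.2, 1), 3)
  shat <- matrix(c(0.2, 0.3, 0.4), 3)
  om <- omega_grid(bhat, shat)
  expect_equal(om[1], 0.2^2 / 4)
  expect_gte(max(om), 4 * 1)
  expect_equal(unique(round(diff(log(om)), 10)),
               round(log(sqrt(2)), 10))
})

test_that("learn_covariances returns PSD unit-max-diagonal components", {
  b <- sparsemet:::with_seed(2, {
    z <- matrix(rnorm(200 * 4), 200, 4)
    z[, 2] <- z[, 1] + rnorm(200, sd = 0.1)
    colnames(z) <- paste0("t", 1:4)
    z
  })
  comps <- learn_covariances(b, rank = 2)
  expect_identical(names(comps)[1], "identity")
  expect_true(all(c("equal_effects", "empirical", "pca") %in% names(comps)))
  expect_identical(length(comps), 4L + 4L)  # canonical + singletons + data
  for (m in comps) {
    expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
    expect_equal(max(diag(m)), 1)
  }
  # the empirical component captures the planted t1-t2 correlation
  expect_gt(comps$empirical["t1", "t2"], 0.5)
})

test_that("EM increases the likelihood monotonically and finds the null", {
  sparsemet:::with_seed(3, {
    bhat <- matrix(rnorm(400 * 3), 400, 3)  # pure noise, s = 1
    colnames(bhat) <- paste0("t", 1:3)
    shat <- matrix(1, 400, 3, dimnames = dimnames(bhat))
    comps <- learn_covariances(bhat)
    fit <- fit_mixture_em(bhat, shat, comps)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
    # near-null mass: the point mass plus the smallest prior scale
    grid <- fit$grid
    near <- c(TRUE, fit$scales[grid$l] <= min(fit$scales))
    expect_gt(sum(fit$weights[near]), 0.9)
  })
})

test_that("EM recovers a strongly shared signal component", {
  sparsemet:::with_seed(4, {
    n <- 300
    b_true <- rnorm(n, sd = 1) %o% c(1, 1, 1)     # perfectly shared
    bhat <- b_true + matrix(rnorm(n * 3, sd = 0.1), n, 3)
    colnames(bhat) <- paste0("t", 1:3)
    shat <- matrix(0.1, n, 3, dimnames = dimnames(bhat))
    comps <- learn_covariances(bhat)
    fit <- fit_mixture_em(bhat, shat, comps)
    grid <- fit$grid
    covs <- c("null", names(comps)[grid$k])
    shared <- covs %in% c("equal_effects", "empirical", "pca")
    expect_gt(sum(fit$weights[shared]), 0.8)
    post <- compute_posteriors(
      structure(list(bhat = bhat, shat = shat,
                     snp_ids = paste0("S", 1:n), phenotypes = colnames(bhat),
                     scales = list(), se_fallback = logical(3)),
                class = "effect_panel"), fit)
    # posterior means shrink toward the truth
    rmse_raw <- sqrt(mean((bhat - b_true)^2))
    rmse_post <- sqrt(mean((post$post_mean - b_true)^2))
    expect_lt(rmse_post, rmse_raw)
  })
})

test_that("fit_mixture_em validates inputs", {
  b <- matrix(rnorm(10), 5, 2)
  s <- matrix(1, 5, 2)
  notpsd <- list(bad = matrix(c(1, 2, 2, 1), 2))
  expect_error(fit_mixture_em(b, s, notpsd),
               class = "sparsemet_parameter_error")
  expect_error(fit_mixture_em(b, matrix(-1, 5, 2), list(id = diag(2))),
               class = "sparsemet_parameter_error")
  expect_error(fit_mixture_em(b, s, list(id = diag(2)), scales = c(-1, 2)),
               class = "sparsemet_parameter_error")
})

test_that("pairwise_sharing counts sign- and magnitude-concordant effects", {
  post <- structure(
    list(post_mean = cbind(t1 = c(1, 1, -1, 0.1),
                           t2 = c(1.5, -1, -1.9, 3)),
         post_sd = matrix(0.1, 4, 2),
         lfsr = cbind(t1 = c(0.01, 0.01, 0.01, 0.9),
                      t2 = c(0.01, 0.01, 0.01, 0.9)),
         null_prob = rep(0, 4),
         snp_ids = paste0("S", 1:4), phenotypes = c("t1", "t2")),
    class = "mash_posterior"
  )
  sh <- pairwise_sharing(post)
  # S1 shared (same sign, ratio 1.5); S2 sign-discordant; S3 same sign but
  # ratio 1.9 < 2 -> shared; S4 not significant in either trait
  expect_equal(sh["t1", "t2"], 2 / 3)
  expect_equal(diag(sh), c(t1 = 1, t2 = 1))
  none <- post
  none$lfsr[] <- 1
  expect_true(is.na(pairwise_sharing(none)["t1", "t2"]))
})

test_that("lfsr-flagged effects rarely have the wrong sign", {
  sparsemet:::with_seed(5, {
    n <- 800
    is_sig <- runif(n) < 0.3
    b_true <- ifelse(is_sig, rnorm(n, sd = 1.5), 0) %o% c(1, 1)
    bhat <- b_true + matrix(rnorm(n * 2, sd = 0.5), n, 2)
    colnames(bhat) <- c("t1", "t2")
    shat <- matrix(0.5, n, 2, dimnames = dimnames(bhat))
    fit <- fit_mixture_em(bhat, shat, learn_covariances(bhat))
    post <- compute_posteriors(
      structure(list(bhat = bhat, shat = shat, snp_ids = paste0("S", 1:n),
                     phenotypes = colnames(bhat), scales = list(),
                     se_fallback = logical(2)), class = "effect_panel"),
      fit)
    called <- post$lfsr <= 0.05
    expect_gt(sum(called), 50)  # the regime has real signal to call
    wrong <- sign(post$post_mean[called]) != sign(b_true[called])
    expect_lte(mean(wrong), 0.10)
  })
})

test_that("build_effect_panel standardizes every phenotype column", {
  sim <- small_sim()
  kin <- vanraden_kinship(maf_filter(sim$genotypes, 0.05))
  g <- maf_filter(sim$genotypes, 0.05)
  blups <- fit_all_blups(standardize_phenotypes(sim$phenotypes), kin,
                         c("seed_yield", "seed_weight"))
  scans <- lapply(blups, function(b) {
    mlm_scan(setNames(b$blups$blup, b$blups$entry), g, kin)
  })
  panel <- build_effect_panel(scans, g)
  expect_identical(panel$phenotypes, c("seed_yield", "seed_weight"))
  expect_equal(unname(colMeans(panel$bhat)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(abs(panel$bhat), 2, max)), c(1, 1))
  expect_true(all(panel$shat > 0))
  expect_false(any(panel$se_fallback))
  # scans on different SNP universes are rejected
  scans2 <- scans
  scans2[[2]] <- scans2[[2]][-1, ]
  expect_error(build_effect_panel(scans2, g), class = "sparsemet_id_error")
})

test_that("the Hedges' G fallback engages when SEs are mostly missing", {
  sim <- small_sim()
  g <- maf_filter(sim$genotypes, 0.05)
  kin <- vanraden_kinship(g)
  blups <- fit_all_blups(standardize_phenotypes(sim$phenotypes), kin,
                         c("seed_yield", "seed_weight"))
  scans <- lapply(blups, function(b) {
    mlm_scan(setNames(b$blups$blup, b$blups$entry), g, kin)
  })
  scans[[1]]$se[seq_len(ceiling(0.2 * nrow(scans[[1]])))] <- NA
  panel <- build_effect_panel(scans, g)
  expect_true(panel$se_fallback[["seed_yield"]])
  expect_false(panel$se_fallback[["seed_weight"]])
  expect_true(all(is.finite(panel$shat)))
})

test_that("build_snp_sets draws deterministic random and strong sets", {
  sim <- small_sim()
  g <- maf_filter(sim$genotypes, 0.05)
  kin <- vanraden_kinship(g)
  b <- fit_blup(standardize_phenotypes(sim$phenotypes), "seed_weight", kin)
  scans <- list(seed_weight = mlm_scan(setNames(b$blups$blup, b$blups$entry),
                                       g, kin))
  s1 <- suppressWarnings(build_snp_sets(scans, g, n_random = 50,
                                        n_strong_per_trait = 20, seed = 9))
  s2 <- suppressWarnings(build_snp_sets(scans, g, n_random = 50,
                                        n_strong_per_trait = 20, seed = 9))
  expect_identical(s1, s2)
  expect_identical(length(s1$random), 50L)
  expect_identical(length(s1$strong), 20L)
  expect_warning(build_snp_sets(scans, g, n_random = 1e6), "capped")
  top <- scans$seed_weight$snp[order(scans$seed_weight$p)][1:20]
  expect_setequal(s1$strong, top)
})
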