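#' Simulate phenotypes with known genetic ground truth
#'
#' Generates record-level phenotypes
#' `y = mu + g + L + LY + e`, where `g` is an entry's additive genetic
#' value (planted QTL effects plus a kinship-structured polygenic term,
#' scaled so that `Va / (Va + Ve)` hits each trait's `h2_target`), `L` and
#' `LY` are independent normal location and location-by-year effects, and
#' `e` is residual noise. Traits with `scale_type = "ordinal"` are emitted
#' by thresholding the latent record value onto the integer `lo..hi` scale
#' at equal-probability cutpoints; `"percent"` traits are mapped onto
#' `[lo, hi]` through the latent normal CDF.
#'
#' @param geno A `genotype_matrix` from [simulate_genotypes()].
#' @param design A design tibble from [simulate_design()].
#' @param config The [sim_config()] used to create both.
#' @return A list with `phenotypes` (tibble: `entry`, `location`, `year`,
#'   `trait`, `value`) and `truth` (class `sim_truth`): true breeding
#'   values, planted QTL effects, realized per-trait heritability, subpop
#'   labels, and the drawn location / location-by-year effects.
#' @export
simulate_phenotypes <- function(geno, design, config) {
  stopifnot(inherits(config, "sim_config"), inherits(geno, "genotype_matrix"))
  if (nrow(design) == 0) {
    stop_sparsemet("`design` is empty.", "sparsemet_parameter_error")
  }
  specs <- config$trait_specs
  if (nrow(specs) == 0) {
    stop_sparsemet("`trait_specs` is empty.", "sparsemet_parameter_error")
  }
  if (any(specs$h2_target == 1 & config$var_error > 0)) {
    stop_sparsemet("h2_target = 1 is inconsistent with var_error > 0.",
                   "sparsemet_parameter_error")
  }
  with_seed(child_seed(config$seed, 37L), {
    n <- length(geno$entry_ids)
    nt <- nrow(specs)
    X <- geno$dosages
    m <- ncol(X)

    qtl <- config$planted_qtl %||% plant_default_qtl(config, m)
    B <- as.matrix(qtl[, specs$name, drop = FALSE])  # n_qtl x traits

    K <- vanraden_kinship(geno)
    eK <- K$eigen
    sd_scale <- sqrt(pmax(eK$values, 0))
    mean_diag <- mean(diag(K$values))

    g_mat <- matrix(0, n, nt, dimnames = list(geno$entry_ids, specs$name))
    realized_h2 <- numeric(nt)
    B_used <- B
    for (t in seq_len(nt)) {
      ve <- config$var_error[t]
      h2 <- specs$h2_target[t]
      g_qtl <- if (nrow(qtl) > 0) {
        as.numeric(X[, qtl$snp_index, drop = FALSE] %*% B[, t])
      } else {
        numeric(n)
      }
      if (h2 == 0) {
        g <- numeric(n)
        B_used[, t] <- 0
      } else if (ve == 0) {
        g <- g_qtl
      } else {
        va_target <- h2 / (1 - h2) * ve
        v_qtl <- var(g_qtl)
        if (v_qtl > va_target && v_qtl > 0) {
          # planted effects alone exceed the target additive variance:
          # shrink magnitudes (signs preserved) to fit
          fac <- sqrt(va_target / v_qtl)
          g_qtl <- g_qtl * fac
          B_used[, t] <- B[, t] * fac
          v_qtl <- va_target
        }
        s2_poly <- max(0, va_target - v_qtl) / mean_diag
        u <- as.numeric(eK$vectors %*% (sd_scale * rnorm(n))) * sqrt(s2_poly)
        g <- g_qtl + u
      }
      g_mat[, t] <- g
      tot <- var(g) + ve
      realized_h2[t] <- if (tot > 0) var(g) / tot else 0
    }

    # location and location-by-year effects per trait
    locs <- sort(unique(design$location))
    ly <- design %>% distinct(location, year) %>% arrange(location, year)
    loc_eff <- matrix(rnorm(length(locs) * nt), length(locs), nt) *
      rep(sqrt(config$var_location), each = length(locs))
    dimnames(loc_eff) <- list(locs, specs$name)
    ly_eff <- matrix(rnorm(nrow(ly) * nt), nrow(ly), nt) *
      rep(sqrt(config$var_locyear), each = nrow(ly))
    ly_key <- paste(ly$location, ly$year)
    rownames(ly_eff) <- ly_key

    idx_e <- match(design$entry, geno$entry_ids)
    idx_l <- match(design$location, locs)
    idx_ly <- match(paste(design$location, design$year), ly_key)
    nrec <- nrow(design)

    tabs <- vector("list", nt)
    for (t in seq_len(nt)) {
      e <- rnorm(nrec, sd = sqrt(config$var_error[t]))
      latent <- specs$mu[t] + g_mat[idx_e, t] + loc_eff[idx_l, t] +
        ly_eff[idx_ly, t] + e
      tabs[[t]] <- tibble(
        entry = design$entry, location = design$location,
        year = design$year, trait = specs$name[t],
        value = emit_scale(latent, specs$scale_type[t],
                           specs$lo[t], specs$hi[t])
      )
    }

    truth <- structure(
      list(
        true_breeding_values = g_mat,
        qtl_effects = dplyr::bind_cols(
          tibble(snp_index = qtl$snp_index,
                 snp = geno$snp_map$snp[qtl$snp_index],
                 group_id = qtl$group_id),
          as_tibble(B_used)
        ),
        realized_h2 = setNames(realized_h2, specs$name),
        subpop_labels = geno$subpop,
        location_effects = loc_eff,
        locyear_effects = ly_eff,
        var_error = setNames(config$var_error, specs$name)
      ),
      class = "sim_truth"
    )
    list(phenotypes = bind_rows(tabs), truth = truth)
  })
}

# Latent-to-observed mapping per trait scale.
emit_scale <- function(latent, kind, lo, hi) {
  if (kind == "continuous" || sd(latent) == 0) return(latent)
  z <- (latent - mean(latent)) / sd(latent)
  if (kind == "percent") {
    lo <- if (is.na(lo)) 0 else lo
    hi <- if (is.na(hi)) 100 else hi
    return(lo + (hi - lo) * pnorm(z))
  }
  if (kind == "ordinal") {
    levels <- seq(lo, hi)
    cuts <- quantile(z, probs = seq_len(length(levels) - 1) / length(levels))
    return(levels[findInterval(z, cuts) + 1])
  }
  stop_sparsemet(sprintf("Unknown scale_type '%s'.", kind),
                 "sparsemet_parameter_error")
}

# Default planted QTL: per trait group, n_qtl_per_group SNPs drawn away
# from block edges; each QTL carries one sign shared by all traits of its
# group (magnitude = qtl_effect_size residual SDs of each trait), and zero
# effect on other groups.
plant_default_qtl <- function(config, n_snps) {
  specs <- config$trait_specs
  groups <- sort(unique(specs$group_id))
  per <- config$n_qtl_per_group
  if (per == 0) {
    out <- tibble(snp_index = integer(0), group_id = integer(0))
    for (nm in specs$name) out[[nm]] <- numeric(0)
    return(out)
  }
  idx <- sample(n_snps, per * length(groups))
  rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    take <- idx[seq((gi - 1) * per + 1, gi * per)]
    signs <- sample(c(-1, 1), per, replace = TRUE)
    eff <- matrix(0, per, nrow(specs))
    in_g <- specs$group_id == g
    eff[, in_g] <- signs %o% (config$qtl_effect_size *
                                sqrt(config$var_error[in_g]))
    colnames(eff) <- specs$name
    rows[[gi]] <- dplyr::bind_cols(
      tibble(snp_index = take, group_id = g), as_tibble(eff)
    )
  }
  bind_rows(rows)
}

#' Simulate a complete sparse-MET data set
#'
#' Convenience wrapper running [simulate_genotypes()], [simulate_design()]
#' and [simulate_phenotypes()] from one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes`, `design`, `phenotypes`, `truth`, `config`.
#' @export
#' @examples
#' sim <- simulate_met(sim_config(n_entries = 50, n_snps = 300, n_years = 8,
#'                                entries_per_year_range = c(10, 25),
#'                                locations_per_year_range = c(3, 6),
#'                                seed = 7))
#' names(sim)
simulate_met <- function(config) {
  geno <- simulate_genotypes(config)
  design <- simulate_design(config)
  ph <- simulate_phenotypes(geno, design, config)
  list(genotypes = geno, design = design,
       phenotypes = ph$phenotypes, truth = ph$truth, config = config)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$true_breeding_values), " entries x ",
      ncol(x$true_breeding_values), " traits; ",
      nrow(x$qtl_effects), " planted QTL; realized h2 ",
      paste(sprintf("%.2f", x$realized_h2), collapse = ", "), "\n", sep = "")
  invisible(x)
}
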