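#' Simulation configuration for a sparse multi-environment trial
#'
#' Bundles every knob of the synthetic-data generator: a structured inbred
#' diversity panel (Balding-Nichols subpopulations, blockwise linkage
#' disequilibrium), a sparse entry x location x year trial design, and
#' additive phenotypes with location and location-by-year effects plus
#' planted pleiotropic QTL organized in trait groups.
#'
#' Defaults emulate a long-running cooperative bean nursery: 327 inbred
#' entries in three subpopulations, 16-61 entries and 10-28 locations used
#' per year, a median of two years of testing per entry, and eight traits
#' whose narrow-sense heritabilities span 0.067-0.733 in two pleiotropy
#' groups (architecture-like and disease-like).
#'
#' @param n_entries Number of germplasm entries in the genotyped panel.
#' @param n_subpops Number of subpopulations (races / gene pools).
#' @param fst Balding-Nichols divergence of subpopulation allele
#'   frequencies from the ancestral frequency, in `[0, 1)`.
#' @param inbreeding Within-entry inbreeding coefficient in `[0, 1]`;
#'   1 gives fully homozygous lines.
#' @param n_snps Number of biallelic SNPs.
#' @param ld_block_size SNPs per linkage block; within a block adjacent
#'   SNPs are copies of the block head perturbed at `flip_prob`.
#' @param flip_prob Per-site probability that a copied SNP is re-drawn,
#'   controlling within-block r-squared.
#' @param n_locations Total locations available to the trial network.
#' @param n_years Number of trial years (calendar years start at
#'   `first_year`).
#' @param first_year Calendar year of the first trial.
#' @param entries_per_year_range Integer `(min, max)` entries grown per year.
#' @param locations_per_year_range Integer `(min, max)` locations used per year.
#' @param years_per_entry_median Target median number of distinct years an
#'   entry is tested; participation runs are geometric.
#' @param trait_specs Tibble with columns `name`, `h2_target`, `scale_type`
#'   (one of `"continuous"`, `"percent"`, `"ordinal"`), `lo`, `hi`
#'   (scale bounds, used for `percent`/`ordinal`), `mu` (trait mean) and
#'   `group_id` (pleiotropy group). `NULL` gives the eight-trait default.
#' @param var_location,var_locyear,var_error Variance components per trait
#'   (recycled if scalar), in squared trait units.
#' @param planted_qtl Optional tibble with column `snp_index` plus one
#'   effect column per trait (trait units). `NULL` plants
#'   `n_qtl_per_group` QTL per trait group with group-shared sign patterns.
#' @param n_qtl_per_group,qtl_effect_size Used when `planted_qtl` is `NULL`:
#'   number of QTL planted per trait group, and allelic effect magnitude in
#'   residual-SD units of each affected trait.
#' @param seed Integer seed; all generator randomness flows from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_entries = 60, n_snps = 500, n_years = 6, seed = 1)
#' str(cfg$trait_specs)
sim_config <- function(n_entries = 327L,
                       n_subpops = 3L,
                       fst = 0.25,
                       inbreeding = 0.95,
                       n_snps = 5000L,
                       ld_block_size = 10L,
                       flip_prob = 0.02,
                       n_locations = 30L,
                       n_years = 20L,
                       first_year = 1981L,
                       entries_per_year_range = c(16L, 61L),
                       locations_per_year_range = c(10L, 28L),
                       years_per_entry_median = 2L,
                       trait_specs = NULL,
                       var_location = NULL,
                       var_locyear = NULL,
                       var_error = NULL,
                       planted_qtl = NULL,
                       n_qtl_per_group = 3L,
                       qtl_effect_size = 0.75,
                       seed = 1L) {
  n_entries <- check_count(n_entries, "n_entries")
  n_subpops <- check_count(n_subpops, "n_subpops")
  n_snps <- check_count(n_snps, "n_snps")
  ld_block_size <- check_count(ld_block_size, "ld_block_size")
  n_locations <- check_count(n_locations, "n_locations")
  n_years <- check_count(n_years, "n_years")
  check_fraction(fst, "fst", 0, 1, hi_open = TRUE)
  check_fraction(inbreeding, "inbreeding", 0, 1)
  check_fraction(flip_prob, "flip_prob", 0, 1)

  epr <- as.integer(entries_per_year_range)
  lpr <- as.integer(locations_per_year_range)
  if (length(epr) != 2 || epr[1] < 1 || epr[1] > epr[2] || epr[2] > n_entries) {
    stop_sparsemet("`entries_per_year_range` must be (min, max) within [1, n_entries].",
                   "sparsemet_parameter_error")
  }
  if (length(lpr) != 2 || lpr[1] < 1 || lpr[1] > lpr[2] || lpr[2] > n_locations) {
    stop_sparsemet("`locations_per_year_range` must be (min, max) within [1, n_locations].",
                   "sparsemet_parameter_error")
  }

  if (is.null(trait_specs)) {
    trait_specs <- default_trait_specs()
  }
  trait_specs <- as_tibble(trait_specs)
  needed <- c("name", "h2_target", "scale_type", "group_id")
  if (!all(needed %in% names(trait_specs)) || nrow(trait_specs) == 0) {
    stop_sparsemet("`trait_specs` needs columns name, h2_target, scale_type, group_id.",
                   "sparsemet_parameter_error")
  }
  if (!"mu" %in% names(trait_specs)) trait_specs$mu <- 0
  if (!"lo" %in% names(trait_specs)) trait_specs$lo <- NA_real_
  if (!"hi" %in% names(trait_specs)) trait_specs$hi <- NA_real_
  if (any(trait_specs$h2_target < 0 | trait_specs$h2_target > 1)) {
    stop_sparsemet("h2_target values must lie in [0, 1].",
                   "sparsemet_parameter_error")
  }
  nt <- nrow(trait_specs)
  rec <- function(x, default) {
    x <- x %||% default
    if (length(x) == 1) x <- rep(x, nt)
    if (length(x) != nt) {
      stop_sparsemet("Variance components must have length 1 or n_traits.",
                     "sparsemet_parameter_error")
    }
    x
  }
  var_location <- rec(var_location, 0.5)
  var_locyear <- rec(var_locyear, 0.5)
  var_error <- rec(var_error, 1)
  if (any(trait_specs$h2_target == 1 & var_error > 0)) {
    stop_sparsemet("h2_target = 1 is inconsistent with var_error > 0.",
                   "sparsemet_parameter_error")
  }

  structure(
    list(
      n_entries = n_entries, n_subpops = n_subpops, fst = fst,
      inbreeding = inbreeding, n_snps = n_snps,
      ld_block_size = ld_block_size, flip_prob = flip_prob,
      n_locations = n_locations, n_years = n_years, first_year = first_year,
      entries_per_year_range = epr, locations_per_year_range = lpr,
      years_per_entry_median = check_count(years_per_entry_median,
                                           "years_per_entry_median"),
      trait_specs = trait_specs,
      var_location = var_location, var_locyear = var_locyear,
      var_error = var_error,
      planted_qtl = planted_qtl,
      n_qtl_per_group = check_count(n_qtl_per_group, "n_qtl_per_group", 0),
      qtl_effect_size = qtl_effect_size,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Eight traits spanning the heritability range of a real nursery panel,
# split into an architecture-like and a disease-like pleiotropy group.
default_trait_specs <- function() {
  tibble(
    name = c("seed_yield", "growth_habit", "lodging", "rust_score",
             "days_to_flowering", "seed_weight", "zinc_deficiency",
             "seed_appearance"),
    h2_target = c(0.193, 0.509, 0.344, 0.621, 0.434, 0.685, 0.733, 0.067),
    scale_type = c("continuous", "ordinal", "ordinal", "ordinal",
                   "continuous", "continuous", "ordinal", "ordinal"),
    lo = c(NA, 1, 1, 1, NA, NA, 1, 1),
    hi = c(NA, 3, 5, 9, NA, NA, 9, 3),
    mu = c(2500, 2, 3, 5, 45, 300, 5, 2),
    group_id = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_entries, " entries / ", x$n_subpops,
      " subpops (fst ", x$fst, "), ", x$n_snps, " SNPs, ",
      x$n_years, " years x ", x$n_locations, " locations, ",
      nrow(x$trait_specs), " traits, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
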