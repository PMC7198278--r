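# End-to-end orchestration: simulate (optional) -> standardize -> kinship
# -> BLUP per trait -> association scans (per trait, plus earliest-year)
# -> multivariate shrinkage -> sharing and catalog overlap. Progress and
# stage timers go to stderr; every output file is stamped with the seed
# and a parameter hash so reruns are byte-identical.

#' Build a pipeline configuration
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Global seed; all stage randomness derives from it.
#' @param sim A [sim_config()] for the simulation stage, or `NULL` to read
#'   genotypes/phenotypes from `genotype_path`/`phenotype_path` instead.
#' @param genotype_path,phenotype_path Input paths when `sim` is `NULL`
#'   (VCF and long-format TSV).
#' @param registry Scale registry (see [read_scale_registry()]), a path to
#'   a YAML registry, or an empty list for no harmonization.
#' @param gwas A [gwas_config()].
#' @param n_random,n_strong_per_trait Shrinkage SNP-set sizes (see
#'   [build_snp_sets()]).
#' @param write_vcf Also write genotypes as VCF? (TSV dosages are always
#'   written.)
#' @param log Log stage progress to stderr?
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, sim = sim_config(),
                            genotype_path = NULL, phenotype_path = NULL,
                            registry = list(), gwas = gwas_config(),
                            n_random = 2000, n_strong_per_trait = 100,
                            write_vcf = FALSE, log = TRUE) {
  if (!is.character(out_dir) || length(out_dir) != 1) {
    stop_sparsemet("`out_dir` must be a single path.",
                   "sparsemet_parameter_error")
  }
  check_count(seed, "seed")
  if (is.null(sim)) {
    for (fld in c("genotype_path", "phenotype_path")) {
      val <- get(fld)
      if (is.null(val)) {
        stop_sparsemet(
          sprintf("Without a simulation config, `%s` is required.", fld),
          "sparsemet_parameter_error")
      }
      if (!file.exists(val)) {
        stop_sparsemet(sprintf("`%s` does not exist: %s", fld, val),
                       "sparsemet_parameter_error")
      }
    }
  }
  if (is.character(registry)) registry <- read_scale_registry(registry)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
         genotype_path = genotype_path, phenotype_path = phenotype_path,
         registry = registry, gwas = gwas, n_random = n_random,
         n_strong_per_trait = n_strong_per_trait, write_vcf = write_vcf,
         log = log),
    class = "pipeline_config"
  )
}

pipeline_log <- function(config, fmt, ...) {
  if (isTRUE(config$log)) {
    message(sprintf(paste0("[sparsemet] ", fmt), ...))
  }
}

run_stage <- function(config, name, fun) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(fun(), error = function(e) {
    stop_sparsemet(
      sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      "sparsemet_stage_error")
  })
  pipeline_log(config, "stage %-12s done in %.1fs", name,
               proc.time()[["elapsed"]] - t0)
  out
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> standardize -> kinship -> BLUP per
#' trait -> association scan per trait plus the earliest-year phenotype ->
#' multivariate shrinkage -> sharing and catalog overlap. All file outputs
#' carry the seed and a parameter hash; a rerun with the same
#' configuration and seed reproduces every output byte for byte. A stage
#' failure aborts with the stage name; outputs of earlier stages are kept.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a `pipeline_result`: `manifest` (also written as
#'   YAML), `scans`, `blups`, `mash`, `sharing`, `overlap`, and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  paths <- list()
  counts <- list()

  # --- simulate / load -------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- run_stage(config, "simulate", function() {
      cfg <- config$sim
      cfg$seed <- seed
      simulate_met(cfg)
    })
    geno <- sim$genotypes
    pheno <- sim$phenotypes
    paths$dosages <- file.path(config$out_dir, "dosages.tsv")
    write_dosage_tsv(geno, paths$dosages, seed = seed)
    if (isTRUE(config$write_vcf)) {
      paths$vcf <- file.path(config$out_dir, "genotypes.vcf")
      write_vcf(geno, paths$vcf, seed = seed)
    }
    paths$phenotypes_raw <- file.path(config$out_dir, "phenotypes_raw.tsv")
    write_phenotype_tsv(pheno, paths$phenotypes_raw, seed = seed)
  } else {
    geno <- run_stage(config, "load", function() read_vcf(config$genotype_path))
    pheno <- read_phenotype_tsv(config$phenotype_path)
  }
  counts$entries <- length(geno$entry_ids)
  counts$snps <- nrow(geno$snp_map)
  counts$phenotype_records <- nrow(pheno)

  # --- standardize ------------------------------------------------------
  std <- run_stage(config, "standardize", function() {
    standardize_phenotypes(pheno, config$registry)
  })
  counts$standardized_records <- nrow(std)
  paths$phenotypes <- file.path(config$out_dir, "phenotypes.tsv")
  write_phenotype_tsv(std, paths$phenotypes, seed = seed)

  # --- kinship ----------------------------------------------------------
  kin <- run_stage(config, "kinship", function() {
    geno <<- maf_filter(geno, 0.05)
    vanraden_kinship(geno)
  })
  counts$snps_after_maf <- nrow(geno$snp_map)
  paths$kinship <- file.path(config$out_dir, "kinship.tsv")
  write_kinship_tsv(kin, paths$kinship, seed = seed)

  # --- BLUP per trait ---------------------------------------------------
  traits <- sort(unique(std$trait))
  blups <- run_stage(config, "blup", function() {
    fit_all_blups(std, kin, traits)
  })
  counts$traits <- length(traits)
  paths$blups <- file.path(config$out_dir, "blups.tsv")
  blup_tab <- purrr::map_dfr(blups, tidy, .id = "trait")
  readr::write_lines(
    c(io_header(seed, params_hash(traits)),
      readr::format_tsv(blup_tab)),
    paths$blups)

  # --- association scans ------------------------------------------------
  scans <- run_stage(config, "gwas", function() {
    Km <- kinship_values(kin)
    max_pcs <- min(config$gwas$max_pcs, length(kin$entry_ids) - 2)
    pcs <- genotype_pca(subset_entries(geno, kin$entry_ids), max_pcs)
    scan_one <- function(y) {
      ids <- intersect(rownames(pcs), names(y)[!is.na(y)])
      k <- select_pcs_bic(as.numeric(y[ids]), pcs[ids, , drop = FALSE],
                          Km[ids, ids], max_pcs)
      mlm_scan(y, geno, kin, n_pcs = k, config = config$gwas)
    }
    per_trait <- lapply(blups, function(b) {
      scan_one(stats::setNames(b$blups$blup, b$blups$entry))
    })
    per_trait$earliest_year <- scan_one(earliest_year_phenotype(std))
    per_trait
  })
  counts$fdr_hits <- vapply(scans, function(s) sum(s$fdr_significant),
                            integer(1))
  paths$associations <- file.path(config$out_dir, "associations.tsv")
  assoc_tab <- bind_rows(scans, .id = "phenotype")
  readr::write_lines(
    c(io_header(seed, params_hash(names(scans))),
      readr::format_tsv(assoc_tab)),
    paths$associations)

  # --- multivariate shrinkage --------------------------------------------
  mash <- run_stage(config, "mash", function() {
    panel <- build_effect_panel(scans, geno)
    sets <- suppressWarnings(build_snp_sets(
      scans, geno, n_random = config$n_random,
      n_strong_per_trait = config$n_strong_per_trait,
      seed = child_seed(seed, 7L)))
    run_mash(panel, sets$random, sets$strong)
  })
  counts$strong_snps <- length(mash$posterior$snp_ids)
  counts$lfsr_hits <- vapply(
    seq_along(mash$posterior$phenotypes),
    function(j) sum(mash$posterior$lfsr[, j] <= 0.05), integer(1))
  names(counts$lfsr_hits) <- mash$posterior$phenotypes
  paths$posterior <- file.path(config$out_dir, "posterior.tsv")
  readr::write_lines(
    c(io_header(seed, params_hash(counts$strong_snps)),
      readr::format_tsv(tidy(mash$posterior))),
    paths$posterior)

  # --- sharing and catalog overlap ---------------------------------------
  overlap <- run_stage(config, "overlap", function() {
    cat_ <- read_association_catalog()
    pub <- filter(cat_, source_class == "published")
    g200 <- group_associations(pub, threshold_kb = 200)
    g20 <- group_associations(pub, threshold_kb = 20,
                              require_same_gene = TRUE)
    list(
      published = nrow(pub),
      in_regions_200kb = attr(g200, "n_in_multi"),
      regions_200kb = attr(g200, "n_regions_multi"),
      in_regions_20kb_gene = attr(g20, "n_in_multi"),
      regions_20kb_gene = attr(g20, "n_regions_multi")
    )
  })
  paths$sharing <- file.path(config$out_dir, "sharing.tsv")
  sh <- mash$sharing
  readr::write_lines(
    c(io_header(seed, params_hash(dim(sh))),
      readr::format_tsv(bind_cols(tibble(phenotype = rownames(sh)),
                                  as_tibble(sh)))),
    paths$sharing)

  # --- manifest -----------------------------------------------------------
  manifest <- list(
    package = "sparsemet",
    version = as.character(utils::packageVersion("sparsemet")),
    seed = seed,
    params_hash = params_hash(config[setdiff(
      names(config), c("out_dir", "log", "genotype_path", "phenotype_path"))]),
    counts = lapply(counts, function(x) {
      if (is.null(names(x))) unname(x) else as.list(x)
    }),
    overlap = overlap,
    outputs = lapply(paths, basename)
  )
  paths$manifest <- file.path(config$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, paths$manifest)

  invisible(structure(
    list(manifest = manifest, scans = scans, blups = blups, mash = mash,
         sharing = mash$sharing, overlap = overlap, paths = paths),
    class = "pipeline_result"
  ))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed ", x$manifest$seed, "; ",
      x$manifest$counts$entries, " entries, ",
      x$manifest$counts$snps, " SNPs, ",
      x$manifest$counts$traits, " traits; outputs in ",
      dirname(x$paths$manifest), "\n", sep = "")
  invisible(x)
}
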