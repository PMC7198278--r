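# Comparison of detected associations against a catalog of previously
# reported associations: proximity clustering, overlap-rate contrasts, and
# effect-size contextualization.

#' Read an association catalog
#'
#' Reads a tab-separated catalog of marker-trait associations with columns
#' `source_class`, `fdr_flag`, `trait`, `study`, `chrom`, `pos_mb_start`,
#' `pos_mb_end`, `candidate_gene`. Positions are megabases; single-point
#' associations have `pos_mb_end == pos_mb_start` or `NA`.
#'
#' @param path Path to the TSV file. Defaults to the catalog bundled with
#'   the package.
#' @return Tibble with the columns above plus `pos_mb` (the interval
#'   midpoint used for proximity clustering).
#' @export
read_association_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "association_catalog.tsv",
                                package = "sparsemet", mustWork = TRUE)
  cat_ <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            source_class = readr::col_character(),
                            fdr_flag = readr::col_character(),
                            trait = readr::col_character(),
                            study = readr::col_character(),
                            chrom = readr::col_character(),
                            pos_mb_start = readr::col_double(),
                            pos_mb_end = readr::col_double(),
                            candidate_gene = readr::col_character()
                          ))
  need <- c("source_class", "trait", "study", "chrom", "pos_mb_start")
  if (!all(need %in% names(cat_))) {
    stop_sparsemet("Catalog is missing required columns.",
                   "sparsemet_parameter_error")
  }
  cat_ %>%
    mutate(pos_mb = ifelse(is.na(pos_mb_end), pos_mb_start,
                           (pos_mb_start + pos_mb_end) / 2))
}

#' Cluster associations by physical proximity
#'
#' Single-linkage clustering of associations within each chromosome:
#' two associations link when their positions are closer than
#' `threshold_kb` (strictly; a pair exactly at the threshold does not
#' link). Ranged associations are represented by their midpoint, and
#' positions are compared as whole kilobases to keep megabase rounding
#' from manufacturing spurious sub-kilobase distances. With
#' `require_same_gene`, two associations also need identical, non-missing
#' candidate genes to link.
#'
#' @param entries Tibble with at least `chrom`, `pos_mb` and (for the gene
#'   rule) `candidate_gene`.
#' @param threshold_kb Linking distance in kilobases.
#' @param require_same_gene Require matching candidate genes?
#' @return The input with a `region` column (`chrom:index`), plus
#'   attributes `n_regions_multi` (regions holding more than one entry)
#'   and `n_in_multi` (entries in those regions).
#' @export
group_associations <- function(entries, threshold_kb,
                               require_same_gene = FALSE) {
  check_count(threshold_kb, "threshold_kb")
  if (nrow(entries) == 0) {
    out <- mutate(entries, region = character(0))
    attr(out, "n_regions_multi") <- 0L
    attr(out, "n_in_multi") <- 0L
    return(out)
  }
  entries <- mutate(entries, .row = dplyr::row_number(),
                    .kb = round(pos_mb * 1000))
  pieces <- entries %>%
    group_by(chrom) %>%
    dplyr::group_map(function(df, key) {
      n <- nrow(df)
      adj <- abs(outer(df$.kb, df$.kb, "-")) < threshold_kb
      if (require_same_gene) {
        gene <- df$candidate_gene
        same <- outer(gene, gene, "==")
        same[is.na(same)] <- FALSE
        adj <- adj & same
      }
      diag(adj) <- TRUE
      # connected components (single linkage) by label propagation
      grp <- seq_len(n)
      repeat {
        new <- vapply(seq_len(n), function(i) min(grp[adj[i, ]]), integer(1))
        if (identical(new, grp)) break
        grp <- new
      }
      grp <- match(grp, sort(unique(grp)))
      mutate(df, region = paste0(key$chrom, ":", grp))
    }) %>%
    bind_rows()
  out <- arrange(pieces, .row) %>% select(-.row, -.kb)
  sizes <- table(out$region)
  attr(out, "n_regions_multi") <- sum(sizes > 1)
  attr(out, "n_in_multi") <- as.integer(sum(sizes[sizes > 1]))
  out
}

#' Contrast overlap rates between two sets of associations
#'
#' Pearson chi-squared test (without continuity correction) on the 2x2
#' table of overlapping vs non-overlapping counts in two association
#' sets, e.g. FDR-significant detections vs the remainder.
#'
#' @param hits_a,total_a Overlapping count and set size for set A.
#' @param hits_b,total_b Same for set B.
#' @return Tibble with `rate_a`, `rate_b`, `statistic`, `p_value`.
#' @export
#' @examples
#' overlap_rate_test(10, 100, 20, 100)  # statistic ~ 3.92
overlap_rate_test <- function(hits_a, total_a, hits_b, total_b) {
  for (v in c(hits_a, total_a, hits_b, total_b)) check_count(v, "count")
  if (hits_a > total_a || hits_b > total_b) {
    stop_sparsemet("Hits cannot exceed the set size.",
                   "sparsemet_parameter_error")
  }
  tab <- matrix(c(hits_a, total_a - hits_a,
                  hits_b, total_b - hits_b), 2, 2, byrow = TRUE)
  ts <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(rate_a = hits_a / total_a, rate_b = hits_b / total_b,
         statistic = unname(ts$statistic), p_value = unname(ts$p.value))
}

#' Effect size as a percentage of a median phenotype
#'
#' Expresses an allele-substitution effect relative to a median trait
#' value, rounded to one decimal place.
#'
#' @param effect Allele effect (trait units).
#' @param median_value Median trait value (same units, non-zero).
#' @return `round(100 * effect / median_value, 1)`.
#' @export
#' @examples
#' percent_yield_change(104, 2803)  # 3.7
#' percent_yield_change(104, 2038)  # 5.1
percent_yield_change <- function(effect, median_value) {
  if (!is.numeric(effect) || !is.numeric(median_value) ||
      any(median_value == 0)) {
    stop_sparsemet("`median_value` must be numeric and non-zero.",
                   "sparsemet_parameter_error")
  }
  round(100 * effect / median_value, 1)
}
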