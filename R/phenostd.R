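#' Define a trait scale
#'
#' @param name Scale label.
#' @param kind One of `"percent"`, `"ordinal"`, `"continuous"`.
#' @param lo,hi Scale endpoints (`lo < hi`).
#' @return A `scale_spec` list.
#' @export
#' @examples
#' scale_spec("lodging_pct", "percent", 0, 100)
scale_spec <- function(name, kind = c("percent", "ordinal", "continuous"),
                       lo, hi) {
  kind <- match.arg(kind)
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi) {
    stop_sparsemet("`lo` must be smaller than `hi`.",
                   "sparsemet_parameter_error")
  }
  structure(list(name = name, kind = kind, lo = lo, hi = hi),
            class = "scale_spec")
}

#' Harmonize a value between trait scales
#'
#' Affine map sending the source endpoints onto the target endpoints:
#' `to$lo + (to$hi - to$lo) * (value - from$lo) / (from$hi - from$lo)`.
#' Used to merge traits scored on different conventions (percent, 1-5,
#' 0-9, 1-9 scales) into one phenotype. Ordinal outputs are not rounded:
#' downstream mixed models treat them as continuous.
#'
#' @param value Numeric value(s) on the source scale.
#' @param from,to [scale_spec()] objects.
#' @return Value(s) on the target scale.
#' @export
#' @examples
#' pct <- scale_spec("pct", "percent", 0, 100)
#' ord5 <- scale_spec("score", "ordinal", 1, 5)
#' harmonize_scale(50, pct, ord5)  # 3
harmonize_scale <- function(value, from, to) {
  stopifnot(inherits(from, "scale_spec"), inherits(to, "scale_spec"))
  tolr <- 1e-9 * (from$hi - from$lo)
  bad <- which(value < from$lo - tolr | value > from$hi + tolr)
  if (length(bad) > 0) {
    stop_sparsemet(
      sprintf("Value %s out of range [%s, %s] of scale '%s' (record %d).",
              format(value[bad[1]]), format(from$lo), format(from$hi),
              from$name, bad[1]),
      "sparsemet_range_error"
    )
  }
  to$lo + (to$hi - to$lo) * (value - from$lo) / (from$hi - from$lo)
}

#' Remove outlier location-by-year cells for a trait
#'
#' Computes each location x year cell's mean, then Tukey fences over the
#' distribution of cell means (Q1 - 1.5 IQR, Q3 + 1.5 IQR). Every record
#' in an exceeding cell is dropped, for every entry in that cell, so a
#' mismeasured trial does not contribute a biased subsample. Duplicate
#' (entry, location, year) records are averaged before filtering.
#'
#' @param table Long-format phenotype tibble.
#' @param trait Trait to filter.
#' @return The filtered tibble, with attribute `"dropped_cells"` (tibble of
#'   the removed location x year cells and their means). With fewer than 4
#'   cells a warning is issued and the table is returned unfiltered.
#' @export
remove_outlier_cells <- function(table, trait) {
  tr <- trait
  this <- table %>% filter(trait == tr)
  rest <- table %>% filter(trait != tr)
  this <- this %>%
    group_by(entry, location, year, trait) %>%
    summarise(value = mean(value), .groups = "drop")

  cells <- this %>%
    group_by(location, year) %>%
    summarise(cell_mean = mean(value), .groups = "drop")
  if (nrow(cells) < 4) {
    warn(sprintf("Trait '%s' has %d location x year cells (< 4); no filtering.",
                 tr, nrow(cells)))
    out <- bind_rows(rest, this)
    attr(out, "dropped_cells") <- cells[0, ]
    return(out)
  }
  q <- quantile(cells$cell_mean, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  bad <- cells %>% filter(cell_mean < fences[1] | cell_mean > fences[2])
  kept <- this %>% anti_join(bad, by = c("location", "year"))
  out <- bind_rows(rest, kept)
  attr(out, "dropped_cells") <- bad
  out
}

#' Pairwise Pearson correlations between trait BLUPs
#'
#' @param blups Entry x trait matrix (see [blup_matrix()]); `NA` allowed.
#' @return Trait x trait correlation matrix (pairwise complete entries;
#'   unit diagonal; `NA` where a trait is constant or pairs are too few).
#' @export
correlate_blups <- function(blups) {
  blups <- as.matrix(blups)
  if (sum(stats::complete.cases(blups)) < 3 && nrow(blups) < 3) {
    stop_sparsemet("Need at least 3 entries.", "sparsemet_dimension_error")
  }
  suppressWarnings(
    cc <- cor(blups, use = "pairwise.complete.obs")
  )
  diag(cc) <- 1
  cc
}
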