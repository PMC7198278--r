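# Reporting helpers: plot-ready coordinate tables and the ggplot2 figures
# built on them. All numeric content lives in the coordinate functions so
# it can be tested without rendering.

#' Quantile-quantile coordinates for association p-values
#'
#' Expected quantiles use the midpoint convention
#' `expected_i = -log10((i - 0.5) / m)` for the i-th smallest of m
#' p-values.
#'
#' @param p Vector of p-values in (0, 1]; `NA` dropped; empty input gives
#'   an empty table.
#' @return Tibble with `expected` and `observed` (-log10 scale), both
#'   sorted ascending.
#' @export
#' @examples
#' qq_coordinates(c(0.5, 0.01, 0.2))
qq_coordinates <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) {
    return(tibble(expected = numeric(0), observed = numeric(0)))
  }
  if (any(p <= 0 | p > 1)) {
    stop_sparsemet("p-values must lie in (0, 1].", "sparsemet_range_error")
  }
  m <- length(p)
  tibble(
    expected = -log10((rev(seq_len(m)) - 0.5) / m),
    observed = -log10(sort(p, decreasing = TRUE))
  )
}

#' Membership-pattern counts for an UpSet-style summary
#'
#' Counts items by their exact membership pattern across named sets
#' (e.g. SNPs significant per phenotype). Pattern counts partition the
#' union, so they sum to the union size.
#'
#' @param sets Named list of character vectors.
#' @return Tibble with `pattern` (set names joined by `&`), `degree`
#'   (number of sets in the pattern), `count`; sorted by count descending.
#' @export
#' @examples
#' upset_counts(list(a = c("x", "y"), b = c("y", "z")))
upset_counts <- function(sets) {
  if (length(sets) == 0 || is.null(names(sets)) || any(names(sets) == "")) {
    stop_sparsemet("`sets` must be a non-empty named list.",
                   "sparsemet_parameter_error")
  }
  items <- unique(unlist(sets))
  if (length(items) == 0) {
    return(tibble(pattern = character(0), degree = integer(0),
                  count = integer(0)))
  }
  member <- vapply(sets, function(s) items %in% s, logical(length(items)))
  member <- matrix(member, nrow = length(items),
                   dimnames = list(items, names(sets)))
  pattern <- unname(apply(member, 1,
                          function(r) paste(names(sets)[r], collapse = "&")))
  tibble(pattern = pattern, degree = as.integer(unname(rowSums(member)))) %>%
    count(pattern, degree, name = "count") %>%
    arrange(dplyr::desc(count), pattern)
}

#' Manhattan plot of an association scan
#'
#' @param scan Association tibble from [mlm_scan()] (`chrom`, `pos`, `p`,
#'   `fdr_significant`).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, title = NULL) {
  chroms <- sort(unique(scan$chrom))
  offs <- c(0, cumsum(vapply(chroms, function(ch) {
    max(scan$pos[scan$chrom == ch]) + 1e6
  }, numeric(1))))
  d <- scan %>%
    mutate(
      x = pos + offs[match(chrom, chroms)],
      neglog10p = -log10(pmax(p, 1e-300)),
      chrom_parity = factor(match(chrom, chroms) %% 2)
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$neglog10p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chrom_parity),
                        size = 0.6, show.legend = FALSE) +
    ggplot2::geom_point(data = dplyr::filter(d, .data$fdr_significant),
                        colour = "red", size = 1.2) +
    ggplot2::scale_colour_manual(values = c("grey30", "grey60")) +
    ggplot2::labs(x = "Position", y = expression(-log[10](p)),
                  title = title) +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of association p-values
#'
#' @param p Vector of p-values.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_qq <- function(p, title = NULL) {
  d <- qq_coordinates(p)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)), title = title) +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise effect sharing
#'
#' @param sharing Matrix from [pairwise_sharing()].
#' @return A ggplot object.
#' @export
plot_sharing <- function(sharing) {
  d <- as.data.frame(as.table(sharing))
  names(d) <- c("phenotype_a", "phenotype_b", "share")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phenotype_a,
                                  y = .data$phenotype_b,
                                  fill = .data$share)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "shared") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
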