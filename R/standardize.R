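#' Read a YAML scale registry
#'
#' The registry maps source trait names to their scoring scale and the
#' harmonized target trait/scale, e.g.
#' ```yaml
#' lodging_pct:
#'   target: lodging
#'   from: {kind: percent, lo: 0, hi: 100}
#'   to:   {kind: ordinal, lo: 1, hi: 5}
#' ```
#'
#' @param path Path to the YAML file.
#' @return A named list of `(target, from, to)` entries with
#'   [scale_spec()] objects.
#' @export
read_scale_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(stats::setNames(names(raw), names(raw)), function(nm) {
    e <- raw[[nm]]
    list(
      target = e$target %||% nm,
      from = scale_spec(nm, e$from$kind, e$from$lo, e$from$hi),
      to = scale_spec(e$target %||% nm, e$to$kind, e$to$lo, e$to$hi)
    )
  })
}

#' Harmonize trait scales across a phenotype table
#'
#' Applies [harmonize_scale()] to every record whose trait appears in the
#' registry, renaming it to the registry's target trait so that variants
#' of one phenotype scored on different scales merge into a single trait.
#' Records for unlisted traits pass through unchanged.
#'
#' @param table Long-format phenotype tibble (`entry`, `location`, `year`,
#'   `trait`, `value`).
#' @param registry A registry from [read_scale_registry()] (or an
#'   equivalently shaped list).
#' @return The harmonized tibble.
#' @export
harmonize_table <- function(table, registry) {
  hit <- table$trait %in% names(registry)
  if (!any(hit)) return(table)
  done <- table[hit, ] %>%
    group_by(trait) %>%
    dplyr::group_modify(function(df, key) {
      e <- registry[[key$trait[[1]]]]
      df$value <- harmonize_scale(df$value, e$from, e$to)
      df
    }) %>%
    ungroup() %>%
    mutate(trait = vapply(trait, function(tr) registry[[tr]]$target,
                          character(1), USE.NAMES = FALSE))
  bind_rows(table[!hit, ], done) %>%
    select(entry, location, year, trait, value)
}

#' Standardize a phenotype table
#'
#' Full standardization stage: scale harmonization via the registry, then
#' per-trait removal of outlier location-by-year cells
#' ([remove_outlier_cells()]).
#'
#' @inheritParams harmonize_table
#' @return The standardized tibble with attribute `"dropped_cells"`
#'   (per-trait log of removed cells).
#' @export
standardize_phenotypes <- function(table, registry = list()) {
  out <- harmonize_table(table, registry)
  logs <- list()
  for (tr in sort(unique(out$trait))) {
    out <- remove_outlier_cells(out, tr)
    dropped <- attr(out, "dropped_cells")
    if (nrow(dropped) > 0) logs[[tr]] <- mutate(dropped, trait = tr)
  }
  attr(out, "dropped_cells") <- bind_rows(logs)
  out
}
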