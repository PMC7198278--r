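#' Simulate a sparse entry x location x year trial design
#'
#' Each year tests a uniformly drawn number of entries and locations within
#' the configured ranges; every selected entry is grown at every selected
#' location of that year. Entry participation is a carry-over process: an
#' entry tested in year `y` is retained in year `y+1` with a fixed
#' continuation probability, otherwise replaced by a new entry, which gives
#' geometric participation runs calibrated so the median number of distinct
#' years per tested entry matches `years_per_entry_median` (entries dropped
#' after a short stint, as in real nurseries).
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `entry`, `location`, `year`: one row per
#'   trial cell.
#' @export
#' @examples
#' d <- simulate_design(sim_config(n_entries = 60, n_snps = 10, seed = 2))
#' dplyr::count(d, year)
simulate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  med <- config$years_per_entry_median
  if (med > config$n_years) {
    stop_sparsemet("years_per_entry_median cannot exceed n_years.",
                   "sparsemet_parameter_error")
  }
  with_seed(child_seed(config$seed, 23L), {
    entry_ids <- sprintf("E%03d", seq_len(config$n_entries))
    loc_ids <- make_location_codes(config$n_locations)
    years <- config$first_year + seq_len(config$n_years) - 1L

    # continuation probability q: median geometric run length equals `med`
    # when q^(med-1) > 1/2 >= q^med
    q <- if (med == 1) 0.3 else exp(log(0.5) / (med - 0.5))

    epr <- config$entries_per_year_range
    lpr <- config$locations_per_year_range
    n_e <- sample(seq(epr[1], epr[2]), config$n_years, replace = TRUE)
    n_l <- sample(seq(lpr[1], lpr[2]), config$n_years, replace = TRUE)

    untested <- entry_ids
    prev <- character(0)
    rows <- vector("list", config$n_years)
    for (y in seq_len(config$n_years)) {
      kept <- prev[runif(length(prev)) < q]
      if (length(kept) > n_e[y]) kept <- sample(kept, n_e[y])
      need <- n_e[y] - length(kept)
      fresh <- character(0)
      if (need > 0) {
        if (length(untested) >= need) {
          fresh <- sample(untested, need)
        } else {
          fresh <- untested
          # panel exhausted: re-admit previously tested entries
          pool <- setdiff(entry_ids, c(kept, fresh))
          fresh <- c(fresh, sample(pool, need - length(fresh)))
        }
        untested <- setdiff(untested, fresh)
      }
      sel <- c(kept, fresh)
      locs <- sample(loc_ids, n_l[y])
      rows[[y]] <- tibble(
        entry = rep(sel, each = length(locs)),
        location = rep(locs, times = length(sel)),
        year = years[y]
      )
      prev <- sel
    }
    bind_rows(rows)
  })
}

# Four-letter location codes: two-letter state/province prefix plus a
# two-letter site code; a trailing "2" marks a second (treated) trial.
make_location_codes <- function(n) {
  states <- c("ND", "MI", "CO", "WA", "NE", "ID", "CA", "NY", "ON", "MB",
              "WI", "OR", "MN", "MT", "KS", "SK", "PR", "WY", "TX", "IA")
  site <- c("FA", "SA", "EA", "HA", "PR", "BR", "CR", "DR")
  codes <- as.vector(outer(states, site, paste0))
  if (n > length(codes)) {
    codes <- c(codes, paste0(codes, "2"))
  }
  codes[seq_len(n)]
}

#' Sparsity summary of a trial design
#'
#' @param design A design tibble from [simulate_design()] (or real data with
#'   the same columns).
#' @return A one-row tibble: entries and locations per year ranges, and the
#'   median number of distinct years per tested entry.
#' @export
design_summary <- function(design) {
  per_year <- design %>%
    group_by(year) %>%
    summarise(n_entries = dplyr::n_distinct(entry),
              n_locations = dplyr::n_distinct(location), .groups = "drop")
  yrs <- design %>%
    distinct(entry, year) %>%
    count(entry, name = "n_years")
  tibble(
    min_entries_per_year = min(per_year$n_entries),
    max_entries_per_year = max(per_year$n_entries),
    min_locations_per_year = min(per_year$n_locations),
    max_locations_per_year = max(per_year$n_locations),
    median_years_per_entry = median(yrs$n_years),
    n_cells = nrow(design)
  )
}
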