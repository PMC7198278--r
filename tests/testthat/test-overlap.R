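test_that("the bundled association catalog reads with expected structure", {
  cat_ <- read_association_catalog()
  expect_s3_class(cat_, "tbl_df")
  expect_identical(nrow(cat_), 114L)
  expect_identical(sum(cat_$source_class == "published"), 80L)
  expect_true(all(c("chrom", "pos_mb", "candidate_gene") %in% names(cat_)))
  # midpoint rule: ranged rows use the interval midpoint
  ranged <- dplyr::filter(cat_, !is.na(pos_mb_end),
                          pos_mb_end != pos_mb_start)
  expect_true(nrow(ranged) > 0)
  expect_equal(ranged$pos_mb, (ranged$pos_mb_start + ranged$pos_mb_end) / 2)
  point <- dplyr::filter(cat_, is.na(pos_mb_end))
  expect_equal(point$pos_mb, point$pos_mb_start)
  expect_error(read_association_catalog(tempfile()))
})

test_that("published catalog entries reproduce the 200-kb clustering", {
  cat_ <- read_association_catalog()
  pub <- dplyr::filter(cat_, source_class == "published")
  grp <- group_associations(pub, threshold_kb = 200)
  expect_identical(attr(grp, "n_regions_multi"), 6L)
  expect_identical(attr(grp, "n_in_multi"), 15L)
})

test_that("group_associations is strict at the threshold", {
  toy <- tibble::tibble(chrom = "Pv01", pos_mb = c(1.000, 1.020),
                        candidate_gene = NA_character_)
  at <- group_associations(toy, threshold_kb = 20)   # exactly 20 kb apart
  expect_identical(attr(at, "n_regions_multi"), 0L)
  just_in <- group_associations(toy, threshold_kb = 21)
  expect_identical(attr(just_in, "n_regions_multi"), 1L)
  expect_identical(attr(just_in, "n_in_multi"), 2L)
})

test_that("grouping is single-linkage within chromosomes only", {
  toy <- tibble::tibble(
    chrom = c("Pv01", "Pv01", "Pv01", "Pv02"),
    pos_mb = c(1.00, 1.15, 1.30, 1.00),
    candidate_gene = NA_character_
  )
  # chain: 1-2 and 2-3 link at 200 kb even though 1-3 are 300 kb apart
  grp <- group_associations(toy, threshold_kb = 200)
  expect_identical(grp$region[1], grp$region[2])
  expect_identical(grp$region[2], grp$region[3])
  expect_false(grp$region[4] == grp$region[1])  # other chromosome
  expect_identical(attr(grp, "n_regions_multi"), 1L)
  expect_identical(attr(grp, "n_in_multi"), 3L)
  # row order of the input is preserved
  expect_identical(grp$pos_mb, toy$pos_mb)
})

test_that("the same-gene rule blocks links between different genes", {
  toy <- tibble::tibble(
    chrom = "Pv01",
    pos_mb = c(1.00, 1.01, 1.02, 1.03),
    candidate_gene = c("GeneA", "GeneA", "GeneB", NA)
  )
  free <- group_associations(toy, threshold_kb = 100)
  expect_identical(attr(free, "n_in_multi"), 4L)
  strict <- group_associations(toy, threshold_kb = 100,
                               require_same_gene = TRUE)
  expect_identical(strict$region[1], strict$region[2])  # same gene links
  expect_false(strict$region[3] == strict$region[1])    # different gene
  expect_false(strict$region[4] == strict$region[1])    # NA gene never links
  expect_identical(attr(strict, "n_regions_multi"), 1L)
  expect_identical(attr(strict, "n_in_multi"), 2L)
})

test_that("group_associations handles empty input and bad thresholds", {
  empty <- tibble::tibble(chrom = character(0), pos_mb = numeric(0),
                          candidate_gene = character(0))
  out <- group_associations(empty, 100)
  expect_identical(nrow(out), 0L)
  expect_identical(attr(out, "n_regions_multi"), 0L)
  expect_error(group_associations(empty, -5),
               class = "sparsemet_parameter_error")
})

test_that("overlap_rate_test matches the uncorrected chi-squared", {
  res <- overlap_rate_test(10, 100, 20, 100)
  expect_equal(res$rate_a, 0.1)
  expect_equal(res$rate_b, 0.2)
  expect_equal(round(res$statistic, 2), 3.92)
  # hand check: X^2 = sum (O-E)^2/E on the 2x2 table
  o <- c(10, 90, 20, 80)
  e <- c(15, 85, 15, 85)
  expect_equal(res$statistic, sum((o - e)^2 / e))
  expect_error(overlap_rate_test(10, 5, 1, 10),
               class = "sparsemet_parameter_error")
  expect_error(overlap_rate_test(-1, 5, 1, 10),
               class = "sparsemet_parameter_error")
})

test_that("percent_yield_change reproduces the worked percentages", {
  expect_identical(percent_yield_change(104, 2803), 3.7)
  expect_identical(percent_yield_change(104, 2038), 5.1)
  expect_identical(percent_yield_change(-50, 1000), -5)
  expect_error(percent_yield_change(10, 0),
               class = "sparsemet_parameter_error")
  expect_error(percent_yield_change("x", 10),
               class = "sparsemet_parameter_error")
})
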