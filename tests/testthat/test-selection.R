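# Dense synthetic candidate supply: one candidate every 5 bp with
# deterministic pseudo-random dTm values.
dense_candidates <- function(chrom_length, oligo_length = 45L, step = 5L,
                             seed = 1L) {
  starts <- seq(0L, chrom_length - oligo_length, by = step)
  set.seed(seed)
  data.table::data.table(
    chrom = "c1", start = starts, end = starts + oligo_length,
    sequence = NA_character_, tm = 70,
    hairpin_tm = 70 - round(runif(length(starts), 11, 30), 3),
    dtm = 0)[, dtm := tm - hairpin_tm][]
}

test_that("adequate supply fills every bin at the requested density", {
  cand <- dense_candidates(10000L)
  ps <- select_by_density(cand, 10000, density_per_kb = 2)
  expect_identical(ps$n_bins, 20L)
  expect_identical(nrow(ps$probes), 20L)
  expect_length(ps$shortfall_bins, 0L)
  expect_equal(ps$bin_width, 500)
  # non-overlap and sortedness
  p <- ps$probes
  expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
})

test_that("each bin takes its best-dTm candidate, leftmost on ties", {
  cand <- data.table::data.table(
    chrom = "c1",
    start = c(0L, 100L, 200L, 600L, 700L),
    end = c(45L, 145L, 245L, 645L, 745L),
    sequence = NA_character_, tm = 70,
    hairpin_tm = c(55, 50, 50, 58, 58),
    dtm = c(15, 20, 20, 12, 12))
  ps <- select_by_density(cand, 1000, density_per_kb = 2)
  # bin 0: dtm 20 tie at starts 100/200 -> leftmost (100)
  # bin 1: dtm 12 tie at 600/700 -> 600
  expect_identical(ps$probes$start, c(100L, 600L))
})

test_that("no-hairpin candidates outrank every finite margin", {
  cand <- data.table::data.table(
    chrom = "c1", start = c(0L, 100L), end = c(45L, 145L),
    sequence = NA_character_, tm = 70, hairpin_tm = c(40, NA),
    dtm = c(30, Inf))
  ps <- select_by_density(cand, 500, density_per_kb = 2)
  expect_identical(ps$probes$start, 100L)
})

test_that("bins blocked by the previous selection become shortfall bins", {
  # bin 0's pick spills into bin 1, whose only candidate overlaps it
  cand <- data.table::data.table(
    chrom = "c1", start = c(480L, 510L), end = c(525L, 555L),
    sequence = NA_character_, tm = 70, hairpin_tm = c(50, 55),
    dtm = c(20, 15))
  ps <- select_by_density(cand, 1000, density_per_kb = 2)
  expect_identical(ps$probes$start, 480L)
  expect_identical(ps$shortfall_bins, 1L)
})

test_that("thinning to a target count keeps ends and spaces evenly", {
  cand <- dense_candidates(15000L, seed = 2L)
  full <- select_by_density(cand, 15000, density_per_kb = 2)
  expect_identical(nrow(full$probes), 30L)
  thinned <- select_by_density(cand, 15000, density_per_kb = 2,
                               target_count = 20)
  expect_identical(nrow(thinned$probes), 20L)
  # direct evaluation of the stated rule: even selection in genomic order
  expect_identical(thinned$probes$start,
                   full$probes$start[round(seq(1, 30, length.out = 20))])
  expect_identical(thinned$probes$start[1], full$probes$start[1])
  expect_identical(tail(thinned$probes$start, 1), tail(full$probes$start, 1))
})

test_that("physically impossible densities are rejected", {
  cand <- dense_candidates(1000L)
  expect_error(select_by_density(cand, 1000, density_per_kb = 25),
               "impossible")
})

test_that("unmasked-length density basis rescales the bin width", {
  cand <- dense_candidates(10000L)
  ps <- select_by_density(cand, 10000, density_per_kb = 2,
                          density_basis = "unmasked",
                          unmasked_length = 5000)
  expect_equal(ps$bin_width, 1000)
  expect_identical(nrow(ps$probes), 10L)
  expect_error(select_by_density(cand, 10000, density_per_kb = 2,
                                 density_basis = "unmasked"),
               "unmasked_length")
})

test_that("selection is deterministic", {
  cand <- dense_candidates(8000L, seed = 3L)
  a <- select_by_density(cand, 8000, density_per_kb = 2)
  b <- select_by_density(cand, 8000, density_per_kb = 2)
  expect_identical(a$probes, b$probes)
})

test_that("stage report telescopes", {
  rep <- stage_report(c(tiled = 100, mask_filter = 80,
                        uniqueness_filter = 50, dtm_filter = 30,
                        selected = 10))
  expect_identical(rep$survivors, c(100L, 80L, 50L, 30L, 10L))
  expect_identical(rep$eliminated, c(0L, 20L, 30L, 20L, 20L))
  expect_error(stage_report(c(a = 10, b = 20)), "non-increasing")

  # empty chromosome: all-zero report is valid
  z <- stage_report(c(tiled = 0, mask_filter = 0, uniqueness_filter = 0,
                      dtm_filter = 0, selected = 0))
  expect_true(all(z$survivors == 0L))
})
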