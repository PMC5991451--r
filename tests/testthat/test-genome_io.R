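test_that("FASTA reading records masking state and normalizes residues", {
  f <- write_tmp_fasta(c(">c1", "ACGTacgtNN"))
  seqs <- read_fasta(f)
  expect_length(seqs, 1L)
  expect_identical(seqs$c1$residues, "ACGTACGTNN")
  expect_identical(seqs$c1$mask,
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                     TRUE, TRUE))

  # ambiguity codes degrade to N with mask = TRUE
  f2 <- write_tmp_fasta(c(">c1", "ACRGT"))
  s2 <- read_fasta(f2)$c1
  expect_identical(s2$residues, "ACNGT")
  expect_identical(s2$mask, c(FALSE, FALSE, TRUE, FALSE, FALSE))

  # multi-record order preserved, wrapping irrelevant
  f3 <- write_tmp_fasta(c(">b", "ACGT", "ACGT", ">a", "GGGG"))
  s3 <- read_fasta(f3)
  expect_identical(names(s3), c("b", "a"))
  expect_identical(s3$b$residues, "ACGTACGT")
})

test_that("FASTA reader rejects malformed input with informative errors", {
  expect_error(read_fasta(write_tmp_fasta(character(0))), "empty")
  expect_error(read_fasta(write_tmp_fasta(c(">a", "ACGT", ">a", "GG"))),
               "duplicate")
  expect_error(read_fasta(write_tmp_fasta(c(">bad", "ACXGT"))), "bad")
})

test_that("FASTA round trip preserves residues and mask", {
  set.seed(11)
  g <- generate_genome(500, seed = 11, name = "chrZ")
  g <- plant_repeat(g, 100, 180)
  g$residues <- paste0(substr(g$residues, 1, 249), "N",
                       substring(g$residues, 251))
  g$mask[250] <- TRUE
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, f)
  back <- read_fasta(f)$chrZ
  expect_identical(back$residues, g$residues)
  expect_identical(back$mask, g$mask)
})

test_that("BED6 writer emits the documented format", {
  probes <- data.frame(chrom = "c1", start = 100L, end = 145L,
                       name = "p1", dtm = 15.0)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(probes, f)
  expect_identical(readLines(f), "c1\t100\t145\tp1\t15.00\t+")
  raw <- readChar(f, file.size(f), useBytes = TRUE)
  expect_identical(substr(raw, nchar(raw), nchar(raw)), "\n")

  # empty probe set -> empty file, success
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(probes[0, ], f2)
  expect_identical(file.size(f2), 0)

  # unsorted input is the caller's bug
  two <- data.frame(chrom = "c1", start = c(200L, 0L), end = c(245L, 45L),
                    name = c("a", "b"), dtm = c(1, 2))
  expect_error(write_bed(two, withr::local_tempfile()), "sorted")
})

test_that("BED reader handles headers and reports bad lines by number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=probes", "c1\t0\t45", "c1\t50\t95\tp2\t1.00\t+",
               "# comment", "c2\t10\t55"), f)
  bed <- read_bed(f)
  expect_identical(nrow(bed), 3L)
  expect_identical(bed$start, c(0L, 50L, 10L))

  writeLines(c("c1\t0\t45", "c1\t45\t45"), f)
  expect_error(read_bed(f), "line 2.*start >= end")
  writeLines("c1\t-5\t45", f)
  expect_error(read_bed(f), "negative")
  writeLines("c1\t45", f)
  expect_error(read_bed(f), "3 columns")
})

test_that("write/read BED round trip preserves coordinates exactly", {
  set.seed(3)
  starts <- sort(sample.int(100000, 50)) * 10L
  probes <- data.frame(chrom = "chr9", start = starts, end = starts + 45L,
                       name = sprintf("p%02d", 1:50),
                       dtm = round(runif(50, 10, 30), 2))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(probes, f)
  back <- read_bed(f)
  expect_identical(back$start, probes$start)
  expect_identical(back$end, probes$end)
  expect_equal(back$score, probes$dtm)
})

test_that("validate_bed checks widths, sort, overlap and bounds", {
  g <- generate_genome(2000, seed = 5, name = "c1")
  probes <- data.frame(chrom = "c1", start = c(0L, 500L, 1000L),
                       end = c(45L, 545L, 1045L),
                       name = c("a", "b", "c"), dtm = c(11, 12, 13))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(probes, f)
  v <- validate_bed(f, list(g))
  expect_identical(v$n_records, 3L)
  expect_identical(v$widths, 45L)
  expect_true(v$sorted && v$non_overlapping && v$within_bounds)

  # overlapping / out-of-bounds flagged
  writeLines(c("c1\t0\t45\ta\t1\t+", "c1\t40\t85\tb\t1\t+",
               "c1\t1990\t2035\tc\t1\t+"), f)
  v2 <- validate_bed(f, list(g))
  expect_false(v2$non_overlapping)
  expect_false(v2$within_bounds)
})
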