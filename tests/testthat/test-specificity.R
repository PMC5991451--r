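test_that("k-mer index counts and lookups behave", {
  g <- masked_seq("c1", paste0("ACGTACGT", random_dna(92, seed = 1)))
  idx <- build_kmer_index(g, k = 8)
  expect_identical(as.numeric(idx$n_positions), 100 - 8 + 1)
  occ <- kmer_occurrences(idx, "ACGTACGT")
  expect_true(0 %in% occ$start)

  # k-mers containing N never indexed
  gn <- masked_seq("c2", paste0(random_dna(20, seed = 2), "N",
                                random_dna(20)))
  idxn <- build_kmer_index(gn, k = 8)
  expect_identical(as.numeric(idxn$n_positions), 2 * (21 - 8))

  expect_error(build_kmer_index(g, k = 4), "between 8 and 31")
  expect_error(build_kmer_index(masked_seq("s", "ACGT"), k = 8), "length")
})

test_that("brute-force scan agrees with the plain-R oracle", {
  set.seed(10)
  for (trial in 1:5) {
    g <- list(a = masked_seq("a", random_dna(300)),
              b = masked_seq("b", random_dna(300)))
    oligo <- substring(g$a$residues, 101, 120)  # 20-mer from the genome
    got <- brute_force_homology(oligo, g, min_identity = 0.7)
    want <- naive_hits(oligo, genome_chars(g), 0.7)
    got <- got[order(got$chrom, got$start, got$strand)]
    want <- want[order(want$chrom, want$start, want$strand), ]
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$start, want$start)
    expect_identical(got$strand, want$strand)
    expect_identical(got$matches, as.integer(want$matches))
  }
})

test_that("planted copies around the 75% boundary resolve exactly", {
  g <- generate_genome(4000, seed = 20, name = "cA")
  # verbatim second copy: two full-identity hits
  d0 <- plant_duplication(g, 500, 545, 2500, n_substitutions = 0, seed = 1)
  oligo <- substring(d0$seq$residues, 501, 545)
  h0 <- brute_force_homology(oligo, d0$seq)
  full <- h0[h0$identity == 1 & h0$strand == "+", ]
  expect_identical(sort(full$start), c(500L, 2500L))

  # 11 substitutions: 34/45 >= 0.75, second locus still reported
  d11 <- plant_duplication(g, 500, 545, 2500, n_substitutions = 11, seed = 2)
  h11 <- brute_force_homology(substring(d11$seq$residues, 501, 545), d11$seq)
  expect_true(any(h11$start == 2500 & h11$matches == 34))

  # 12 substitutions: 33/45 < 0.75, no hit at the copy
  d12 <- plant_duplication(g, 500, 545, 2500, n_substitutions = 12, seed = 3)
  h12 <- brute_force_homology(substring(d12$seq$residues, 501, 545), d12$seq)
  expect_false(any(h12$start >= 2456 & h12$start <= 2544))
})

test_that("seeded search finds exact duplicates and emits no false positive", {
  g <- generate_genome(5000, seed = 30, name = "cA")
  d <- plant_duplication(g, 1000, 1045, 3000, n_substitutions = 0, seed = 1)
  oligo <- substring(d$seq$residues, 1001, 1045)
  loci <- find_homologous_loci(oligo, d$seq)
  expect_true(all(c(1000, 3000) %in% loci$start))
  expect_true(all(loci$identity >= 0.75))

  # just below threshold is never emitted (verification is exact)
  d12 <- plant_duplication(g, 1000, 1045, 3000, n_substitutions = 12, seed = 2)
  loci12 <- find_homologous_loci(substring(d12$seq$residues, 1001, 1045),
                                 d12$seq)
  expect_false(any(loci12$start >= 2956 & loci12$start <= 3044))
})

test_that("seeded search merges overlapping placements into one locus", {
  # tandem AT-repeat context produces many overlapping self-placements
  core <- paste0(strrep("ACGT", 20))
  g <- masked_seq("cA", paste0(random_dna(200, seed = 40), core,
                               random_dna(200)))
  oligo <- substr(core, 1, 45)
  loci <- find_homologous_loci(oligo, g, min_identity = 0.75)
  expect_gte(nrow(loci), 1L)
  # merged loci never overlap within a strand, and the seeded merge
  # agrees with merging the exhaustive scan
  for (str in unique(loci$strand)) {
    s <- loci[loci$strand == str]
    s <- s[order(s$start)]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  ref <- merge_hits_for_test(oligo, g)
  expect_identical(loci$start, ref$start)
  expect_identical(loci$strand, ref$strand)
  expect_identical(loci$matches, ref$matches)
})

test_that("uniqueness filter keeps single-copy and drops duplicated oligos", {
  fx <- make_fixture(seed = 7, chrom_length = 6000)
  g <- fx$genome
  cand <- mask_filter(tile_candidates(g$chrA), g$chrA)
  res <- uniqueness_filter(cand, g)
  expect_identical(nrow(res$kept) + sum(res$n_loci != 1L), nrow(cand))

  # oligos fully inside the cross-chromosome exact duplication are gone
  dup <- fx$manifest$planted_duplications[[1]]
  inside <- cand$start >= dup$source_start & cand$end <= dup$source_end
  expect_true(any(inside))
  expect_false(any(res$kept$start >= dup$source_start &
                     res$kept$end <= dup$source_end))

  # exact and heuristic agree on the survivor set
  res_exact <- uniqueness_filter(cand, g, exact = TRUE)
  expect_identical(res$kept$start, res_exact$kept$start)
})

test_that("reverse-complementing the genome leaves verdicts unchanged", {
  g <- generate_genome(3000, seed = 50, name = "cA")
  d <- plant_duplication(g, 400, 445, 2000, n_substitutions = 5, seed = 1)
  g <- d$seq
  cand <- tile_candidates(g)[seq(1, 500, by = 7)]
  v1 <- uniqueness_filter(cand, g, exact = TRUE)$n_loci

  grc <- masked_seq("cA", rc(g$residues))
  # same oligos, searched against the reverse-complemented assembly
  hits <- merge_hits_for_test(cand$sequence, grc)
  v2 <- vapply(seq_len(nrow(cand)), function(i) {
    h <- hits[hits$qid == i]
    # source locus maps to mirrored coordinates on the '-' strand
    L <- nchar(g$residues)
    src_start <- L - cand$end[i]
    is_src <- h$strand == "-" & h$start < src_start + 45 & h$end > src_start
    as.integer(any(is_src)) + sum(!is_src)
  }, 0L)
  expect_identical(v1, v2)
})
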