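# Seeded synthetic genomes with planted repeats, near-duplications and
# hairpins, plus a ground-truth manifest, so every pipeline stage is
# testable with no external data.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random unmasked chromosome
#'
#' Draws i.i.d. bases at the stated GC fraction from R's seeded
#' generator; a fixed seed reproduces the sequence bit-identically. The
#' default GC of 0.44 approximates a rice-like nuclear genome.
#'
#' @param length sequence length in bases.
#' @param gc_fraction expected fraction of G+C (G and C equiprobable).
#' @param seed integer RNG seed.
#' @param name sequence name.
#' @return a [masked_seq] with an all-`FALSE` mask.
#' @export
generate_genome <- function(length, gc_fraction = 0.44, seed = 1L,
                            name = "chrSim") {
  stopifnot(length > 0, gc_fraction >= 0, gc_fraction <= 1)
  bases <- with_seed(seed, sample(
    c("A", "C", "G", "T"), length, replace = TRUE,
    prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
             gc_fraction / 2, (1 - gc_fraction) / 2)))
  masked_seq(name, paste0(bases, collapse = ""))
}

replace_interval <- function(seq, start, insert) {
  # start 0-based; insert replaces length(insert) bases
  res <- seq$residues
  end <- start + nchar(insert)
  stopifnot(start >= 0, end <= nchar(res))
  seq$residues <- paste0(substr(res, 1, start), insert,
                         substring(res, end + 1))
  seq
}

#' Mark an interval as repeat-masked
#'
#' Emulates a RepeatMasker annotation: the bases keep their identity but
#' acquire `mask = TRUE` (written lowercase by [write_fasta()]).
#'
#' @param seq a [masked_seq].
#' @param start,end 0-based half-open interval.
#' @return the modified [masked_seq].
#' @export
plant_repeat <- function(seq, start, end) {
  stopifnot(inherits(seq, "masked_seq"), start >= 0, start < end,
            end <= nchar(seq$residues))
  seq$mask[(start + 1):end] <- TRUE
  seq
}

#' Plant a near-identical duplication
#'
#' Overwrites the target interval with a copy of the source interval
#' carrying exactly `n_substitutions` substitutions at seeded positions
#' (each substituted base is guaranteed to differ from the copied base).
#' With 45-bp intervals, 11 substitutions leave 34/45 ~ 75.6% identity
#' (still disqualifying at the 75% threshold) and 12 leave
#' 33/45 ~ 73.3% (below it).
#'
#' @param seq a [masked_seq] (source and target on the same sequence)
#'   or the target [masked_seq] when `source_seq` is given.
#' @param source_start,source_end 0-based half-open source interval.
#' @param target_start 0-based start of the overwritten interval (same
#'   width as the source). Source and target must be disjoint when on
#'   the same sequence.
#' @param n_substitutions number of substituted positions.
#' @param seed integer RNG seed for substitution placement.
#' @param source_seq optional [masked_seq] to copy from, for
#'   cross-chromosome duplications.
#' @return list with `seq` (modified target sequence) and `record`
#'   (manifest entry: source, target, `n_substitutions`).
#' @export
plant_duplication <- function(seq, source_start, source_end, target_start,
                              n_substitutions = 0L, seed = 1L,
                              source_seq = NULL) {
  src <- if (is.null(source_seq)) seq else source_seq
  len <- source_end - source_start
  stopifnot(len > 0, n_substitutions >= 0, n_substitutions <= len,
            source_end <= nchar(src$residues),
            target_start + len <= nchar(seq$residues))
  same <- is.null(source_seq) || identical(src$name, seq$name)
  if (same && target_start < source_end && target_start + len > source_start)
    stop("source and target intervals overlap")
  copy <- strsplit(substring(src$residues, source_start + 1, source_end),
                   "", fixed = TRUE)[[1]]
  if (n_substitutions > 0) {
    subs <- with_seed(seed, {
      pos <- sample.int(len, n_substitutions)
      repl <- vapply(copy[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      list(pos = pos, repl = repl)
    })
    copy[subs$pos] <- subs$repl
  }
  seq <- replace_interval(seq, target_start, paste0(copy, collapse = ""))
  list(seq = seq,
       record = list(source_chrom = src$name, source_start = source_start,
                     source_end = source_end, target_chrom = seq$name,
                     target_start = target_start,
                     target_end = target_start + len,
                     n_substitutions = as.integer(n_substitutions)))
}

#' Plant a hairpin-forming palindrome
#'
#' Writes `STEM + loop + reverse-complement(STEM)` at the given
#' position, with a seeded random stem and loop. Oligos spanning the
#' palindrome acquire a strong intramolecular stem and fail the dTm
#' screen under default settings once the stem is long enough
#' (12 bp at 50 mM monovalent comfortably exceeds the 10 degree
#' margin). `stem_len = 0` leaves the genome unchanged.
#'
#' @param seq a [masked_seq].
#' @param position 0-based start of the palindromic insert.
#' @param stem_len stem length in bases.
#' @param loop_len loop length in bases.
#' @param seed integer RNG seed for the stem and loop content.
#' @return list with `seq` and `record` (interval, stem and loop
#'   lengths, the stem sequence).
#' @export
plant_hairpin <- function(seq, position, stem_len = 12L, loop_len = 5L,
                          seed = 1L) {
  stopifnot(stem_len >= 0, loop_len >= 0,
            position + 2 * stem_len + loop_len <= nchar(seq$residues))
  if (stem_len == 0L)
    return(list(seq = seq, record = NULL))
  parts <- with_seed(seed, list(
    stem = paste0(sample(c("A", "C", "G", "T"), stem_len, replace = TRUE,
                         prob = c(.2, .3, .3, .2)), collapse = ""),
    loop = paste0(sample(c("A", "C", "G", "T"), loop_len, replace = TRUE),
                  collapse = "")))
  insert <- paste0(parts$stem, parts$loop, revcomp(parts$stem))
  seq <- replace_interval(seq, position, insert)
  list(seq = seq,
       record = list(chrom = seq$name, start = position,
                     end = position + nchar(insert),
                     stem_len = as.integer(stem_len),
                     loop_len = as.integer(loop_len), stem = parts$stem))
}

#' Build a standard two-chromosome test fixture
#'
#' Assembles a complete synthetic world for end-to-end testing: a target
#' chromosome and an off-target chromosome, a planted repeat block, an
#' exact cross-chromosome duplication, near-duplications just above and
#' just below the default identity threshold, and a palindromic
#' hairpin. All randomness derives from one seed; the manifest records
#' every planted feature.
#'
#' @param seed integer master seed.
#' @param chrom_length length of each chromosome in bases.
#' @param gc_fraction genome GC content.
#' @param oligo_length probe length the thresholds are phrased for.
#' @return list with `genome` (named list of [masked_seq]) and
#'   `manifest` (seed plus `planted_repeats`, `planted_duplications`,
#'   `planted_hairpins`).
#' @export
make_fixture <- function(seed = 1L, chrom_length = 25000L,
                         gc_fraction = 0.44, oligo_length = 45L) {
  L <- as.integer(chrom_length)
  chrA <- generate_genome(L, gc_fraction, seed = seed, name = "chrA")
  chrB <- generate_genome(L, gc_fraction, seed = seed + 1L, name = "chrB")
  manifest <- list(rng_seed = as.integer(seed),
                   chrom_length = L,
                   gc_fraction = gc_fraction,
                   planted_repeats = list(),
                   planted_duplications = list(),
                   planted_hairpins = list())
  # repeat block on the target chromosome
  rep_start <- as.integer(L * 0.10)
  rep_end <- rep_start + 1000L
  chrA <- plant_repeat(chrA, rep_start, rep_end)
  manifest$planted_repeats[[1]] <-
    list(chrom = "chrA", start = rep_start, end = rep_end)
  # exact copy of a chrA block onto chrB (disqualifies its oligos)
  d1 <- plant_duplication(chrB, as.integer(L * 0.30),
                          as.integer(L * 0.30) + 600L,
                          as.integer(L * 0.50), n_substitutions = 0L,
                          seed = seed + 2L, source_seq = chrA)
  chrB <- d1$seq
  manifest$planted_duplications[[1]] <- d1$record
  # 45-bp copies just above / below the 75% identity boundary
  sub_counts <- c(11L, 12L)
  tgt <- as.integer(L * c(0.62, 0.66))
  srcs <- as.integer(L * c(0.40, 0.44))
  for (i in 1:2) {
    d <- plant_duplication(chrB, srcs[i], srcs[i] + oligo_length, tgt[i],
                           n_substitutions = sub_counts[i],
                           seed = seed + 2L + i, source_seq = chrA)
    chrB <- d$seq
    manifest$planted_duplications[[i + 1L]] <- d$record
  }
  # palindrome on the target chromosome
  hp_pos <- as.integer(L * 0.80)
  h <- plant_hairpin(chrA, hp_pos, stem_len = 14L, loop_len = 5L,
                     seed = seed + 9L)
  chrA <- h$seq
  manifest$planted_hairpins[[1]] <- h$record
  list(genome = list(chrA = chrA, chrB = chrB), manifest = manifest)
}

#' Serialize a fixture to FASTA plus manifest JSON
#'
#' @param fixture a [make_fixture()] result.
#' @param dir output directory (created if missing).
#' @return named vector of the two paths (`fasta`, `manifest`).
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "fixture.fa")
  mf <- file.path(dir, "manifest.json")
  write_fasta(fixture$genome, fa)
  jsonlite::write_json(fixture$manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(fasta = fa, manifest = mf)
}
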