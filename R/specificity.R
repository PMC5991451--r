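# Genome-wide specificity: a candidate survives only if its sole genomic
# match at >= threshold ungapped identity is its own source locus.

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, "", USE.NAMES = FALSE)
}

genome_as_list <- function(genome) {
  if (inherits(genome, "masked_seq")) genome <- list(genome)
  stopifnot(all(vapply(genome, inherits, TRUE, "masked_seq")))
  genome
}

# identity >= threshold  <=>  matches >= ceiling(threshold * L), i.e. an
# inclusive bound: 75% over 45 nt means >= 34 matching bases.
min_match_count <- function(oligo_length, min_identity) {
  as.integer(ceiling(min_identity * oligo_length - 1e-9))
}

#' Build a k-mer seed index over a genome
#'
#' Indexes every k-mer position on the forward strand of every sequence
#' (k-mers containing `N` are never indexed). Lookups for both strands
#' are supported by seeding queries with the oligo and with its reverse
#' complement, which is equivalent to indexing both strands.
#'
#' @param genome a [masked_seq] or list of them.
#' @param k seed length in bases (8..31).
#' @return object of class `kmer_index` holding an external pointer; it
#'   is valid for the current session only and is rebuilt cheaply.
#' @export
build_kmer_index <- function(genome, k = 8L) {
  genome <- genome_as_list(genome)
  k <- as.integer(k)
  if (k < 8L || k > 31L) stop("seed k must be between 8 and 31")
  lens <- vapply(genome, function(s) nchar(s$residues), 0L)
  if (k > max(lens)) stop("k exceeds the length of every sequence")
  res <- vapply(genome, `[[`, "", "residues")
  ptr <- cpp_build_index(res, k)
  structure(list(ptr = ptr, k = k,
                 seqnames = vapply(genome, `[[`, "", "name"),
                 lengths = lens,
                 n_positions = attr(ptr, "n_positions")),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d over %d sequence(s), %s indexed positions\n",
              x$k, length(x$seqnames),
              format(x$n_positions, big.mark = ",")))
  invisible(x)
}

#' Look up the genomic occurrences of one k-mer
#'
#' @param index a [build_kmer_index()] result.
#' @param kmer string of length `k` over `{A,C,G,T}`; a k-mer containing
#'   `N` has no occurrences by construction.
#' @return data.frame of forward-strand occurrences: `chrom`, `start`.
#' @export
kmer_occurrences <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  m <- cpp_index_lookup(index$ptr, toupper(kmer))
  data.frame(chrom = index$seqnames[m[, 1]], start = m[, 2],
             stringsAsFactors = FALSE)
}

hits_frame <- function(df, seqnames, oligo_length, oligos) {
  L <- nchar(oligos)[1]
  data.table::data.table(
    qid = df$qid,
    chrom = seqnames[df$sid],
    start = df$start,
    end = df$start + L,
    strand = df$strand,
    matches = df$matches,
    identity = df$matches / L)
}

#' Exhaustive homology scan (reference oracle)
#'
#' Scans every offset of every genomic sequence on both strands and
#' reports each window whose ungapped match count against the oligo
#' reaches the identity threshold. `N` in the genome counts as a
#' mismatch. A `-` strand hit means the reverse complement of the
#' genomic window matches the oligo. This is the exact reference
#' semantics; [find_homologous_loci()] is the seeded production path.
#'
#' @param oligos character vector of equal-length oligo sequences.
#' @param genome a [masked_seq] or list of them.
#' @param min_identity identity threshold (fraction of `oligo_length`).
#' @return `data.table` with `qid` (index into `oligos`), `chrom`,
#'   `start`, `end`, `strand`, `matches`, `identity`; one row per
#'   qualifying window, unmerged.
#' @export
brute_force_homology <- function(oligos, genome, min_identity = 0.75) {
  genome <- genome_as_list(genome)
  stopifnot(length(unique(nchar(oligos))) == 1L)
  mm <- min_match_count(nchar(oligos)[1], min_identity)
  df <- cpp_brute_hits(toupper(oligos),
                       vapply(genome, `[[`, "", "residues"), mm)
  hits_frame(df, vapply(genome, `[[`, "", "name"), nchar(oligos)[1], oligos)
}

# Collapse hits whose windows overlap on the same chromosome and strand
# into one locus, keeping the highest-identity placement (ties: leftmost).
merge_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  data.table::setorder(hits, qid, chrom, strand, start)
  grp <- hits[, {
    run_end <- cummax(end)
    new_run <- c(TRUE, start[-1] >= run_end[-.N])
    list(start = start, end = end, matches = matches, identity = identity,
         locus = cumsum(new_run))
  }, by = c("qid", "chrom", "strand")]
  best <- grp[order(-matches, start),
              .SD[1L], by = c("qid", "chrom", "strand", "locus")]
  out <- best[, c("qid", "chrom", "start", "end", "strand", "matches",
                  "identity")]
  data.table::setorder(out, qid, chrom, start, strand)
  out
}

#' Seeded genome-wide homology search
#'
#' Seed-and-extend: candidate placements are collected wherever the
#' oligo (or its reverse complement, for `-` strand hits) shares an
#' exact k-mer with the genome, each placement is verified by full
#' ungapped comparison over the oligo length, and verified placements
#' whose windows overlap on the same strand are merged into one locus
#' keeping the maximal identity. Verification is exact, so the result
#' contains no false positive; sensitivity relies on a shared seed and
#' is guaranteed for every hit carrying at least one exact k-mer match
#' (always true for exact duplicates).
#'
#' @param oligos character vector of equal-length oligo sequences.
#' @param genome a [masked_seq] or list of them.
#' @param index a [build_kmer_index()] over the same genome; built on
#'   the fly when `NULL`.
#' @param min_identity identity threshold.
#' @param k seed length, used only when `index` is `NULL`.
#' @param seed_mm allowed mismatches within a seed (0 or 1). The default
#'   of 1 looks up every Hamming-distance-1 neighbor of each seed
#'   (BLAST-style neighborhood words); at `k = 8` over 45-nt oligos this
#'   guarantees a triggering seed for every locus with at most 9
#'   mismatches (>= 80% identity) and misses loci at 11 mismatches with
#'   probability below 1e-5.
#' @return merged locus table with the columns of
#'   [brute_force_homology()].
#' @export
find_homologous_loci <- function(oligos, genome, index = NULL,
                                 min_identity = 0.75, k = 8L,
                                 seed_mm = 1L) {
  genome <- genome_as_list(genome)
  if (is.null(index)) index <- build_kmer_index(genome, k)
  stopifnot(inherits(index, "kmer_index"),
            length(unique(nchar(oligos))) == 1L, seed_mm %in% c(0L, 1L))
  mm <- min_match_count(nchar(oligos)[1], min_identity)
  df <- cpp_seed_hits(toupper(oligos), index$ptr, mm, as.integer(seed_mm))
  merge_hits(hits_frame(df, index$seqnames, nchar(oligos)[1], oligos))
}

# Shared uniqueness decision given a merged hit table: the source locus
# (any + strand hit overlapping the candidate's own interval by >= 1 bp
# on its own chromosome) is collapsed into one tally entry; every other
# merged locus -- other chromosomes, non-overlapping placements, and
# - strand self-overlaps (near-palindromic self-hybridization) -- counts
# separately. Survivors have exactly one locus.
uniqueness_verdict <- function(candidates, hits) {
  n <- nrow(candidates)
  is_src <- hits$strand == "+" &
    hits$chrom == candidates$chrom[hits$qid] &
    hits$start < candidates$end[hits$qid] &
    hits$end > candidates$start[hits$qid]
  src_found <- tabulate(hits$qid[is_src], nbins = n) > 0L
  if (!all(src_found))
    stop("internal consistency error: source locus not recovered for ",
         sum(!src_found), " candidate(s)")
  src_exact <- hits$qid[is_src & hits$identity >= 1]
  if (!all(seq_len(n) %in% src_exact))
    stop("internal consistency error: source locus recovered at identity < 1")
  n_loci <- tabulate(hits$qid[is_src], nbins = n) > 0L  # source: one entry
  n_loci <- as.integer(n_loci) + tabulate(hits$qid[!is_src], nbins = n)
  n_loci
}

#' Eliminate candidates matching two or more genomic loci
#'
#' Applies the specificity rule: a candidate is kept exactly when its
#' only genomic match at or above the identity threshold -- searched on
#' both strands across every chromosome -- is its own source locus. The
#' source tally collapses overlapping `+` strand self-hits; a `-` strand
#' hit over the source interval (a near-palindrome that would
#' self-hybridize) counts as a second locus and disqualifies.
#'
#' @param candidates candidate table (from [mask_filter()]).
#' @param genome a [masked_seq] or list of them (the whole assembly, not
#'   just the target chromosome).
#' @param min_identity identity threshold.
#' @param exact use [brute_force_homology()] instead of the seeded
#'   search.
#' @param index optional prebuilt [build_kmer_index()].
#' @param k seed length for the heuristic path.
#' @param seed_mm seed mismatch allowance, see [find_homologous_loci()].
#' @return list with `kept` (surviving candidate subset) and `n_loci`
#'   (locus tally per input candidate, for diagnostics).
#' @export
uniqueness_filter <- function(candidates, genome, min_identity = 0.75,
                              exact = FALSE, index = NULL, k = 8L,
                              seed_mm = 1L) {
  genome <- genome_as_list(genome)
  if (nrow(candidates) == 0L)
    return(list(kept = candidates, n_loci = integer(0)))
  hits <- if (exact) {
    merge_hits(brute_force_homology(candidates$sequence, genome, min_identity))
  } else {
    find_homologous_loci(candidates$sequence, genome, index, min_identity,
                         k, seed_mm)
  }
  n_loci <- uniqueness_verdict(candidates, hits)
  list(kept = candidates[which(n_loci == 1L), ], n_loci = n_loci)
}
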