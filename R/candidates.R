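#' Pipeline configuration
#'
#' Collects the tunable constants of the probe-design pipeline. Defaults
#' are the published chromosome-painting settings: 45-nt oligos tiled at
#' a 5-nt step, elimination of candidates matching two or more genomic
#' loci at >= 75% ungapped identity, retention of oligos whose duplex
#' melting temperature exceeds their hairpin melting temperature by more
#' than 10 degrees C, and selection at two oligos per kilobase.
#'
#' @param oligo_length probe length in bases.
#' @param step tiling step in bases (`0 < step <= oligo_length`).
#' @param homology_threshold minimum ungapped identity fraction at which
#'   a second genomic locus disqualifies a candidate.
#' @param dtm_min retention threshold in degrees C: candidates are kept
#'   when `Tm - hairpin Tm > dtm_min` (strict).
#' @param density_per_kb target probe density (oligos per kilobase).
#' @param target_count optional cap on the final probe count; when the
#'   density selection yields more, the set is thinned evenly in genomic
#'   order.
#' @param density_basis whether `density_per_kb` refers to total
#'   chromosome length or to its unmasked portion.
#' @param seed_k seed k-mer length for the heuristic homology search.
#' @param seed_mm seed mismatch allowance (0 or 1); 1 enables
#'   neighborhood-word seeding, see [find_homologous_loci()].
#' @param exact use the exhaustive both-strand scan instead of
#'   seed-and-extend for the uniqueness stage.
#' @param min_stem,min_loop minimum hairpin stem pairing length and loop
#'   length in bases.
#' @param rng_seed seed recorded for any randomized step (the default
#'   pipeline path is fully deterministic).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(oligo_length = 45L, step = 5L,
                            homology_threshold = 0.75, dtm_min = 10,
                            density_per_kb = 2, target_count = NULL,
                            density_basis = c("total", "unmasked"),
                            seed_k = 8L, seed_mm = 1L, exact = FALSE,
                            min_stem = 4L, min_loop = 3L,
                            rng_seed = 1L) {
  density_basis <- match.arg(density_basis)
  oligo_length <- as.integer(oligo_length)
  step <- as.integer(step)
  stopifnot(oligo_length >= 1L, step >= 1L, step <= oligo_length,
            homology_threshold > 0, homology_threshold <= 1,
            density_per_kb > 0, is.numeric(dtm_min),
            seed_k >= 8L, seed_k <= oligo_length, seed_mm %in% c(0L, 1L),
            min_stem >= 1L, min_loop >= 0L)
  if (!is.null(target_count)) {
    target_count <- as.integer(target_count)
    stopifnot(target_count >= 1L)
  }
  structure(list(oligo_length = oligo_length, step = step,
                 homology_threshold = homology_threshold,
                 dtm_min = dtm_min, density_per_kb = density_per_kb,
                 target_count = target_count,
                 density_basis = density_basis,
                 seed_k = as.integer(seed_k),
                 seed_mm = as.integer(seed_mm), exact = isTRUE(exact),
                 min_stem = as.integer(min_stem),
                 min_loop = as.integer(min_loop),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-20s %s\n", f, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

#' Tile fixed-length candidate oligos along a sequence
#'
#' Generates every window of `oligo_length` bases starting at
#' `0, step, 2*step, ...` up to `L - oligo_length` (forward strand
#' only). No mask filtering is applied at this stage. A sequence shorter
#' than `oligo_length` yields an empty candidate table.
#'
#' @param seq a [masked_seq].
#' @param oligo_length window width in bases.
#' @param step tiling step in bases.
#' @return `data.table` with one row per candidate: `chrom`, `start`
#'   (0-based), `end` (exclusive), `sequence`.
#' @export
tile_candidates <- function(seq, oligo_length = 45L, step = 5L) {
  stopifnot(inherits(seq, "masked_seq"), oligo_length >= 1L, step >= 1L)
  oligo_length <- as.integer(oligo_length)
  step <- as.integer(step)
  L <- nchar(seq$residues)
  if (L < oligo_length) {
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), sequence = character(0)))
  }
  starts <- seq.int(0L, L - oligo_length, by = step)
  data.table::data.table(
    chrom = seq$name,
    start = starts,
    end = starts + as.integer(oligo_length),
    sequence = substring(seq$residues, starts + 1L, starts + oligo_length))
}

#' Drop candidates touching masked or ambiguous bases
#'
#' Retains exactly the candidates whose windows contain zero
#' repeat-masked bases and zero `N` (a single masked base anywhere in
#' the window disqualifies the candidate). Relative order is preserved;
#' the operation is idempotent.
#'
#' @param candidates candidate table from [tile_candidates()].
#' @param seq the [masked_seq] the candidates were tiled from.
#' @return the surviving subset of `candidates`.
#' @export
mask_filter <- function(candidates, seq) {
  stopifnot(inherits(seq, "masked_seq"))
  if (nrow(candidates) == 0L) return(candidates)
  if (!all(candidates$chrom == seq$name))
    stop("candidates do not belong to sequence '", seq$name, "'")
  if (max(candidates$end) > nchar(seq$residues))
    stop("candidate window extends beyond sequence end")
  cs <- c(0L, cumsum(seq$mask))
  n_masked <- cs[candidates$end + 1L] - cs[candidates$start + 1L]
  candidates[n_masked == 0L, , drop = FALSE]
}
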