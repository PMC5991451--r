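#' Select the final probe set at a target density
#'
#' Partitions the chromosome into bins of width
#' `1000 / density_per_kb` bases (500 bp at two oligos per kilobase) and
#' in each bin, walking left to right, picks the candidate with the
#' highest dTm whose window does not overlap the previously selected
#' probe (ties broken by smallest start; `dtm = Inf`, i.e. no hairpin,
#' ranks above every finite margin). Bins yielding no eligible candidate
#' are recorded as shortfall bins. When `target_count` is given and the
#' selection exceeds it, the set is thinned evenly in genomic order
#' (first and last picks retained) to exactly `target_count` probes.
#' The procedure is deterministic.
#'
#' With `density_basis = "unmasked"` the bin width is rescaled by
#' `chrom_length / unmasked_length`, so the requested density is
#' realized per unmasked kilobase while bins still partition the entire
#' chromosome.
#'
#' @param candidates candidate table with `dtm` (from [dtm_filter()]),
#'   sorted by `start`.
#' @param chrom_length target chromosome length in bases.
#' @param density_per_kb requested probe density.
#' @param target_count optional final-set size cap.
#' @param density_basis see [pipeline_config()].
#' @param unmasked_length unmasked base count, required for
#'   `density_basis = "unmasked"`.
#' @return object of class `probe_set`: list with `probes` (the
#'   selected rows, sorted, non-overlapping), `bin_width`,
#'   `shortfall_bins` (0-based bin indices with no probe) and `n_bins`.
#' @export
select_by_density <- function(candidates, chrom_length, density_per_kb = 2,
                              target_count = NULL,
                              density_basis = c("total", "unmasked"),
                              unmasked_length = NULL) {
  density_basis <- match.arg(density_basis)
  stopifnot(chrom_length >= 1, density_per_kb > 0)
  candidates <- data.table::as.data.table(candidates)
  if (nrow(candidates) > 0) {
    if (is.null(candidates$dtm))
      stop("candidates carry no dtm column; run thermo_profile() first")
    if (is.unsorted(candidates$start))
      stop("candidates must be sorted by start")
    if (length(unique(candidates$chrom)) > 1L)
      stop("select_by_density operates on a single chromosome")
  }
  bin_width <- 1000 / density_per_kb
  if (density_basis == "unmasked") {
    if (is.null(unmasked_length) || unmasked_length <= 0)
      stop("density_basis='unmasked' requires a positive unmasked_length")
    bin_width <- bin_width * chrom_length / unmasked_length
  }
  oligo_length <- if (nrow(candidates) > 0) {
    candidates$end[1] - candidates$start[1]
  } else 0
  if (nrow(candidates) > 0 && bin_width < oligo_length)
    stop(sprintf(
      "requested density implies %.0f bp bins, narrower than the %d bp oligo: non-overlapping selection is impossible",
      bin_width, oligo_length))
  n_bins <- as.integer(ceiling(chrom_length / bin_width))
  bin_of <- as.integer(floor(candidates$start / bin_width))
  by_bin <- split(seq_len(nrow(candidates)), factor(bin_of, levels = seq_len(n_bins) - 1L))
  picked <- integer(n_bins)
  n_picked <- 0L
  shortfall <- integer(0)
  prev_end <- -1L
  for (b in seq_len(n_bins) - 1L) {
    idx <- by_bin[[b + 1L]]
    idx <- idx[candidates$start[idx] >= prev_end]
    if (length(idx) == 0L) {
      shortfall <- c(shortfall, b)
      next
    }
    sub <- candidates[idx]
    best <- idx[order(-sub$dtm, sub$start)[1L]]
    n_picked <- n_picked + 1L
    picked[n_picked] <- best
    prev_end <- candidates$end[best]
  }
  picked <- picked[seq_len(n_picked)]
  probes <- candidates[picked]
  if (!is.null(target_count) && nrow(probes) > target_count) {
    keep <- round(seq(1L, nrow(probes), length.out = target_count))
    probes <- probes[keep]
  }
  if (nrow(probes) > 0)
    probes$name <- sprintf("%s_probe_%06d", probes$chrom, seq_len(nrow(probes)))
  structure(list(probes = probes, bin_width = bin_width,
                 shortfall_bins = shortfall, n_bins = n_bins),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf(
    "<probe_set> %d probes, %d/%d bins filled (bin width %.0f bp)\n",
    nrow(x$probes), x$n_bins - length(x$shortfall_bins), x$n_bins,
    x$bin_width))
  invisible(x)
}

#' Per-stage survivor report
#'
#' @param counts named numeric vector of survivor counts in pipeline
#'   order (e.g. `tiled`, `mask_filter`, `uniqueness_filter`,
#'   `dtm_filter`, `selected`). Counts must telescope: each stage's
#'   survivors cannot exceed the previous stage's.
#' @return data.frame with `stage`, `survivors`, `eliminated` (relative
#'   to the previous stage).
#' @export
stage_report <- function(counts) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), length(counts) >= 1)
  if (any(diff(counts) > 0))
    stop("stage survivor counts must be non-increasing")
  data.frame(stage = names(counts),
             survivors = as.integer(counts),
             eliminated = as.integer(c(0, -diff(counts))),
             stringsAsFactors = FALSE)
}
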