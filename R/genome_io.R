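#' Masked nucleotide sequence
#'
#' Container for one chromosome (or contig) with per-base repeat-mask
#' flags. Bases that were lowercase (soft-masked), `N` (hard-masked) or
#' IUPAC ambiguity codes in the source FASTA carry `mask = TRUE`;
#' ambiguity codes are degraded to `N`. Residues are stored uppercased
#' over the alphabet `{A,C,G,T,N}`.
#'
#' @param name sequence identifier (chromosome name).
#' @param residues single string of residues; lowercase and ambiguity
#'   codes are normalized as for FASTA input.
#' @param mask optional logical vector, one flag per base; when omitted
#'   it is derived from case/`N`/ambiguity as for FASTA input.
#' @return an object of class `masked_seq` with fields `name`,
#'   `residues` (uppercase string) and `mask` (logical vector).
#' @examples
#' s <- masked_seq("c1", "ACGTacgtNN")
#' s$mask
#' @export
masked_seq <- function(name, residues, mask = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(residues), length(residues) == 1L)
  bad <- regmatches(residues, regexpr("[^ACGTNRYSWKMBDHVacgtnryswkmbdhv]", residues))
  if (length(bad) > 0)
    stop(sprintf("record '%s': non-nucleotide character '%s'", name, bad))
  lower <- grepl("[a-z]", strsplit(residues, "", fixed = TRUE)[[1]])
  up <- chartr("RYSWKMBDHV", "NNNNNNNNNN", toupper(residues))
  is_n <- charToRaw(up) == charToRaw("N")
  derived <- lower | is_n
  if (is.null(mask)) {
    mask <- derived
  } else {
    stopifnot(is.logical(mask), length(mask) == nchar(up))
    mask <- mask | derived  # lowercase / N always masked
  }
  structure(list(name = name, residues = up, mask = mask),
            class = "masked_seq")
}

#' @export
print.masked_seq <- function(x, ...) {
  cat(sprintf("<masked_seq> %s: %d bp, %d masked (%.1f%%)\n",
              x$name, nchar(x$residues), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
length.masked_seq <- function(x) nchar(x$residues)

#' Read a mask-aware FASTA genome
#'
#' Reads a (multi-)FASTA assembly, preserving repeat-mask state: bases
#' that are lowercase (soft-masked by e.g. RepeatMasker) or `N`
#' (hard-masked) are flagged as masked. IUPAC ambiguity codes are
#' converted to `N` with `mask = TRUE` rather than rejected, since real
#' assemblies contain them. Record order is preserved.
#'
#' @param path path to a FASTA file (arbitrary line wrapping).
#' @return named list of [masked_seq] objects, in file order.
#' @seealso [write_fasta()] for the lossless inverse.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate record name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- masked_seq(nm[i], as.character(set[[i]]))
  }
  names(out) <- nm
  out
}

#' Write a mask-aware FASTA genome
#'
#' Inverse of [read_fasta()]: masked bases are emitted lowercase so a
#' round trip preserves both residues and mask.
#'
#' @param seqs a [masked_seq] or list of them.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "masked_seq")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    chars <- strsplit(s$residues, "", fixed = TRUE)[[1]]
    chars[s$mask] <- tolower(chars[s$mask])
    body <- paste0(chars, collapse = "")
    starts <- seq(1L, max(nchar(body), 1L), by = width)
    writeLines(c(paste0(">", s$name),
                 substring(body, starts, pmin(starts + width - 1L, nchar(body)))),
               con)
  }
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' Parses BED3+ with 0-based half-open coordinates. `track`, `browser`,
#' comment and blank lines are skipped. Malformed records (fewer than 3
#' columns, non-integer or negative coordinates, start >= end) raise an
#' error naming the offending line.
#'
#' @param path path to a BED file.
#' @return `data.frame` with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 3L))
    stop(sprintf("BED line %d: fewer than 3 columns", lineno[which(ncol < 3L)[1]]))
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad))
    stop(sprintf("BED line %d: non-integer coordinate", lineno[which(bad)[1]]))
  if (any(start < 0))
    stop(sprintf("BED line %d: negative coordinate", lineno[which(start < 0)[1]]))
  if (any(start >= end))
    stop(sprintf("BED line %d: start >= end", lineno[which(start >= end)[1]]))
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  if (all(ncol >= 4L)) out$name <- vapply(parts, `[[`, "", 4L)
  if (all(ncol >= 5L))
    out$score <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5L)))
  if (all(ncol >= 6L)) out$strand <- vapply(parts, `[[`, "", 6L)
  out
}

#' Write a probe set as BED6
#'
#' Emits one 6-column BED line per probe: `chrom`, `start` (0-based),
#' `end` (exclusive), probe id, the dTm margin rounded to 2 decimals as
#' score, and strand `+`. Input must already be sorted by
#' `(chrom, start)`; an unsorted probe table is an error, not silently
#' reordered.
#'
#' @param probes a probe set from [select_by_density()] or a data.frame
#'   with columns `chrom`, `start`, `end`, `name`, `dtm`.
#' @param path output path.
#' @return `path`, invisibly. An empty probe set writes an empty file.
#' @export
write_bed <- function(probes, path) {
  if (inherits(probes, "probe_set")) probes <- probes$probes
  probes <- as.data.frame(probes)
  if (nrow(probes) > 0) {
    o <- order(probes$chrom, probes$start)
    if (!identical(o, seq_len(nrow(probes))))
      stop("probe set must be sorted by (chrom, start) before writing BED")
  }
  if (is.null(probes$name) && nrow(probes) > 0)
    probes$name <- sprintf("probe_%05d", seq_len(nrow(probes)))
  score <- if (nrow(probes) > 0) {
    ifelse(is.finite(probes$dtm), sprintf("%.2f", probes$dtm), "Inf")
  } else character(0)
  lines <- if (nrow(probes) > 0) {
    paste(probes$chrom, format(probes$start, scientific = FALSE, trim = TRUE),
          format(probes$end, scientific = FALSE, trim = TRUE),
          probes$name, score, "+", sep = "\t")
  } else character(0)
  con <- file(path, "wb")  # binary: guarantees Unix newlines
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Validate a painting-probe BED against its genome
#'
#' Checks a BED probe file of the kind this pipeline emits (or a
#' published probe list): records parse, widths are uniform, records are
#' sorted, non-overlapping and within chromosome bounds.
#'
#' @param bed_path path to the BED file.
#' @param genome optional named list of [masked_seq] (or a FASTA path)
#'   for bounds checking.
#' @return list with `n_records`, `widths` (unique interval widths),
#'   `sorted`, `non_overlapping`, `within_bounds` (NA when no genome is
#'   supplied) and `chroms`.
#' @export
validate_bed <- function(bed_path, genome = NULL) {
  bed <- read_bed(bed_path)
  if (is.character(genome)) genome <- read_fasta(genome)
  o <- order(bed$chrom, bed$start)
  sorted <- identical(o, seq_len(nrow(bed)))
  non_overlapping <- TRUE
  for (ch in unique(bed$chrom)) {
    b <- bed[bed$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      non_overlapping <- FALSE
      break
    }
  }
  within <- NA
  if (!is.null(genome)) {
    lens <- vapply(genome, function(s) nchar(s$residues), 0)
    names(lens) <- vapply(genome, `[[`, "", "name")
    within <- all(bed$chrom %in% names(lens)) &&
      all(bed$end <= lens[bed$chrom])
  }
  list(n_records = nrow(bed), widths = sort(unique(bed$end - bed$start)),
       sorted = sorted, non_overlapping = non_overlapping,
       within_bounds = within, chroms = unique(bed$chrom))
}
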