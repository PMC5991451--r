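# Independent oracles and small builders shared across tests. These stay
# deliberately naive (plain R loops) so they cannot share a defect with
# the compiled production paths they check.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(s, "", fixed = TRUE),
                                  function(ch) paste(rev(ch), collapse = ""),
                                  ""))
}

# Plain-R full scan: every window on both strands with identity >=
# threshold (N mismatches everything). Tiny inputs only.
naive_hits <- function(oligo, seqs, min_identity) {
  L <- nchar(oligo)
  need <- ceiling(min_identity * L - 1e-9)
  qf <- strsplit(oligo, "", fixed = TRUE)[[1]]
  qr <- strsplit(rc(oligo), "", fixed = TRUE)[[1]]
  out <- list()
  for (nm in names(seqs)) {
    s <- strsplit(seqs[[nm]], "", fixed = TRUE)[[1]]
    if (length(s) < L) next
    for (p in 0:(length(s) - L)) {
      w <- s[(p + 1):(p + L)]
      w[w == "N"] <- "!"  # never matches
      for (str in c("+", "-")) {
        q <- if (str == "+") qf else qr
        m <- sum(w == q)
        if (m >= need) {
          out[[length(out) + 1]] <- data.frame(
            chrom = nm, start = p, end = p + L, strand = str,
            matches = m, identity = m / L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      matches = integer(0), identity = numeric(0)))
  }
  do.call(rbind, out)
}

# Plain-R stem enumeration per the hairpin definition: all (i, j, k) with
# seq[i..i+k) reverse-complementary to seq[j..j+k), loop >= min_loop,
# k >= min_stem; maximum unimolecular NN Tm over stems, NA when none.
naive_hairpin_tm <- function(s, model, min_stem = 4L, min_loop = 3L) {
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  best <- NA_real_
  for (i in 0:(n - 1)) {
    for (k in min_stem:floor((n - min_loop) / 2)) {
      if (i + k > n) break
      for (j in seq_len(n)) {
        j0 <- j - 1
        if (j0 < i + k + min_loop || j0 + k > n) next
        stem <- paste0(ch[(i + 1):(i + k)], collapse = "")
        other <- paste0(ch[(j0 + 1):(j0 + k)], collapse = "")
        if (identical(rc(stem), other)) {
          tm <- melting_temperature(stem, model, unimolecular = TRUE)
          if (is.na(best) || tm > best) best <- tm
        }
      }
    }
  }
  best
}

# Exact-scan hits merged with the package's locus-collapsing rule.
merge_hits_for_test <- function(oligos, genome, min_identity = 0.75) {
  probepaint:::merge_hits(
    brute_force_homology(oligos, genome, min_identity))
}

genome_chars <- function(seqs) {
  out <- lapply(seqs, function(x) x$residues)
  names(out) <- vapply(seqs, `[[`, "", "name")
  out
}

write_tmp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
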