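#' Nearest-neighbor thermodynamic model
#'
#' Loads the dinucleotide stacking parameters and hybridization
#' conditions used for all melting-temperature predictions. The shipped
#' table is the unified DNA/DNA parameter set (enthalpy in kcal/mol,
#' entropy in cal/mol/K at 1 M NaCl) with per-terminal initiation terms
#' and a self-complementarity entropy penalty. Default conditions are
#' 50 mM monovalent cation and 0.25 uM total strand, a common
#' hybridization-buffer working point; the screen downstream uses the
#' dTm margin, so consistency matters more than absolute calibration.
#'
#' @param nn_table path to a parameter TSV (`term`, `dH`, `dS`; 16
#'   dinucleotides plus `init_AT`, `init_GC`, `sym` rows). Defaults to
#'   the table shipped with the package.
#' @param monovalent_cation monovalent cation concentration, mol/L.
#' @param strand_conc total strand concentration, mol/L.
#' @return object of class `thermo_model`.
#' @export
thermo_model <- function(nn_table = system.file("extdata",
                                                "nn_unified_v1.tsv",
                                                package = "probepaint"),
                         monovalent_cation = 0.05,
                         strand_conc = 0.25e-6) {
  stopifnot(monovalent_cation > 0, strand_conc > 0)
  tab <- utils::read.delim(nn_table, comment.char = "#",
                           stringsAsFactors = FALSE)
  # order must match the compiled code's 4*first + second indexing
  dinucs <- paste0(rep(c("A", "C", "G", "T"), each = 4),
                   rep(c("A", "C", "G", "T"), times = 4))
  missing <- setdiff(c(dinucs, "init_AT", "init_GC", "sym"), tab$term)
  if (length(missing) > 0)
    stop("parameter table lacks entries: ", paste(missing, collapse = ", "))
  rownames(tab) <- tab$term
  structure(list(
    dH = setNames(tab[dinucs, "dH"], dinucs),
    dS = setNames(tab[dinucs, "dS"], dinucs),
    init_AT = c(dH = tab["init_AT", "dH"], dS = tab["init_AT", "dS"]),
    init_GC = c(dH = tab["init_GC", "dH"], dS = tab["init_GC", "dS"]),
    sym_dS = tab["sym", "dS"],
    monovalent_cation = monovalent_cation,
    strand_conc = strand_conc,
    table_path = nn_table), class = "thermo_model")
}

#' @export
print.thermo_model <- function(x, ...) {
  cat(sprintf(
    "<thermo_model> unified NN table (%d stacks), %.0f mM monovalent, %.2g M strand\n",
    length(x$dH), 1000 * x$monovalent_cation, x$strand_conc))
  invisible(x)
}

GAS_CONSTANT <- 1.9872  # cal/(mol*K)
SALT_DS_COEF <- 0.368   # cal/(mol*K) per phosphate pair (entropy salt term)

#' Nearest-neighbor duplex melting temperature
#'
#' Predicts the melting temperature of a perfect duplex by summing
#' dinucleotide stacking enthalpies/entropies and terminal initiation
#' terms, applying the entropic salt correction
#' `dS_salt = 0.368 (L-1) ln[Na+]`, and (bimolecular case) the strand
#' concentration term `R ln(C_T/x)` with `x = 1` for self-complementary
#' sequences (which also receive the symmetry entropy penalty) and
#' `x = 4` otherwise:
#' `Tm = 1000 dH / (dS + dS_salt + R ln(C_T/x)) - 273.15`.
#' With `unimolecular = TRUE` the concentration term is omitted, the
#' convention used for hairpin stems.
#'
#' @param sequences character vector over `{A,C,G,T}`, each at least 2
#'   bases long. `N` or ambiguity codes are an error: such candidates
#'   are removed by [mask_filter()] before thermodynamics.
#' @param model a [thermo_model()].
#' @param unimolecular omit the strand-concentration term.
#' @return numeric vector of Tm in degrees C.
#' @export
melting_temperature <- function(sequences, model = thermo_model(),
                                unimolecular = FALSE) {
  stopifnot(inherits(model, "thermo_model"))
  sequences <- toupper(sequences)
  if (any(grepl("[^ACGT]", sequences)))
    stop("melting_temperature: sequence contains a non-ACGT character")
  if (any(nchar(sequences) < 2L))
    stop("melting_temperature: sequence shorter than 2 bases")
  salt_ln <- log(model$monovalent_cation)
  vapply(sequences, function(s) {
    n <- nchar(s)
    di <- substring(s, 1:(n - 1), 2:n)
    dH <- sum(model$dH[di])
    dS <- sum(model$dS[di])
    for (b in c(substr(s, 1, 1), substr(s, n, n))) {
      term <- if (b %in% c("A", "T")) model$init_AT else model$init_GC
      dH <- dH + term[["dH"]]
      dS <- dS + term[["dS"]]
    }
    selfcomp <- identical(s, revcomp(s))
    if (selfcomp) dS <- dS + model$sym_dS
    dS <- dS + SALT_DS_COEF * (n - 1) * salt_ln
    denom <- if (unimolecular) dS else {
      dS + GAS_CONSTANT * log(model$strand_conc / if (selfcomp) 1 else 4)
    }
    1000 * dH / denom - 273.15
  }, 0, USE.NAMES = FALSE)
}

#' Strongest-hairpin melting temperature
#'
#' Enumerates every ungapped stem `(i, j, k)` of the oligo --
#' `seq[i..i+k)` reverse-complementary (Watson-Crick only, no G.T
#' wobble) to `seq[j..j+k)` with loop `j - (i + k) >= min_loop` and stem
#' `k >= min_stem` -- and returns the maximum over stems of the stem's
#' nearest-neighbor duplex Tm under unimolecular conditions (no strand
#' concentration term). `NA` is the no-hairpin sentinel: no qualifying
#' stem exists and the oligo is treated as structure-free.
#'
#' @inheritParams melting_temperature
#' @param min_stem minimum stem pairing length in bases.
#' @param min_loop minimum loop length in bases.
#' @return numeric vector of hairpin Tm in degrees C, `NA` where no stem
#'   exists.
#' @export
hairpin_tm <- function(sequences, model = thermo_model(),
                       min_stem = 4L, min_loop = 3L) {
  stopifnot(inherits(model, "thermo_model"), min_stem >= 1L, min_loop >= 0L)
  sequences <- toupper(sequences)
  if (any(grepl("[^ACGT]", sequences)))
    stop("hairpin_tm: sequence contains a non-ACGT character")
  cpp_hairpin_tm(sequences, as.integer(min_stem), as.integer(min_loop),
                 unname(model$dH), unname(model$dS),
                 unname(model$init_AT), unname(model$init_GC),
                 model$sym_dS,
                 SALT_DS_COEF * log(model$monovalent_cation))
}

#' Attach duplex Tm, hairpin Tm and dTm to candidates
#'
#' @param candidates candidate table with a `sequence` column.
#' @param model a [thermo_model()].
#' @param min_stem,min_loop hairpin stem/loop minima.
#' @return `candidates` with added columns `tm`, `hairpin_tm` (`NA` when
#'   no stem exists) and `dtm = tm - hairpin_tm` (`Inf` when no stem
#'   exists: absence of self-structure is the best case).
#' @export
thermo_profile <- function(candidates, model = thermo_model(),
                           min_stem = 4L, min_loop = 3L) {
  candidates <- data.table::as.data.table(candidates)
  if (nrow(candidates) == 0L) {
    candidates$tm <- numeric(0)
    candidates$hairpin_tm <- numeric(0)
    candidates$dtm <- numeric(0)
    return(candidates)
  }
  tm <- melting_temperature(candidates$sequence, model)
  hp <- hairpin_tm(candidates$sequence, model, min_stem, min_loop)
  candidates$tm <- tm
  candidates$hairpin_tm <- hp
  candidates$dtm <- ifelse(is.na(hp), Inf, tm - hp)
  candidates
}

#' Retain candidates whose duplex Tm dominates self-structure
#'
#' Keeps exactly the candidates with `dtm` strictly greater than
#' `dtm_min` (a candidate at exactly the threshold is dropped).
#' Candidates with no hairpin (`dtm = Inf`) are always kept. Order is
#' preserved.
#'
#' @param candidates table from [thermo_profile()] (has a `dtm` column).
#' @param dtm_min threshold in degrees C.
#' @return the surviving subset.
#' @export
dtm_filter <- function(candidates, dtm_min = 10) {
  if (is.null(candidates$dtm))
    stop("candidates carry no thermodynamic profile; run thermo_profile() first")
  candidates[which(candidates$dtm > dtm_min), ]
}
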