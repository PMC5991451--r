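Package: probepaint
Title: Design of Chromosome-Specific Oligo-FISH Painting Probe Sets
Version: 0.1.0
Authors@R:
    person("probepaint", "developers", email = "devel@probepaint.org",
           role = c("aut", "cre"))
Description: Designs chromosome painting probe sets for oligonucleotide
    fluorescence in situ hybridization (oligo-FISH) from a repeat-masked
    genome assembly. Fixed-length candidate oligos are tiled along the
    target chromosome, candidates overlapping repeat-masked or ambiguous
    bases are discarded, genome-wide specificity is enforced by an
    ungapped percent-identity search on both strands (seed-and-extend
    with an exact brute-force mode), self-structure is screened by the
    margin between nearest-neighbor duplex melting temperature and
    hairpin melting temperature, and a final non-overlapping probe set is
    chosen at a target density and written as BED. A seeded synthetic
    fixture generator plants repeats, near-duplications and hairpins with
    a ground-truth manifest so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
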