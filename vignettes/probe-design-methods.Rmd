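---
title: "Methods: chromosome painting probe design in probepaint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome painting probe design in probepaint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probepaint)
```

## Scope and model

`probepaint` selects a pool of short oligonucleotides that uniquely and
uniformly cover one chromosome of an assembled genome, for use as a
chromosome-painting FISH probe. The pipeline is a cascade of
deterministic filters over fixed-length sequence windows; no stage uses
randomness, so a probe set is a pure function of the assembly and the
configuration.

The stages, their defaults, and why:

| stage | parameter | default | meaning |
|---|---|---|---|
| tiling | `oligo_length` | 45 nt | probe length; synthesis-friendly and long enough for stable hybridization |
| tiling | `step` | 5 nt | candidate spacing; 9-fold window overlap gives the selector freedom |
| repeat filter | — | — | one masked or ambiguous base anywhere disqualifies the window |
| uniqueness | `homology_threshold` | 0.75 | a second genomic locus at ≥ 75% ungapped identity disqualifies |
| thermo | `dtm_min` | 10 °C | keep only `Tm − hairpin Tm > 10` (strict) |
| selection | `density_per_kb` | 2 | one probe per 500-bp bin |
| selection | `target_count` | unset | optional even thinning to a fixed pool size |

## Coordinates and masking

All coordinates are 0-based half-open, internally and in BED; 1-based
coordinates appear nowhere, which removes an entire class of
off-by-one defects. Repeat annotation is consumed, never computed:
lowercase (soft-masked) and `N` (hard-masked) bases are both honored,
and IUPAC ambiguity codes degrade to masked `N` rather than erroring,
because real assemblies contain them. The strictest reading of "repeat
filtered" is used — a single masked base anywhere in a 45-mer
disqualifies it — since even partial repeat overlap risks
cross-hybridization of a pooled probe.

## Uniqueness: ungapped identity, both strands, whole genome

"Homology" is implemented as ungapped full-length percent identity
(matching bases / `oligo_length`); there is no gap model. At 45 nt,
hybridization specificity is dominated by substitutions, and the
ungapped definition admits an exact, cheap brute-force oracle
(`brute_force_homology()`), which scans every offset of every
chromosome on both strands. The threshold is inclusive: 75% of 45
means ≥ 34 matching bases, so a second copy carrying 11 substitutions
(34/45 ≈ 75.6%) disqualifies and one carrying 12 (33/45 ≈ 73.3%) does
not. Genomic `N` always scores as a mismatch.

The candidate's own locus counts toward the "two or more loci" tally:
`+`-strand hits overlapping the source interval collapse into it, but a
`-`-strand hit over the same interval (a near-palindromic oligo that
would self-hybridize) counts as a second locus and disqualifies.
Overlapping qualifying windows elsewhere merge into one locus, keeping
the best identity — a tandem-sliding match is one competing locus, not
many.

### Seeding design

The production search is seed-and-extend over a k-mer position index,
with exact verification of every seeded placement, so false positives
are impossible and the only design question is seed sensitivity. A
contiguous-seed analysis shows that no practical contiguous k
suffices: with 9 substitutions scattered in a 45-mer (80% identity,
the level at which the search is documented to be reliable), the
probability that no 16-mer survives intact is 0.89, and even for k = 8
it is 6.5%. The default is therefore **k = 8 seeds with 1-mismatch
neighborhood lookup** (the BLAST neighborhood-word idea): every 8-mer
of the oligo, and every Hamming-distance-1 neighbor of it, is looked
up. A counting argument makes this sensitivity *guaranteed* at ≥ 80%
identity — 9 substitutions can cover at most 9 × 8 = 72 of the
2 × 38 = 76 (window, allowed-mismatch) slots needed to spoil all
seeds — and Monte Carlo puts the miss probability at 11 substitutions
(75.6% identity, the decision boundary) below 10⁻⁵. Both `seed_k` and
`seed_mm` are configurable; `exact = TRUE` replaces the heuristic with
the oracle scan outright, which is affordable up to ~100 kb genomes
and is how the test suite cross-validates the heuristic.

## Thermodynamics

Duplex Tm uses the unified nearest-neighbor parameter set (dinucleotide
ΔH/ΔS at 1 M NaCl with per-terminal initiation terms and a
self-complementarity entropy penalty), shipped as a versioned TSV. The
temperature is

Tm = 1000·ΔH / (ΔS + 0.368·(L−1)·ln[Na⁺] + R·ln(C_T/x)) − 273.15

with x = 1 for self-complementary duplexes and 4 otherwise. Default
conditions are 50 mM monovalent cation and 0.25 µM total strand — a
generic hybridization working point, configurable in `thermo_model()`.
The downstream filter uses only the *margin* dTm = Tm − hairpin Tm, so
consistency between the two Tm computations matters more than absolute
calibration against any particular buffer.

Hairpin Tm is deliberately simple: enumerate every ungapped
Watson–Crick stem (i, j, k) — `seq[i..i+k)` reverse-complementary to
`seq[j..j+k)`, stem ≥ 4 bp, loop ≥ 3 nt, no G·T wobble — and report
the maximum over stems of the stem's NN duplex Tm under unimolecular
conditions (concentration term omitted). This is a screening statistic,
not a folding prediction: it has no loop-entropy penalty, so it
*overestimates* the stability of short stems, and under the defaults
roughly 85% of random 45-mers carry a finite hairpin Tm. That bias is
conservative for probe design (structure-prone oligos are culled
aggressively) and keeps an exact brute-force oracle feasible; a
partition-function fold is explicitly out of scope. An oligo with no
qualifying stem at all gets the `NA` sentinel, treated as dTm = +∞ and
always kept — absence of any stem is the best case. The dTm rule is a
strict inequality: a candidate at exactly the threshold is dropped.

## Selection

The chromosome is partitioned into bins of `1000 / density_per_kb` bp
and each bin, scanned left to right, contributes the surviving
candidate with the highest dTm whose window does not overlap the
previous pick (ties: leftmost). Bin-and-pick was chosen over greedy
global spacing because it guarantees representation along the entire
chromosome length — the property that makes a painting probe paint —
and is deterministic. Bins with no eligible candidate (masked deserts,
hairpin clusters, or blocking by the previous pick) are reported as
shortfall bins rather than silently absorbed.

Density is defined over total chromosome length including masked spans,
because the design goal is stated per physical kilobase of chromosome;
a `density_basis = "unmasked"` mode instead rescales the bin width by
(total / unmasked) so the density is realized per unmasked kilobase
(at realistic repeat fractions the two differ by a factor of ~2; the
published pool sizes are consistent with the repeat-filtered basis, but
the source description does not settle it, so both are offered and
`"total"` is the default). When a `target_count` is set and exceeded,
the selection is thinned evenly in genomic order —
`round(seq(1, n, length.out = target_count))` — keeping the first and
last picks; the even rule preserves uniform coverage and avoids any
seed dependence. Note the literal reading "keep every ⌈n/target⌉-th"
cannot yield an exact target size (30 → every 2nd gives 15, not 20),
which is why the even-index formulation is used.

## Synthetic fixtures: what a green test establishes

`generate_genome()` draws i.i.d. bases at a stated GC fraction
(default 0.44, a rice-like nuclear genome) from a single integer seed;
`plant_repeat()`, `plant_duplication()` and `plant_hairpin()` overwrite
intervals with known structure and record a manifest. The default
two-chromosome fixture plants a 1-kb repeat, a 600-bp exact
cross-chromosome duplication, 45-bp copies at 11 and 12 substitutions
(straddling the 75% boundary) and a 14-bp-stem palindrome — one planted
cause for every filter.

The generator emulates *composition*, not *genome biology*: real
genomes have segmental duplications with indels, nested
transposable-element families, GC isochores and assembly gaps, none of
which are modeled. A green suite therefore establishes that the filters
implement their stated rules exactly (against brute-force oracles and
hand-computed thermodynamic values), not that the heuristic search or
the thermodynamic screen have been validated on real repeat
landscapes. Indels in particular are invisible to the ungapped identity
definition by construction.

## Numerical and degenerate-input choices

* Identity threshold uses ceiling semantics with a 10⁻⁹ guard against
  floating-point boundary error (`ceiling(0.75 × 45 − 1e−9) = 34`).
* Both Tm computations are pure functions, bit-identical across runs;
  the compiled hairpin kernel and the R duplex-Tm function share the
  same parameter vector and summation order (tested to 10⁻⁹ °C).
* A sequence shorter than the oligo length tiles to an empty candidate
  set; an empty chromosome produces an all-zero stage report and an
  empty BED, both successes, not errors.
* An impossible density (bin width < oligo length) is a hard error, as
  is a BED with unsorted probes, a missing chromosome, or a candidate
  whose own source locus fails to be recovered by the search
  (internal-consistency guard).
* Probe ids are assigned after selection (`<chrom>_probe_<n>`), so ids
  are stable for a fixed input and configuration.

## Known limitations

* Ungapped identity only; a diverged copy with indels is not seen as a
  competing locus.
* The hairpin screen is a stem-stability bound, not a fold; it
  over-culls short-stem oligos and ignores multi-branch structures.
* No GC-content or homopolymer-complexity filters are applied (none are
  part of the reproduced procedure); the configuration leaves room for
  them as extension points.
* The exact search mode is quadratic and intended for ≤ ~100 kb test
  genomes; chromosome-scale runs should use the seeded path.
* Absolute Tm values depend on the chosen salt/strand conditions;
  reproducing a historically published probe list exactly may require
  matching the original tool's (unstated) thermodynamic defaults.
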