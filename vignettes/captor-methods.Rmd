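---
title: "Control library adaptors: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control library adaptors: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(captor)
```

This vignette explains the science implemented by `captor`: what each stage
models, which parameters matter and why their defaults were chosen, what the
simulator does and does not emulate, and where the design was genuinely open.

## 1. Why control adaptors

Sequencing adaptors are ligated to every fragment of a library, so an adaptor
that carries designed reference content is an internal control that costs no
extra protocol step and cannot be over- or under-spiked: it arrives in a fixed
1:1 ratio with the sample molecules. On a long-read platform the adaptor can
be long enough (90 nt here) to encode real information: a diversity of 6-mers
for error profiling, a known concentration for quantification, or an entire
clinical exon for matched error correction.

## 2. Panel design

Each adaptor is `constant5 + variable + constant3`, by default 30 + 30 + 30 nt.

* The shared 5' constant acts as a *burn-in*: the first 15–20 nt of a
  nanopore read are systematically less accurate, and placing a constant,
  analysis-expendable segment there keeps that noise out of the informative
  region. It also serves as the anchor that localises the adaptor during
  classification.
* The shared 3' constant equalises ligation ends so no adaptor is
  preferentially incorporated.
* The variable regions are windows of a **de Bruijn source sequence**
  `B(4, 6)` — length `4^6 + 5` with every 6-mer exactly once — built by the
  Fredricksen–Kessler–Maiorana necklace concatenation and rotated to a
  seed-determined start. Windows are selected greedily by the number of
  not-yet-covered 6-mers they add. 72 windows of 30 nt can cover at most
  72 × 25 = 1800 of the 4096 6-mers; the designer therefore maximises and
  *reports* coverage (the default design reaches the 1800 ceiling because
  de Bruijn windows never repeat a 6-mer). Completeness across the panel is
  not claimed, only diversity.

Two screens emulate the wet-lab exclusion criteria with deterministic local
computations:

* **Homology screen**: the longest exact substring (either strand) shared
  with a user-supplied FASTA must be ≤ 20 nt. This is a self-contained
  surrogate for an online BLAST search; 20 nt is short enough that a chance
  exact match to a genome is vanishingly unlikely to mediate mispriming or
  misassignment.
* **Hairpin screen**: the longest contiguous self-complementary stem with a
  loop of ≥ 3 nt must be ≤ 8 nt. The stem is contiguous Watson–Crick pairing
  only (no wobble, no bulges) — the simplest testable surrogate for a
  secondary-structure prediction, and the variant that admits an exact
  brute-force oracle in the test suite.

Candidates failing a screen are skipped deterministically in favour of the
next-best window, so a given seed always yields byte-identical panels. The
constant segments are seed-derived random sequences passed through the same
screens (the published constants are not public, so the package generates its
own; any real constant pair can be substituted via `make`-style panel
construction).

`min_pairwise_edits = 10` between variable regions is a package choice (the
source design does not state one): at a per-base error rate of ~0.1, a read
needs ≥ 5 well-placed errors to cross half the distance to another adaptor,
which keeps misclassification effectively at zero (the test suite asserts
zero misassignments on 5,000 simulated reads).

## 3. The staggered master mix

`build_staggered_manifest()` splits the panel into `n_levels = 8` groups of
`group_size = 9` and dilutes group *g* by `fold^g` (`fold = 2`), mixing equal
amounts of each dilution. Relative concentration is therefore `2^-g` per
adaptor and the expected read fraction `2^-g / (9 · Σ_{g=0}^{7} 2^-g)`; the
dynamic range is 128-fold and the most dilute adaptors are expected at
1/2295 ≈ 0.044 % of reads — below 1 %, so the low end of the ladder probes
realistic low-abundance quantification. Group assignment is input-order
deterministic; a seeded shuffle is available but off by default so manifests
are reproducible artifacts.

## 4. The read simulator

The simulator exists so that every downstream stage has exact ground truth.
A read is `adaptor + insert (+ adaptor)`, passed base-by-base through a
context-dependent error channel, and emitted on a random strand (probability
0.5, flagged in the truth table).

**Context error model.** For each 6-mer and each error class
(mismatch/insertion/deletion):

```
rate = clamp(base + gc_slope·GC + homopolymer_slope·(maxrun − 1) + e, 0, 0.5),
e ~ Normal(0, systematic_sd)  (drawn once per 6-mer per class, fixed by seed)
```

The defaults — `base_mismatch 0.020`, `base_insertion 0.018`,
`base_deletion 0.018`, `gc_slope 0.015` (per unit GC fraction),
`homopolymer_slope 0.006` (per extra run base), `systematic_sd 0.008` — were
chosen once so that class means land near reported MinION R9.4.1 figures
(mismatch ≈ 0.03/nt, indel ≈ 0.06/nt, total ≈ 0.09/nt) with positive GC and
homopolymer effects, and a reproducible (systematic) per-6-mer component that
dominates resampling noise. The per-6-mer offsets make two simulated
libraries agree far better with each other than chance, mirroring the
observation that nanopore errors are predominantly systematic.

**Channel (pore) model.** Each read draws a channel with throughput weights
`1/multiplier` and scales its error rates by the channel's multiplier
(log-normal, `sdlog 0.35` over 12 channels by default): inaccurate pores are
also low-throughput, and the max/min accuracy ratio across channels is a
few-fold. Start times are uniform over the run; `ch=` and `start_time=`
appear in the FASTQ headers exactly as the downstream parser expects.

**Mechanics and their limits.** At most one event per template position; the
context is the template 6-mer ending at the emitted base (the first five
positions use an implicit A-padding); insertions emit one uniform base after
the current position; quality strings are constant placeholders. Positions
are independent given context — real nanopore errors are autocorrelated
within reads, base-caller dependent, and quality-informative, none of which
is modelled. Passing tests therefore demonstrate that the *analysis* recovers
what the *generator* injected under a faithful-but-idealised error process;
they do not certify accuracy numbers on real flowcells.

## 5. Classification and event profiling

Reads are clipped to their first 500 nt. Classification is two-stage,
all unit-cost semi-global (fitting) alignment — reference end-to-end, free
query end gaps, traceback preference match > mismatch > deletion > insertion,
leftmost minimal end:

1. the shared 5' constant is located on the read and (optionally) its reverse
   complement; a strand whose constant fits far worse than the other's is
   skipped;
2. every variable region is scored inside the localised window; the minimal
   edit distance wins. An exact tie between distinct adaptors is
   `UNCLASSIFIED` — ambiguity is data, not an error.

The decision *between* adaptors uses only the variable region (the constants
carry no between-adaptor signal). The *classified-versus-unclassified* gate
uses the full-adaptor identity against `min_identity = 0.7`: a genuine
adaptor read also matches the constants, while the best variable-region match
of a random sequence against a 72-strong panel can reach ~0.7 identity by
chance, so gating on the variable region alone would admit noise. Identity
0.7 sits ~3 standard deviations above random full-adaptor identity (~0.6) and
far below genuine reads (~0.9 at default error rates).

Doubly-ligated reads carry adaptors at both ends; a read may legitimately
classify by either (both are independent draws from the same master mix, so
ladder statistics are unaffected). Event profiles attribute insertions to the
reference position immediately 5' of the inserted base (pileup convention),
giving the invariant `n_match + n_mismatch + n_deletion = depth` at every
position.

## 6. Per-6-mer error tables and their estimator

`kmer_table()` restricts each profile to the variable region, slides 25
overlapping 6-mer windows across it, takes the unweighted mean of the
positional rates over each window's six positions, and averages across all
instances of a 6-mer. Positions below `min_depth = 10` invalidate their
windows (skipped and logged) rather than biasing the mean.

Two properties of this estimator matter when comparing recovered rates with
a known injected model:

* It is evaluated per 6-mer at the *window* scale, so its binomial standard
  error at depth *d* is ≈ `sqrt(p(1−p)/(6d))`.
* Alignment-based error measurement has a class-identifiability limit:
  an injected insertion adjacent to a deletion can re-align as a single
  mismatch, deflating indel rates (≈ −15 to −20 % relative at default rates)
  and inflating mismatches, with a ~5 % deflation of the total. This is a
  property of minimum-edit alignment, not of the generator.

The package's recovery check (test suite) therefore evaluates agreement at
~400 reads per adaptor, where 3 binomial SE (~20 % relative) comfortably
contains the estimator's alignment bias; at several thousand reads the SE
shrinks below that bias and the comparison would measure alignment
identifiability, not recovery. Rate recovery uses truth-table alignment
(reads aligned to their known adaptor), while the ladder is computed from
end-to-end classification.

Replicate agreement (`compare_tables()`) is quantified as the symmetric mean
relative difference `mean(100·|a−b| / ((a+b)/2))` per class, excluding
6-mers at zero in both tables. The metric is a documented stand-in — the
upstream literature reports replicate percentage differences without a
formula — so no equivalence to any published value is claimed.

## 7. Ladder, LOQ and depth

`ladder_fit()` regresses log2 observed count on log2 relative concentration.
Zero-count adaptors are excluded rather than pseudocounted — a pseudocount
would bend the low end of an otherwise linear ladder exactly where the signal
of interest (drop-out) lives; they are reported as not-detected instead. The
log2–log2 axes choice follows the standard presentation of spike-in ladders.

`segmental_fit()` fits a continuous two-segment model `y ~ x + max(x − c, 0)`
with the breakpoint *c* searched over midpoints between consecutive distinct
x values (each side must keep ≥ 2 points at ≥ 2 distinct x). The LOQ is the
fitted count at the breakpoint, `2^ŷ(c)`, in reads. Collinear input is
flagged degenerate (breakpoint at the boundary); a side whose observed values
have no variance — e.g. a fully detection-censored low end where every
surviving count is 1 — reports `NA` R², and the under-sampled regime then
shows as a flattened left slope.

`min_reliable_depth()` operationalises "reliable quantification" as: every
manifest adaptor detected with ≥ 5 reads *and* ladder R² ≥ 0.95. The
criterion is configurable because the upstream notion is qualitative; with
the default manifest the most dilute adaptor at 1/2295 needs on the order of
`5 × 2295 ≈ 10^4` reads, which is why full-dynamic-range quantification
requires a few ×10⁴ reads.

## 8. Normalisation

`tmm_factors()` fronts edgeR's TMM (trim 0.3 on M, 0.05 on A, precision
weights, reference = upper-quartile-closest-to-mean, factors scaled to
geometric mean 1) — the package treats TMM as an established step, not a
contribution. `ruvg_normalize()` implements control-anchored RUVg directly:
`log(count + 1)` of the control rows, row-centred; SVD; the first *k*
sample-space singular vectors form W; W is regressed out of every log row and
the matrix exponentiated back. `k = 1` is the default (smallest model); the
planted-batch benchmark uses `k = 2` because its unwanted variation has two
components (a feature-loaded batch factor and a depth scalar). Adaptor rows
are ideal negative controls: the master mix is identical in every library, so
any between-sample variation they show is technical by construction, and
using them relaxes the usual assumption that most features are unchanged.

Fold-change evaluation uses an effect-size threshold (|log2FC| ≥ 1 detected)
rather than significance tests: at desk-scale replicate counts (3 per
condition) p-value machinery would test the noise model more than the
normalisation, and the upstream ANOVA-style testing is explicitly out of
scope.

## 9. Gene-specific controls and subtraction correction

A gene control is an exact strand-aware slice of a reference exon
(`design_gene_controls()`, 0-based half-open BED coordinates). Sequenced
alongside patient fragments of the same exon, it shares their systematic
error profile; `subtract_profiles()` computes
`corrected = max(0, sample − control)` per position and class (rates are
probabilities, so negative differences clamp at zero — the upstream
description is silent on this point). Subtraction removes the shared
systematic component while a true variant, present only in the sample,
retains its excess rate; summaries report medians before/after, and
`restrict_to_variants()` recomputes them over an annotated mask (or its
complement).

One caveat the correction benchmark makes explicit: a substitution variant
inside a homopolymer run has ambiguous positional attribution under
minimum-edit alignment (the mismatch can sit anywhere in the run), smearing
its excess rate over neighbouring positions. The benchmark therefore plants
its variants outside runs, so it measures subtraction, not repeat
ambiguity; real variant panels inside repeats would need run-aware
aggregation before correction.

## 10. Problem sizes and numerical conventions

The shipped analyses use desk-scale sizes chosen to keep every check
statistically meaningful: 50,000-read libraries for ladder and error-model
recovery (the depth at which the full 128-fold range is quantifiable),
~400 reads per adaptor for per-6-mer recovery, 400-read gene-control pools,
and six 2,500-read libraries for the normalisation benchmark. All randomness
flows from explicit integer seeds through R's RNG (the C++ mutation channel
draws from R's stream), so every artifact is byte-reproducible;
seeded functions restore the caller's RNG state. Coordinates are 0-based
half-open throughout; FASTQ parsing is permissive (CRLF tolerated, `+` line
ignored, absent header fields are `NA`, a malformed channel warns per read).

## 11. Known limitations

* The error model treats positions as independent given context; real
  nanopore error is autocorrelated and base-caller specific.
* The hairpin screen scores contiguous Watson–Crick stems only — no wobble
  pairs, bulges or free-energy model.
* The homology screen is exact-substring, not alignment-based; it will not
  flag a 25-nt region with one mismatch.
* Alignment-based error estimation redistributes adjacent indel pairs into
  mismatches; per-class rates at very high depth reflect this
  identifiability limit.
* Classification of doubly-ligated reads returns one of the two terminal
  adaptors; analyses that need the 5'-terminal one specifically should use
  single-ended simulation (`attach_3prime = FALSE`) or the truth table.
* `UNCLASSIFIED`/`UNASSIGNED` are values, not errors; pipelines must not
  treat their presence as failure.
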