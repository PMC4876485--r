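---
title: "Methods: colored de Bruijn graph coassembly of MDA-amplified single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colored de Bruijn graph coassembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Multiple displacement amplification (MDA) of a single bacterial cell
produces reads with two pathologies: depth that varies over orders of
magnitude along the genome, and *blackout regions* that were never amplified
and therefore contribute no reads at all. The loci affected differ between
independently amplified cells, which is the opening coassembly exploits: a
region invisible in one cell is usually well covered in another.

`coasm` builds one de Bruijn graph over all input read sets. A vertex is a
*canonical* k-mer — the lexicographic minimum of the k-mer and its reverse
complement — and carries an integer multiplicity per input data set
("color"). An edge exists between two vertices only when some read contains
the two k-mers consecutively, i.e. when the corresponding (k+1)-mer was
observed; adjacency is never inferred from bare (k−1)-overlap. Contigs are
maximal non-branching paths of the *union* (color-blind) graph, annotated
afterwards with their average multiplicity per color. Everything downstream
— rescue, trimming, and the exclusivity analysis — follows from that vertex
bookkeeping.

Graph cleaning happens in two stages, in this order:

1. **Tip clipping.** A unitig with exactly one dead end, shorter than
   `tip_len_factor * k`, is removed when the best competing branch at its
   attachment junction has strictly greater max-over-colors average
   coverage. Isolated linear pieces are never tips. This targets the
   read-end error spurs classical de Bruijn assemblers clip.
2. **Progressive coverage trimming.** `trim_steps` thresholds rise linearly
   from `cutoff/trim_steps` to `cutoff`; at each step the graph is
   re-condensed and every unitig whose **maximum** per-color average
   coverage is below the threshold is deleted. Judging on the max over
   colors is the rescue mechanism: one strong color saves the unitig for
   all colors, while many weak colors cannot jointly fake strength (a sum
   would let them). The gradual schedule mimics the progressive cutoff of
   the Velvet-SC lineage of single-cell assemblers, which this package's
   cleaning is modeled after; the ancestry prescribes no exact schedule, so
   the linear ramp is our choice.

The comparison module works at whole-contig granularity: a contig is
*present* in a color when its average coverage there is strictly greater
than `presence_epsilon` (default 0). Because contigs come from a single
union graph, any sequence of length ≥ k shared between two colors already
lies in common contigs, so shared/exclusive base-pair totals need no
alignment. The exclusivity ratio of color *i* w.r.t. *j* is
exclusive(i)/total(i), 0 when the total is 0.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 25 | k-mer size (odd, 3–31); 25 suits 34–58 bp single-cell reads |
| `coverage_cutoff` | 100 | final trimming threshold on max-over-colors average unitig coverage; the standard deep-lane setting — scale it with depth (the 50× simulations use 5) |
| `trim_steps` | 10 | number of progressive thresholds |
| `min_contig_len` | 100 bp | output length filter |
| `presence_epsilon` | 0 | strict lower bound for color presence |
| `tip_len_factor` | 2 | tips shorter than `2k` are clippable |

The upper bound k ≤ 31 comes from 2-bit packing of k-mers (and their
(k+1)-mer edge witnesses) into 64-bit words in the compiled core. Counts
saturate at 2^32 − 1 per color per k-mer.

## Numerical and tie-breaking conventions

* k is forced odd so no k-mer equals its own reverse complement, making
  canonical orientation total. Whether the original method used canonical
  k-mers or an explicitly bidirected graph is not documented; canonicalization
  is our convention, standard across de Bruijn assemblers.
* All node iteration and output ordering is lexicographic on canonical
  sequence (byte order, locale-independent); contig sets are sorted by
  length descending then sequence ascending. The assembler draws no random
  numbers, so identical inputs give byte-identical outputs.
* Unitig sequences are emitted canonically (min of sequence and reverse
  complement). Perfect cycles — components where every vertex has one
  predecessor and one successor — are emitted as a linear walk starting at
  the component's lexicographically smallest k-mer in forward orientation.
* Coverage is the *unweighted mean of k-mer multiplicities* over a contig's
  constituent vertices, not per-base read depth.
* Interval outputs (blackout BED) are 0-based, half-open.
* Exclusivity ratios are stored at full precision; report layers round (the
  pairwise TSV prints 4 decimals). Published pairwise tables mix 3- and
  4-decimal conventions, so we deliberately do not bake any rounding into
  the statistic itself.

## Design choices where the design was open

* **Iterative multi-k assembly** (`iterative_assemble()`): injecting one
  round's contigs as pseudo-reads into the colors where they are present
  lets a larger k resolve repeats that fragment the smaller-k assembly. The
  method family both describes this adaptation and reports its headline
  results without it, so the mode exists but is off by default everywhere;
  the single-k `assemble()` is the reference behavior.
* **Cleaning order** (tips before coverage trimming) is unstated upstream;
  clipping error spurs first prevents a spur from splitting a unitig that
  trimming should judge as a whole.
* **Comparison granularity**: shared/exclusive totals are computed from
  whole-contig presence vectors rather than sub-contig sequence
  intersection; on a union graph the two coincide for material ≥ k, and the
  former requires no alignment machinery.
* **Pairwise arithmetic from published totals**:
  `exclusivity_from_totals()` exists so that the decomposition can be
  applied when only total and shared assembly sizes are known; it is the
  same invariant (total = shared + exclusive) the full pipeline obeys.

## The simulator: what it emulates and what it does not

`simulate_cell()` models exactly the two MDA pathologies the assembler
addresses: (1) blackout — `num_blackout_intervals` non-overlapping
intervals totaling `floor(blackout_fraction * len)` bp, placed uniformly at
random, in which no read may start; and (2) multiplicative gain bias —
per-window (500 bp) lognormal weights `exp(N(0, gain_sigma^2))` that scale
the read-start probability. Read counts are Poisson around
`mean_depth * len / read_len`; strands are uniform; errors are i.i.d.
substitutions. Reads that *start* outside a blackout may run into it, so the
realized zero-coverage span of an interval shrinks by up to `read_len` at
its left edge; tests account for this.

Defaults (2% blackout in 4 intervals, `gain_sigma` 1, 50× depth, 50 bp
error-free reads) are the package's standard experimental conditions: a
blackout fraction between the published per-cell estimates for real single
cells (≈0.1–1.8% of an *E. coli*-sized genome, here set slightly above so
the effect is unambiguous at 100 kb scale), unit log-gain dispersion as a
moderate bias level, and read length/depth typical of the short-read
single-cell data the method targets.

The simulator does **not** model chimeric reads, paired ends, quality-score
decay, GC-dependent or otherwise deterministic bias, or contamination.
Passing the rescue and exclusivity tests therefore demonstrates the graph
semantics (union coverage, max-over-colors trimming, presence bookkeeping)
under realistic dropout geometry — it does not certify performance on real
MDA libraries, whose bias is structured and whose errors are not uniform.

## Problem sizes used by the test suite

The suite exercises full-scale graph logic at desk scale: oracle
equivalence against a brute-force pure-R condenser on 50 random genomes of
0.2–2 kb at k ∈ {7, 15}; the rescue experiment on a 100 kb genome, two
cells, 50× (individual assemblies miss ≥ 1.5% of reference bases, the
coassembly's per-cell slices ≤ 0.2%); exclusivity separation on 50 kb + 40 kb
genomes with three cells (same-genome ratios ≤ 0.02, cross-genome ≥ 0.95);
and simulator calibration over 10 seeds (realized blackout within ±20% of
the requested fraction, cross-cell blackout overlap < 0.5%). These sizes
were chosen as the smallest at which the phenomena are comfortably away
from their thresholds.

## Known limitations

* No error correction, bubble popping, scaffolding, or paired-end use —
  deliberately, matching the scope of the method this package implements.
* k ≤ 31; genomes are held in memory (hash-table counting, no disk spill).
* The k-mer reference evaluator is a surrogate for alignment-based
  evaluation: monotone in completeness, but its "missing bases" are not
  comparable to alignment error classes (SNPs, indels, relocations).
* A real-data coverage track requires an external mapper; within the
  package, coverage tracks come from the simulator.
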