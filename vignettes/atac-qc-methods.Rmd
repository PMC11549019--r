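---
title: "Methods: single-pass ATAC-seq quality control in atacqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-pass ATAC-seq quality control in atacqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacqc)
```

## The procedure

`qc_run()` makes one pass over a coordinate-sorted BAM. Records are read in
chunks (200,000 by default) and converted to a per-read table with 0-based,
half-open coordinates — the native convention of both BAM and BED, used
internally everywhere; 1-based coordinates appear only in samtools-style
region strings, converted on parse. Each read receives a category from the
reference catalog (nuclear by default; mitochondrial or plastid when its
reference name matches the organelle name lists, case-insensitively) and a
verdict under the active criteria. Checks run in a fixed order — unmapped,
secondary, supplementary, QC-fail, duplicate, proper pair, MAPQ, fragment
bounds, organellar, target/blacklist — and all applicable failure reasons are
recorded rather than short-circuiting, so the failure tally is complete.

Counters update for every read; histograms and depth events only for passing
nuclear reads. Fragment lengths are |TLEN| of properly paired reads, counted
once per fragment via the mate with positive TLEN. Depth uses the full
alignment footprint (start to CIGAR-derived end), not the 5′-resized
interval: depth describes sequencing evidence, whereas resizing is a
signal-processing transform applied only to pileups and footprints.

Assumptions: the input is coordinate-sorted (enforced via the header `SO`
tag and a monotonicity check during the pass, since a stale tag is possible);
duplicates are recognized solely by SAM flag 0x400 — upstream markers set
it, and re-deriving duplicates from coordinates would duplicate their job
incorrectly; single-end data skip (rather than fail) the pairing and
fragment filters, and fragment statistics are reported as unavailable.

## Parameters

| parameter | default | units | notes |
|---|---|---|---|
| `min_mapq` | 0 | phred-like | §grid exploration typically 0–40 |
| `min_fragment`, `max_fragment` | 0, unlimited | bp | applied to \|TLEN\| of proper pairs |
| `nfr` preset | `max_fragment = 120` | bp | sub-nucleosomal cutoff; the NFR/mononucleosome boundary sits between ~120 and ~147 bp and published pipelines use values in that range — 120 is this package's choice |
| `mono` preset | 150–250 | bp | one nucleosome plus linker |
| Tn5 offsets | +4 / −5 | bp | standard ATAC convention marking the transposition center; configurable |
| `resize` | 1 | bp | window width around the (shifted) 5′ end; `NA` in `chip` mode keeps full alignments |
| `tss_radius` | 1000 | bp | pileup half-width |
| `footprint_radius` | 100 | bp | TF footprints are local |
| `smooth` | 25 | bp | TES moving-average window |
| `flank_fraction` | 0.1 | — | fraction of window used as background per side |
| `max_fragment_tracked` | 2000 | bp | histogram cap; longer fragments pool into one overflow bin |
| periodicity `range` / `band` | 40–250 / 5–20 | bp | nucleosomal fragment range; candidate periods bracketing the 10.5 bp helical pitch |
| periodicity `prominence` | 15 | — | peak power over median band power required to call a period |

The TES formula (smoothed maximum over flank-mean background) is this
package's definition: the score is named in the ATAC literature but has no
single canonical formula, so the definition, its smoothing window and flank
fraction are recorded in every JSON report and agreement with any specific
external implementation is not claimed. It is constructed so that a flat
profile scores exactly 1 and the score is invariant to rescaling the
profile, which makes the degenerate cases testable.

## Numerical choices

* **Histogram medians** use the lower-bin convention: the smallest bin value
  at which cumulative mass reaches half the total. Deterministic and exact
  on integer-binned data.
* **Even resize widths** are left-biased by one base (window start =
  shifted 5′ base − width/2), so every width has a well-defined window.
* **Unstranded anchors** use the interval midpoint, left-biased; stranded
  TSS anchors use the BED start (+) or end−1 (−), and minus-strand anchors
  have their axis flipped so downstream is always to the right.
* **Periodicity**: the histogram over the analysis range is divided by a
  centered 21-bp moving average and recentered (removing the broad
  fragment-size envelope while leaving a ~10.5 bp ripple nearly intact,
  since 21 bp spans two full periods), then a dense 2048-point periodogram
  over the period band is maximized with quadratic interpolation of the
  spectral peak. A period is called only when peak power exceeds 15× the
  median band power; below 1000 fragments in range the estimate is refused
  (`NA`). Both thresholds guard against reading periodicity into noise —
  in tests, unmodulated uniform libraries at typical fixture depth produce
  peak-to-median ratios around 7–10, modulated ones in the hundreds.
* **Depth** is computed per reference by a sweep over sorted start/end
  events (`cumsum` of +1/−1 deltas), giving bases-at-depth without a
  per-base array. The reported depth histogram covers depth ≥ 1; the
  depth-0 mass is `effective_genome − bases_covered` in the coverage block.
  The effective genome is the nuclear length, replaced by the target size
  under a restriction, minus blacklisted bases.
* **Degenerate inputs**: an empty BAM yields a complete report with zero
  counts and `NA` statistics; zero passing reads make FRiP `NA` with a
  warning; a zero pileup background makes TES `NA`.

Events are buffered per reference for the duration of the pass (memory
proportional to passing reads, not genome size); a production C
implementation would flush each reference as the stream leaves it, which the
per-reference sweep here mirrors structurally.

## The synthetic generator

`generate_fixture()` simulates paired-end fragments on a toy three-sequence
genome (200 kb nuclear, 30 kb mitochondrial, 20 kb plastid by default):
categories are drawn from stated proportions, fragment lengths from a
mixture of uniform/truncated-normal components, optionally reweighted by
`1 + a·cos(2πL/p)` via rejection sampling — a form whose spectral peak is
known exactly, making the periodicity estimator testable as parameter
recovery. Enriched components place fragment centers at anchors with
Gaussian spread (50 bp default), emulating TSS enrichment; a protection mask
rejects placements whose Tn5-shifted insertion points fall within a window
around TF sites, emulating footprints. Duplicate/secondary/improper-pair
rates set the corresponding SAM flags. Reads are error-free with fixed
length, random sequence at a set GC probability, and SAM-conformant flags
and TLEN; the leftmost mate carries the positive TLEN. Identical spec and
seed reproduce the fixture exactly.

Every fixture returns a per-read truth table from which the expected value
of each reported count is recomputable exactly — the tests assert equality,
not approximation, for category totals, passing counts, FRiP and fragment
histogram masses.

What the generator does **not** emulate: sequencing errors and base
qualities, alignment ambiguity (MAPQ is assigned, not earned), chimeric and
supplementary alignments, GC-coverage bias, and real genomic sequence.
Passing tests therefore demonstrate the correctness of the counting,
filtering and signal machinery on known ground truth — not that any
particular real library will look like a preset. Preset fixtures
(`preset_fixtures()`) cover the regimes relevant to QC interpretation:
`clean`, `free_dna` (uniform, unmodulated — no periodicity should be
called), `organellar_heavy`, `footprint`, and `grid` (TSS-enriched
nucleosome-free signal at high MAPQ over long-fragment and low-MAPQ noise,
for threshold exploration). Generator parameters are fixed properties of
these regimes, chosen once to represent them.

## Design decisions in open territory

* **Filter order and preset thresholds** are not externally specified; the
  order above and the 120/150–250 bp presets are documented choices.
* **GC content** is computed from the stored query sequence including
  soft-clipped bases; records without a sequence contribute nothing.
* **Overlap semantics** are any-overlap (≥ 1 bp) everywhere — region
  restriction, target, blacklist, FRiP — matching indexed region queries.
* **`use_all`** still excludes unmapped, secondary and supplementary
  records, so "all reads" means all mapped primary alignments.
* **Percentages** are emitted against both denominators (total reads;
  mapped reads), each labeled, since either convention is defensible.
* **Filtered BAM** records are copied verbatim (auxiliary tags preserved)
  by re-running the same verdict function used for QC inside the BAM
  filter, so the written count provably equals the reported passing count.
* **JSON** field names are this package's contract (schema shipped in
  `inst/schema/`, versioned, validated structurally on read and write;
  unknown fields tolerated on read). Numbers are serialized at 17
  significant digits so doubles round-trip bit-exactly; unlimited
  `max_fragment` serializes as `null`.

## Problem sizes

The test suite runs on fixtures of 500–8000 fragments (1000–16,000 reads) on
the 250 kb toy genome, 20 randomized depth comparisons against a per-base
oracle on 20–100 kb references, a 125-cell threshold grid, and one
million-fragment periodicity recovery; the whole suite completes in well
under a minute on one core. These sizes give exact truth-table equality
checks and binomially tight distributional checks while keeping the suite
fast; nothing in the method depends on them.

## Known limitations

Single-threaded; `--threads` is accepted for interface compatibility but
serial. CRAM is not supported. No per-base signal output (bedGraph/bigWig),
no peak calling, no duplicate marking. Chunked streaming holds one chunk of
parsed reads plus the passing-read interval table in memory, which is ample
for QC-scale work but not the constant-memory profile a C implementation
would achieve.
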