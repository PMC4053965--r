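---
title: "Methods: splice-junction discovery, event classification and differential splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splice-junction discovery, event classification and differential splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the numerical choices and
the design rationale behind `splicewatch`. Code chunks are illustrative
and not evaluated; the quantitative guarantees quoted here are exactly
the ones computed by the test suite (`tests/testthat/test-acceptance.R`)
and by `scripts/acceptance.R`.

## Data model

The pipeline's primary input is a set of *spliced alignments*: per read,
an ordered list of aligned reference blocks. A read whose alignment
jumps an intron contributes two (or more) blocks separated by a gap; the
gap interval *is* the junction observation. Internally every interval is
0-based half-open; the GFF3 (1-based closed) and SAM (1-based) formats
are converted only in the readers/writers, so no coordinate arithmetic
ever mixes conventions.

Strand is handled in *transcribed orientation*: for a minus-strand gene
the donor of an intron is its genomic **end** coordinate, intron ranks
run right to left, and all signed quantities (alternative-site offsets,
site-matrix positions, coverage-profile bins) are reported 5′→3′ along
the transcript. This single convention is applied in one place per
module (`annotation_introns()`, `exons_transcribed()`) rather than
scattered sign flips.

## Junctions and the false-positive filter

A junction's support is summarised by two statistics:

* `read_count` — reads whose gap equals the interval exactly;
* `max_overhang` — over those reads, the maximum of each read's
  *shorter* gap-adjacent block.

Misplaced reads produce junctions that look exactly like real ones in
coordinates but not in these statistics: they pile up at short overhangs
and singleton support. The filter keeps a junction iff
`max_overhang > 20` (strict, so 21 nt is the smallest kept) and
`read_count >= 2`.

The calibration instrument is the *decoy junction null*: reference
sequences formed by concatenating the donor-side flank of one intron
with the acceptor-side flank of an intron on a **different chromosome**.
Flanks are `read_length − 11` nt of spliced transcript context each
(180 nt references for 101 nt reads), so a read placed across the
midpoint necessarily anchors ≥ 11 nt on both sides. Matching is exact
substring placement (`Biostrings::matchPDict`); a read matching one
reference at several offsets counts once at its largest overhang. The
matcher is deliberately mismatch-free: the null asks what *perfectly
matching* but biologically impossible junctions look like, which is the
conservative case for the filter. An independent brute-force all-offset
scanner in the test helpers serves as its oracle.

The generator plants 100 decoy reads with 11–15 nt overhangs and
singleton support — at or above the anchor (so every decoy registers
with the matcher and the filter is genuinely exercised) and at or below
the short-overhang profile of false positives. The acceptance suite
verifies that the filter removes 100% of them while retaining ≥ 95% of
observed true junctions at ≥ 30× exon depth.

## Event classification

Unannotated filtered junctions are interpreted against the annotated
introns of their gene:

* **CASSETTE / COORD_CASSETTE** — both junction ends coincide with
  annotated exon boundaries such that one (or ≥ 2 consecutive) internal
  exons are skipped.
* **ALT5SS / ALT3SS** — the junction shares its acceptor (donor) with an
  annotated intron but moves the other end. The *dominant* counterpart
  is the annotated intron with the highest catalog read count (ties →
  shortest), and the offset is signed downstream-positive in transcribed
  orientation. The generator plants offsets uniformly on ±2..±10 nt;
  the acceptance suite requires exact signed recovery on both strands
  and ≥ 95% of the offset mass within ±10 nt.
* **ALT_FIRST / ALT_LAST** — the moving end pairs with a terminal intron
  but lies outside the annotated terminal exon and intron.
* **MUTEX** — two cassette events skipping adjacent exons whose
  separating intron is absent from the catalog (the exons are never
  observed co-included); both members are relabelled.

Each junction receives at most one type; junctions in no gene are
`intergenic`, unmatched ones `unclassified` — nothing is silently
dropped.

**Intron retention** is called from unspliced coverage: ≥ 5 distinct
reads overlapping the intron *without* being gapped exactly over it, and
≥ 50% of intron bases covered at least once by such reads. Reads gapped
over a different interval inside the intron still count — their gap is
not this intron. The retained fraction is estimated as intron RPKM over
the combined RPKM (summed counts over summed length) of the two flanking
exons, with a flagged `NA` when the flanks are unexpressed.

**Frame impact** (`frame_impact()`) classifies the coding consequence: a
net change that is not a multiple of 3 is a frameshift; an in-frame
insertion is scanned for stop codons in the reading frame given by the
insertion point's phase, distinguishing clean in-frame indels from
premature termination inside a retained intron.

## Differential testing

Libraries are resampled to equal depth (uniform, without replacement,
seeded) before any counting, so read-count comparisons across conditions
need no offset terms. Each event or intron yields the 2×2 table

|            | condition A | condition B |
|------------|-------------|-------------|
| focal reads| $a$         | $b$         |
| flanking-exon reads | $c$ | $d$        |

tested two-sided with `fisher_2x2()`: the p-value sums, over the
hypergeometric support fixed by the margins, every table probability not
exceeding the observed one, with a `1e-7` *relative* tolerance absorbing
floating-point ties (without it, mathematically tied tables on the other
tail are dropped or kept unpredictably). A zero margin returns p = 1
with a warning rather than an error, since zero-information rows occur
routinely in genome-wide sweeps. `stats::fisher.test` is used only as an
independent cross-check in tests; the acceptance suite additionally
compares against an `lchoose`-based enumeration oracle over every 2×2
table with all margins ≤ 30, requiring max |Δp| < 1e−12.

Significance uses unadjusted α = 0.01 for events and α = 0.001 for
introns (a Benjamini–Hochberg column is emitted for convenience). An
event observed in only one condition cannot produce a meaningful Fisher
p against a zero column; the *assigned-zero rule* declares it
significant when it has ≥ 5 focal reads, reporting `p = 0` with an
explicit `assigned_zero` flag so downstream consumers can always
separate assigned from computed values. Direction labels are strict
(`none` on exact rate ties), which makes them antisymmetric under
condition swap — a property the unit tests pin down.

## Generator design, realism and limitations

The generator is the package's measurement standard, so its biases
matter more than its realism:

* **Molar sampling.** A read is a window on a molecule, so isoforms are
  sampled proportionally to mixture weight × isoform length within a
  uniformly chosen gene. Sampling by weight alone under-covers long
  (e.g. intron-retaining) isoforms per base and biases the IR-proportion
  estimator; with molar sampling the estimator is unbiased up to edge
  effects, and the acceptance suite recovers a planted retention
  fraction of 0.15 within [0.12, 0.18] over 50 introns.
* **Planted truth, not an aligner.** Alignments are derived from the
  generating isoform, so coordinates are exact; substitution errors (per
  base 0.001) are applied to the raw sequences only. This isolates the
  pipeline's own behaviour from aligner artefacts — decoy reads model
  the mismapping channel separately and controllably.
* **Canonical boundaries by construction.** Every annotated intron is
  forced to GT..AG on the transcribed strand, giving the site-matrix
  module an exact expected answer (100% purity at donor +1/+2 and
  acceptor −2/−1).
* **Geometry.** Defaults: 3–5 exons of 100–250 nt per gene, introns
  60–150 nt, genes alternating strand and distributed round-robin over
  ≥ 2 chromosomes (cross-chromosome decoys need two). Known
  limitations: uniform base composition (no real splice-site motif
  beyond the planted dinucleotides, no GC structure), single-isoform
  annotation per gene, no overlapping genes, no indel or clipping
  errors, constant FASTQ quality. These are deliberate: each omission
  removes a confounder from parameter-recovery tests.

## Determinism and problem sizes

One run-level seed fans out to stage seeds through
`derive_seed(seed, stage) = (seed · 2654435 + 97 · stage) mod 2147483629`,
keeping every derived seed below 2³¹; each stage is independently
rerunnable. `run_all()` writes every table with a fixed-format TSV
writer and records md5 checksums in a JSON manifest; two runs with the
same configuration are byte-identical, which the acceptance suite checks
at the package's reference scale (200 genes, two conditions, 50 000
reads each — a couple of minutes on one CPU). Unit tests run at 6–14
genes and a few thousand reads; the calibration and recovery worlds use
40–70 genes and 25 000–60 000 reads, chosen so that every guarantee is
exercised with comfortable margins (≥ 200 true junctions at ≥ 30×;
50 planted introns at ≥ 50×) while the whole suite stays desk-sized.

```{r example}
library(splicewatch)
cfg <- run_config(
  sim = sim_config(n_genes = 30L, library_depth = 15000L, seed = 42L),
  conditions = list(WT = list(),
                    MUT = list(n_ir = 3L, n_alt5 = 3L, n_alt3 = 3L,
                               n_skip = 2L)))
res <- run_all(cfg, "demo_run")
str(res$offsets)
```
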