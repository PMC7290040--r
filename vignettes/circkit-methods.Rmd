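---
title: "Methods: back-splice junction analysis and translation evidence in circkit"
author: "circkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: back-splice junction analysis and translation evidence in circkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circkit)
```

## Background

Circular RNAs (circRNAs) are covalently closed transcripts produced by
back-splicing: a downstream 5′ splice donor is ligated to an upstream 3′
acceptor, creating a non-colinear joint — the back-splice junction (BSJ) —
that does not exist in any linear transcript. The BSJ is both the
diagnostic feature of a circRNA and the key obstacle to analyzing one: a
linear aligner cannot place a read across a joint that is absent from the
reference.

circkit implements the downstream-analysis layer for circRNAs that have
already been detected (by CIRI-style tools or curated databases): evidence
for their translation from ribosome profiling, classification of their
junction positions against a gene annotation, sequence meta-features, and
detection of flanking reverse-complementary repeats that can drive
circularization.

## The doubled pseudo-circular reference

For a circRNA occupying the genomic interval of length $L$, the package
extracts the genomic sequence $S$ (reverse-complemented for minus-strand
circRNAs, so $S$ reads 5′→3′ on the transcribed molecule) and concatenates
it to itself. On the doubled sequence $SS$ the BSJ appears as the ordinary
internal position between offsets $L-1$ and $L$ (0-based), so any linear
aligner can span it. Every circular substring of width $w \le L$ appears
as a contiguous window of $SS$; the suite checks this against a
brute-force circular-string oracle.

Two consequences are worth noting. First, a read shorter than the circle
covers each circular position at most once, and the per-position circular
coverage used by the mapping plot is the modulo-$L$ projection of the
doubled-reference span; total coverage mass equals
$\sum_\text{reads} \min(\text{aligned length}, L)$ exactly. Second, the
doubling guarantees that one read can align at two internal positions of
the same reference; junction evidence is therefore counted as *distinct
read ids*, never alignment records.

**Known limitation.** The circRNA is treated as its contiguous genomic
interval: introns of multi-exon circRNAs are not spliced out before
doubling. For exonic circRNAs with retained annotation introns the
simulated junction sequence differs from the mature molecule near internal
splice sites; the BSJ itself — the quantity everything downstream depends
on — is unaffected.

## Translation evidence from ribosome profiling

Ribosome-protected fragments are short (typically ~30 nt, under 50 nt), so
a read that happens to align across a BSJ may equally well originate from
rRNA contamination or from a similar region of a linear transcript. The
caller therefore works on three externally produced SAM alignment sets:
reads against an rRNA reference, reads against the linear
genome/transcriptome, and reads against the doubled junction references.

1. **Subtraction filter.** Any read with a mapped record (primary,
   secondary or supplementary alike) in the rRNA or linear alignments is
   discarded; only reads that failed both linear passes remain. When a
   read maps in both, it is attributed to the rRNA pass. Unmapped records
   (flag 0x4) never subtract. Any combination of linear inputs (genome,
   transcriptome, or both) is accepted and their union is subtracted.
2. **Junction-spanning criterion.** A kept read whose alignment span
   $[s, e)$ on the doubled reference satisfies
   $s \le L - v$ and $e \ge L + v$ spans the junction with overhang
   $v$ nt on each side. The default $v = 5$ is a deliberate choice:
   a 1-nt overhang on a ≤50-nt read is indistinguishable from alignment
   noise, while 5 nt remains permissive for 30-nt footprints (which can
   then start anywhere in a 21-position window around the junction).
   The overhang is a parameter everywhere it appears.
3. **Translation call.** A circRNA is called translated when at least 3
   distinct surviving junction-spanning reads support its BSJ. The
   threshold is exposed as a parameter; the translated set is
   non-increasing in it, which the suite verifies by sweeping.

## Seven-way junction classification

Each circRNA is classified by where the two boundaries of its BSJ fall
relative to the annotation. Boundary positions are the first and last base
*inside* the circle — stable under the half-open BED convention and
agnostic to whether a flank-based convention was intended. Each boundary
receives one of three contexts: `exon` (inside any annotated exon),
`intron` (inside a gene span but no exon), or `intergenic`. The unordered
context pair maps onto seven categories:

| boundary contexts | category |
|---|---|
| exon + exon, same transcript and exon ordinal | `same_exon` |
| exon + exon, otherwise | `different_exon` |
| exon + intron | `intron_exon` |
| intron + intron | `intron` |
| intron + intergenic | `intron_intergenic` |
| exon + intergenic | `exon_intergenic` |
| intergenic + intergenic | `intergenic` |

Deliberate resolution rules where annotations disagree: exon beats intron
across transcripts (a junction at an annotated exon boundary is an exonic
back-splice — the convention CIRCexplorer-style classifiers use); among
exon hits the transcript with the most exons wins, ties broken by
lexicographic transcript id; two exonic ends in *different genes* are
`different_exon`, with both gene ids recorded in the output for scrutiny.
Annotation strand is ignored for context lookup — the categories are
positional — and the circRNA strand is carried through to the output.
Classification is total and deterministic: every circRNA gets exactly one
label, independent of input order.

The per-chromosome density table bins circRNA *midpoints* into equal-width
half-open bins, so counts conserve exactly (one representative point per
circRNA); the figure-legend aliases `interg_exon_circ`/`interg_intron_circ`
seen elsewhere for the two mixed intergenic categories are not emitted —
the text labels above are canonical.

## Sequence meta-features

**Splice signals.** The signal of a circRNA is the dinucleotide
immediately 5′ of its start and the dinucleotide immediately 3′ of its end,
both read on the transcribed strand and reported as
`upstream/downstream` (e.g. `AG/GT`). For minus-strand circRNAs the two
plus-strand flanks are mirrored and reverse-complemented; the suite checks
this equivalence on random genomes. Whether such pairs should be read
donor-first or acceptor-first is a convention, not an inference — this
package fixes and documents the one above. Flanks running off a chromosome
end are padded with `N`.

**Histograms.** Length histograms use half-open bins $[kw, (k+1)w)$;
chromosome counts sort naturally (`chr2` before `chr10`); all tables
conserve totals and fractions normalize to 1, enforced by tests.

**GC track.** Non-overlapping windows (default 10 kb; the last window may
be short) with GC computed over the non-N denominator; all-N windows are
`NA`, not 0, so assembly gaps are not painted AT-rich. Bin and window
edges are uniformly half-open-right across the package.

## Stem-loop (reverse-complement repeat) scan

Flanking reverse-complementary repeats can base-pair across a circRNA and
promote circularization. For each circRNA the scan extracts `flank` nt on
each side (default 200, a typical search span for circularization
elements, truncated at chromosome ends), reverse-complements the upstream
flank, and locally aligns it against the downstream flank
(Smith–Waterman with affine gaps). The default scheme is BLASTN-like:
match +2, mismatch −3, gap open −5, gap extend −2, with a gap of length
$k$ costing $5 + 2k$. One optimal traceback is reported per circRNA — one
CSV row each — with the span on the upstream flank mapped back from
reverse-complement space into flank coordinates. The score of an empty or
all-negative comparison is 0 with an empty alignment.

Flanks are taken in genomic plus-strand orientation regardless of circRNA
strand: the revcomp-versus-direct comparison is symmetric under strand for
this purpose, and the local score itself is invariant under
reverse-complementing both sequences (a tested property). Identity is
matched columns over alignment columns, including gap columns. No score
threshold defines "a stem-loop": raw hits are reported and thresholding is
left to the user, since any cutoff is data-set dependent. Note that when a
perfect planted repeat is flanked by random sequence, the *optimal* local
alignment may profitably extend a few columns past the repeat, so
whole-alignment identity can fall slightly below 1.0 even though the
repeat itself aligns perfectly.

## Coordinate conventions

Genomic features — circRNAs, genes, exons, introns — live in `GRanges`
(1-based, closed), the native Bioconductor convention; BED input/output is
converted at the format boundary and GTF is native. Alignment spans and
all CSV/bedGraph outputs use the 0-based half-open convention of
BED/SAM-derived arithmetic (`ref_start = POS − 1`,
`ref_end = ref_start +` reference-consumed CIGAR length over M/D/N/=/X;
insertions and clips never extend the reference span). Each data kind uses
exactly one convention, and conversions happen only at read/write time.

## The synthetic study generator

The generator exists so that every module is testable end to end with no
download, with planted truth the pipeline must recover *exactly*. Its
defaults define the study conditions used throughout the tests and the
acceptance script:

* 2 chromosomes of 20 kb, 3 genes each (4 exons of 250–350 nt, introns of
  400–600 nt) separated by ≥2.2 kb intergenic gaps, plus a 2 kb `rRNA`
  contig excluded from the annotation — the minimal mechanism that makes
  every junction category geometrically realizable and gives the
  subtraction filter a real target;
* 5 circRNAs per category (35 total), boundaries placed inside the
  appropriate features with small random jitter;
* 30-nt reads (the ribosome-footprint regime), pure-match CIGARs so span
  arithmetic stays transparent; roles cycle through `translated` (5
  surviving junction reads each), `decoy_low` (≤2 surviving reads), and
  `decoy_filtered` (4 junction-spanning reads whose ids also carry mapped
  rRNA or linear records, so the filter must remove them); plus 300
  background reads mapped only to rRNA or the linear genome — roughly 500
  reads per data set;
* a 20-nt reverse-complement repeat planted in the flanks of
  intergenic-category circRNAs for the stem-loop scan;
* full determinism: one seed drives every stage, and identical
  configurations produce byte-identical files.

These sizes keep a full simulate–classify–call cycle under a few seconds,
so the recovery properties can be checked across 20 independent seeds in
the acceptance script. What the generator deliberately does **not**
emulate: sequencing errors and quality scores, ribosome dwell-time
structure, spliced (exon-joined) circRNA sequences, rolling-circle
multi-pass reads, and multi-mapping ambiguity beyond the doubled-reference
duplication. Passing recovery tests therefore demonstrates the logic of
the subtraction-and-threshold procedure and the classifier — not
robustness to alignment noise in real libraries, which belongs to the
upstream aligner.

## Numerical and degenerate-input choices

* Ties in the mapping table sort by junction reads descending, then
  lexicographic circRNA id.
* A read aligned multiply to one doubled reference counts once; reads
  aligned to references absent from the set are skipped with a message,
  as are alignment ids outside the declared read universe.
* Empty inputs are legal wherever they are meaningful (empty alignment
  sets, empty circRNA sets give header-only tables); an empty junction
  reference set is an error, since there is nothing to align against.
* Degenerate single-base circles double to two bases with offset 1.
* Codon marks for the mapping plot are found by scanning the doubled
  string and keeping start positions below $L$, which captures codons that
  wrap across the BSJ in any frame.
* Renderers validate their input tables and draw only tested numbers; no
  statistic is computed inside a plotting function, and plot files are
  tested structurally (existence, non-emptiness), never pixel-wise.

## Limitations

Beyond the intron-retention point above: the classifier does not attempt
alternative-splicing-aware exon resolution (the most-exons tie-break is a
heuristic); the stem-loop scan reports a single best hit, not sub-optimal
pairings; BAM input is out of scope (SAM text is the tested surface); and
no P-site offsetting or reading-frame analysis is performed on the
ribosome-profiling reads — the junction-spanning count is deliberately the
whole criterion.
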