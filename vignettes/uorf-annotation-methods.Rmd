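---
title: "Models and methods behind uORFtools"
author: "uORFtools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uORFtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uORFtools)
```

# Scope and data model

`uORFtools` reasons about upstream open reading frames (uORFs) on *spliced*
transcripts. The central types are `TranscriptModel` (exon structure,
strand, and the genomic anchors of the main CDS *including* its stop
codon), `OrfRecord` (an ORF as genomic blocks plus transcript-space TIS and
stop anchors), `KozakPWM`, `SignalTrack`, and `MergedFeature` (the sequence
scanned when a variant may change a uORF's length).

One convention carries the whole package: internally every genomic
coordinate is 0-based half-open and every transcript position is a 0-based
offset along the spliced transcript read 5′→3′, regardless of strand.
BED stays 0-based half-open; GTF (1-based closed) and VCF (1-based,
anchor-base indel convention) are converted exactly once, at the I/O
boundary. Minus-strand transcripts keep their exons in ascending genomic
order — the BED12 block convention — and all 5′/3′ reasoning goes through
`genomicToTranscript()` / `transcriptToGenomic()`. This removes the
off-by-one and strand-flip bug classes by construction; the test suite
checks the round-trip identity for every exonic base of every fixture
transcript and a full strand-mirror invariance (reverse-complementing the
genome and flipping all annotations changes nothing).

GTF `CDS` features are taken at face value and must span the main ORF
*including* the stop codon; transcripts violating this (no CDS, CDS outside
the exon union, spliced CDS length not a positive multiple of 3) are
skipped with a warning, or rejected when `strict = TRUE`.

# ORF building and the four classes

`buildOrf()` walks codons 5′→3′ from a TIS to the first in-frame stop.
With `c` the transcript position of the main start and frame congruence
`(tis − c) mod 3`, `classifyOrf()` assigns:

* stop entirely before `c` → **non_overlapping_uORF**;
* crosses `c` out of frame → **overlapping_uORF**;
* upstream, in frame, no intervening stop → **cds_extension** (its stop is
  necessarily the main stop);
* downstream of `c`, in frame → **cds_truncation**.

Two retention choices matter. ORFs that meet no stop before the transcript
end are kept with `stopFound = FALSE` rather than dropped — they are
exactly the read-through geometries the variant annotator must reason
about. Downstream out-of-frame TISs do not fit any of the four classes; they
are labelled `internal_oof` and kept, so the four classes stay pure without
silently discarding input.

# Codon-independent Kozak scoring

The Kozak score of a candidate start codon deliberately ignores the codon
itself: offsets 0–2 are masked, and the score is the product over the
remaining window offsets (default −6…+5) of
`f(offset, base) / max_b f(offset, b)`. It is 1 exactly on the
per-position consensus, lies in (0, 1], and is invariant to swapping the
start codon — a property the tests quantify over every scanned candidate.
The multiplicative max-normalized form is chosen because it is monotone in
per-position consensus agreement and scale-free; the PWM file is a plain
TSV the user can replace (the shipped default is a vertebrate-consensus-
shaped placeholder, not an empirical matrix).

Candidate territory is the 5′UTR plus the first 100 nt of the CDS; context
windows may *extend* into any available transcript sequence but candidates
themselves are restricted to transcribed positions — sequence upstream of
the TSS cannot contain a TIS. Candidates whose window is truncated by a
transcript edge are scored over the available offsets and flagged
`partial_context` instead of being dropped, since first-exon starts are
biologically relevant. An `N` at a scored offset contributes that offset's
minimum frequency ratio (the conservative choice).

# The variant annotator

Variants are normalized before annotation: multiallelic records are split,
shared suffix/prefix bases trimmed, and indels left-aligned by allele
rotation (an anchored allele may shift one base left exactly when the
varying tail's last base equals the anchor). REF is verified against the
genome; mismatches become per-record error entries. Indels longer than
`maxIndelLen` (default 50 nt — a configurable guess, since "large" is not
otherwise defined) are dropped with a logged reason.

Only variants inside uORF boundaries are reported. Location uses a 2-nt
intronic splice window (the canonical donor/acceptor positions):
`exonic` when all affected bases are exonic, `splice_site` when any falls
in the window, `deep_intronic` otherwise — counted, but with no sequence
consequence computed. A splice-site location short-circuits the consequence
to `splice_site`; multi-base variants touching both exonic and intronic
bases additionally carry `junction_spanning = TRUE` (their sequence
consequence is not computed either, because the edited splice product is
not predictable from sequence arithmetic alone).

For exonic variants the uORF-level consequence comes from editing the
**merged feature** — the spliced substring from the uORF TIS through the
end of the main stop codon, which for a non-overlapping uORF is exactly
uORF + exonic gap + main CDS, with nothing counted twice for overlapping
ones. Length-preserving edits are classified codon-wise
(synonymous/missense/stop_gained/stop_lost), indels as frameshift or
inframe_indel unless they move the uORF's first stop, and any edit that
changes the start codon content is `start_lost` (reported with impact
`not_applicable`: the four impact categories cover length-affecting
variants only).

For `stop_gained`, `stop_lost` and `frameshift` the edited feature is
scanned from index 0 in the (possibly shifted) uORF frame for its first
stop, through the entire feature; finding none sets `read_through`. The
impact decision table is then:

| first new stop | frame vs main CDS | original uORF | impact |
|---|---|---|---|
| before main start | — | non-overlapping | main_CDS_unaffected |
| before main start | — | overlapping | overlap_removal |
| at/after main start or absent | unchanged congruence | overlapping | main_CDS_unaffected |
| none before main start | congruent | — | N-terminal_extension |
| at/after main start or absent | incongruent | — | out_of_frame_overlap |

The third row is a deliberate reading of "variants that do not change the
overlap": a stop-loss in an already-overlapping uORF extends an overlap
that already existed in the same frame, so it is not a new overlap event.
The effective edit used in these shift computations excludes the VCF
anchor base — which sits 5′ of the change on the plus strand but 3′ of it
on the minus strand — a detail that an exhaustive oracle comparison showed
to matter at exon and CDS boundaries.

Outputs: a TSV with fixed column order, the input VCF with a
`UORF=orf_id|start_codon|orf_class|consequence|impact` INFO tag
(comma-separated across annotations), and paired BED records per
length-affecting variant — the original uORF in black (0,0,0) and the
resulting ORF in red (255,0,0) — written separately for ATG- and
non-ATG-started uORFs for genome-browser inspection. All transcripts a
variant hits are reported; no canonical-transcript election is attempted.

# Catalog reconciliation

`compareCatalogs()` matches uORFs across catalogs by exact TIS genomic
coordinate (the default) or by exact stop-codon coordinate — the two
criteria a cross-study comparison could plausibly key on, provided because
published lists rarely state theirs. Within-catalog duplicates collapse;
an entry is high-confidence when seen in at least two catalogs; results are
split into ATG- and non-ATG-started subsets. The operation is symmetric
under catalog permutation and idempotent under self-union, and refuses
inputs whose declared assemblies differ.

`relativeTisSignal()` is the summed initiating-ribosome count over the uORF
start codon divided by the same sum at the main start; the default window
is the codon's 3 nt only (window = 0), configurable, with `NA` and a
warning when the main start has no signal — a ratio against zero has no
meaning.

# The TIS classifier pipeline

Windows of `2·flank + 1` nt (default 101) are centered on the **first base**
of the candidate codon — the phrasing "centered on the start codon" is
ambiguous between the first and middle base; the choice is recorded in the
encoding fingerprint and configurable. One-hot encoding maps A,C,G,T to
4-bit indicators and X/N to the zero block (`ACGTX` → four unit vectors
plus a zero vector), giving 404 features at the default; the per-position
signal block (raw counts capped at 5000 and scaled linearly to [0, 10])
adds 101, and z-scored per-gene expression features (8 in the synthetic
default — the real total of 581 implies a 76-column expression block whose
composition is configuration, not structure) complete the row.

Splits are gene-aware: genes are clustered by genomic overlap, clusters
shuffled with a fixed seed and cut at 0.8/0.1/0.1 of genes, so no gene (or
overlapping-gene cluster) leaks across splits; the deviation from the
fractions is at most one cluster. Training uses a binary logistic XGBoost
with early stopping after 10 non-improving trees. The positive-class
weight defaults to 1: with a fixed 0.5 threshold the calibrated
probabilities are the meaningful output, and an auto-balanced weight
(available via `scalePosWeight = NA`) recenters a no-signal model's
predictions at the threshold, which would turn the label-shuffle negative
control into coin-flip calls instead of the near-prevalence baseline it is
meant to expose. Predictions are averaged per genomic coordinate and called
at mean ≥ 0.5 (the boundary counts as positive, documented); evaluation
tallies confusion counts and F1/PRC/REC/BAC per start codon.

# The synthetic fixture generator

`makeFixture()` builds a ~50 kb two-contig genome carrying nine engineered
transcripts: plus and minus strand, single- and multi-exon (introns with
canonical GT…AG ends), planted uORFs of all four classes, a
multi-TIS/common-stop pair, uORFs spanning exon junctions, and a
non-overlapping ATG uORF whose stop-loss creates an out-of-frame CDS
overlap — the geometry of the clinically described 5′UTR stop-loss
variants. The planted variant suite covers every consequence and every
impact class on both strands, plus the operational edge cases:
multiallelic records, a non-left-aligned insertion, a junction-spanning
deletion, a deep-intronic and a splice-window SNV, an over-length
insertion, and a variant outside every uORF. Critical sequence regions are
engineered from stop-free codon alphabets (poly-GCA is stop-free in every
frame) with stops planted at chosen offsets in chosen frames; the
generator asserts these properties at build time.

All ground truth — ORF blocks and expected variant labels — is computed
inside the generator by per-base brute-force projection, independent of the
package's interval-arithmetic code paths, so manifest-versus-package tests
are non-circular. The only randomness is filler sequence, driven entirely
by the seed: the same seed yields byte-identical files.

`makeMlDataset()` plants a known decision rule — positive iff the scaled
signal at the codon's first base is ≥ 8 *and* the fixed context 6-mer
GCCACC immediately precedes the codon — over 20,000 candidates in 1,000
single-exon genes, with a rule-positive fraction of ~0.4 and 5% label
noise. These are the generator's study conditions, fixed once: the noise
rate puts the achievable held-out F1 ceiling near 0.94, so the recovery
check (F1 and balanced accuracy ≥ 0.9) passes exactly when the pipeline
learns the rule, and the label-shuffle control collapses to the
all-negative call.

What the fixtures do *not* emulate: realistic ribosome-profiling biases
(peak shapes, digestion artifacts, coverage heterogeneity), alternative
isoform ambiguity, CAGE-refined transcript starts, or human-genome scale.
Passing tests therefore demonstrate the correctness of the coordinate,
classification and scanning logic under controlled geometry — not
performance on real Ribo-seq data.

# Numerical and degenerate-input choices

* PWM rows are pseudocounted when any entry is 0 and renormalized, so
  scores stay in (0, 1] and log-free products cannot hit 0.
* A mean predicted probability exactly at the threshold is a positive call.
* `relativeTisSignal` with a silent main start returns `NA` with a warning
  rather than `Inf`.
* `metricsFromConfusion` defines each ratio as 0 when its denominator is 0
  (and balanced accuracy as the mean of the two defined rates).
* Problem sizes in the routine test run are deliberately modest — an
  exhaustive variant enumeration of roughly 2,400 SNVs and 1–2 nt indels
  across four uORFs, and the 20,000-candidate recovery experiment — chosen
  as the smallest sets that exercise every decision branch on both strands.

# Known limitations

* Splice-site variants receive a positional label only; no splicing-effect
  prediction is attempted, and junction-spanning edits are flagged rather
  than scored.
* The annotator evaluates existing uORFs; variants that *create* a new
  upstream AUG are out of scope.
* The default Kozak PWM is a placeholder shape, not a fitted matrix.
* The classifier depends on experimental signal features by design; it is
  not a pure-sequence model, and inference quality degrades where signal
  is sparse.
* Catalog matching by exact coordinate is strict; near-miss TISs (e.g.
  1–2 nt annotation jitter between assemblies) will not merge.
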