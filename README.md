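# uORFtools

Upstream open reading frames (uORFs) are short ORFs in the 5′ untranslated
regions of protein-coding genes. They modulate translation of the main
coding sequence (CDS), and variants that disrupt them — nonsense, stop-loss
and frameshift changes in particular — are an under-recognized class of
pathogenic variation in Mendelian disease genes. Interpreting such variants
requires reasoning jointly about spliced transcript structure, reading
frames, and where the first stop codon lands after an edit.

`uORFtools` is an R/Bioconductor-style toolkit for this problem, aimed at
people annotating 5′UTR variants or cataloguing translation initiation
sites (TISs):

* **ORF building and classification** — convert a TIS (ATG or one of the
  nine near-cognate codons TTG, GTG, CTG, AAG, AGG, ACG, ATA, ATT, ATC)
  into an ORF along the spliced transcript and classify it as a
  non-overlapping uORF, an overlapping uORF, a CDS extension or a CDS
  truncation, based on frame congruence with the main CDS and the position
  of the first in-frame stop.
* **Codon-independent Kozak scoring** — a position weight matrix score over
  the context window (default −6…+5) with the codon positions 0–2 masked,
  so the score reflects only the surrounding context:
  `score = ∏ f(offset, base) / max_b f(offset, b)` over scored offsets,
  equal to 1 exactly on the per-position consensus.
* **The uORF variant annotator** — for each variant × uORF × transcript
  triple, a uORF-level consequence (synonymous, missense, inframe_indel,
  stop_gained, stop_lost, frameshift, start_lost, splice_site) and, for
  length-affecting variants, a four-way main-CDS impact obtained by
  scanning the edited *merged feature* (uORF + exonic gap + main CDS) for
  its first stop codon: `main_CDS_unaffected`, `overlap_removal`,
  `N-terminal_extension`, or `out_of_frame_overlap`. Outputs are an
  annotated VCF, a TSV table, and paired black/red BED records (original
  and resulting ORF) for browser visualization, split by ATG/non-ATG start.
* **Catalog reconciliation** — a "high-confidence" uORF set defined as TISs
  predicted in at least two independent catalogs.
* **A gradient-boosted TIS classifier pipeline** — one-hot encoding of
  101-nt windows centered on the candidate codon (404-long vectors),
  initiating-ribosome signal capped at 5000 reads and scaled to [0, 10],
  per-gene expression features, gene-aware train/validation/test splitting
  that co-assigns overlapping genes, XGBoost training with early stopping,
  probability averaging per genomic coordinate at a 0.5 call threshold, and
  per-start-codon F1/precision/recall/balanced-accuracy evaluation.
* **A deterministic fixture generator** — synthetic genomes, multi-exon
  transcripts on both strands, planted uORFs of every class, signal tracks,
  and a variant suite with known expected annotations, used as ground truth
  throughout the test suite.

## Worked example

```r
library(uORFtools)

fx  <- makeFixture(seed = 1L, dir = tempfile())   # synthetic study set
res <- annotateUorfVariants(fx$paths$vcf, fx$paths$bed,
                            fx$paths$gtf, fx$paths$fasta,
                            outPrefix = file.path(tempdir(), "out"))

res$table[res$table$id %in% c("sg_p", "sl_p", "sle_p", "fse_p"),
          c("id", "orf_id", "orf_class", "consequence", "impact",
            "read_through")]
#>     id            orf_id            orf_class consequence               impact read_through
#>   sg_p  TX_NOV_P:421:ATG non_overlapping_uORF stop_gained  main_CDS_unaffected        FALSE
#>   sl_p  TX_NOV_P:421:ATG non_overlapping_uORF   stop_lost N-terminal_extension        FALSE
#>  fse_p TX_ETF_P:2738:ATG non_overlapping_uORF  frameshift out_of_frame_overlap         TRUE
#>  sle_p TX_ETF_P:2738:ATG non_overlapping_uORF   stop_lost out_of_frame_overlap        FALSE
```

Reading the rows: a stop-gained inside a non-overlapping uORF truncates the
uORF but leaves the main CDS untouched; a stop-loss in a uORF that is in
frame with the CDS reads through the gap and produces a chimeric
N-terminal extension; in an out-of-frame uORF the same stop-loss creates a
new overlap with the CDS translated in a different frame — the geometry of
the well-known pathogenic 5′UTR stop-loss variants.

The probable loss-of-function (pLoF) breakdown of the planted suite:

```r
res$summary$pLoF
#>                impact start_type n proportion
#>   main_CDS_unaffected        ATG 7  0.4666667
#>  N-terminal_extension        ATG 2  0.1333333
#>  out_of_frame_overlap        ATG 4  0.2666667
#>       overlap_removal        ATG 2  0.1333333
```

ORF records and initiation signal:

```r
orf <- fx$orfs[["TX_NOV_P:421:ATG"]]
orf
#> OrfRecord TX_NOV_P:421:ATG [non_overlapping_uORF] c1:+ ATG blocks=2 len=27nt stop=found
relativeTisSignal(orf, fx$transcripts[["TX_NOV_P"]], fx$track)
#> [1] 2
```

Command-line wrappers over the same functions live in `inst/scripts/`
(`uorf_annotator.R`, `kozak_scan.R`, `make_fixtures.R`).

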