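# Shared fixture objects, built once per test run.

fixtureDir <- file.path(tempdir(), "uorf_fixture_seed1")
FX <- makeFixture(seed = 1L, dir = fixtureDir)

# a mirrored fixture: reverse-complemented genome with flipped annotations,
# for strand-invariance checks
mirrorFixture <- function(fx) {
  widths <- vapply(names(fx$genome), function(nm) length(fx$genome[[nm]]),
                   integer(1))
  genome <- Biostrings::reverseComplement(fx$genome)
  flipPos <- function(chrom, pos) widths[[chrom]] - 1L - pos
  flipIval <- function(chrom, s, e) {
    ns <- widths[[chrom]] - e
    list(start = ns, end = widths[[chrom]] - s)
  }
  transcripts <- lapply(fx$transcripts, function(t) {
    w <- widths[[t@chrom]]
    ns <- rev(w - t@exonEnds)
    ne <- rev(w - t@exonStarts)
    TranscriptModel(t@transcriptId, t@geneId, t@chrom,
                    if (t@strand == "+") "-" else "+",
                    ns, ne, w - t@cdsEndG, w - t@cdsStartG + 0L)
  })
  orfTis <- lapply(fx$orfs, function(o) {
    list(transcriptId = o@transcriptId,
         gpos = flipPos(o@chrom, o@tisGpos),
         codon = o@startCodon, class = o@orfClass)
  })
  list(genome = genome, transcripts = transcripts, orfTis = orfTis)
}

# toy single-exon transcript on a tiny genome, for hand-checkable cases
toyGenome <- function(seq, name = "t1") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- name
  g
}
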