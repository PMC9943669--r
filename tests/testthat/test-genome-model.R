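test_that("FASTA loading normalizes case, keeps N, rejects duplicates", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1 description text", "acgtn"), fa)
  g <- loadGenome(fa)
  expect_identical(names(g), "c1")
  expect_identical(as.character(g[[1]]), "ACGTN")

  writeLines(c(">c1", "ACGT", ">c1", "GGCC"), fa)
  expect_error(loadGenome(fa), "duplicate contig")

  # fixture FASTA round-trips through the reader
  g2 <- loadGenome(FX$paths$fasta)
  expect_identical(as.character(g2), as.character(FX$genome))
})

test_that("contig lookups outside bounds are errors", {
  g <- toyGenome("ATGCCC")
  expect_identical(contigSequence(g, "t1", 0L, 3L), "ATG")
  expect_error(contigSequence(g, "t1", 4L, 10L), "outside contig")
  expect_error(contigSequence(g, "nope", 0L, 3L), "not in genome")
})

test_that("coordinate mapping follows the 5'-to-3' convention on both strands", {
  # plus strand, exon at [100, 110): genomic 100 is transcript position 0
  tp <- TranscriptModel("t", "g", "c", "+", c(100L), c(110L), 101L, 107L)
  expect_identical(genomicToTranscript(tp, 100L), 0L)
  # minus strand, single exon [100, 110): highest coordinate maps to 0
  tm <- TranscriptModel("t", "g", "c", "-", c(100L), c(110L), 101L, 107L)
  expect_identical(genomicToTranscript(tm, 109L), 0L)
  expect_true(is.na(genomicToTranscript(tp, 99L)))
  expect_error(transcriptToGenomic(tp, 10L), "out of range")
})

test_that("round-trip identity holds for every exonic base of every fixture transcript", {
  for (t in FX$transcripts) {
    g <- unlist(mapply(function(s, e) s:(e - 1L), t@exonStarts, t@exonEnds,
                       SIMPLIFY = FALSE))
    tp <- genomicToTranscript(t, g)
    expect_false(anyNA(tp))
    expect_identical(transcriptToGenomic(t, tp), g)
    # intronic positions map to NA
    if (length(t@exonStarts) > 1L)
      expect_true(is.na(genomicToTranscript(t, t@exonEnds[1L] + 1L)))
  }
})

test_that("spliced sequences concatenate exons and honour strand", {
  g <- toyGenome("ATGCCCTAA")
  tp <- TranscriptModel("t", "g", "t1", "+", c(0L, 6L), c(3L, 9L), 0L, 9L)
  expect_identical(splicedSequence(tp, g), "ATGTAA")
  g2 <- toyGenome("ATGTAA")
  tm <- TranscriptModel("t", "g", "t1", "-", 0L, 6L, 0L, 6L)
  expect_identical(splicedSequence(tm, g2), "TTACAT")
  # every fixture main CDS begins with its start codon and ends with a stop
  for (t in FX$transcripts) {
    S <- splicedSequence(t, FX$genome)
    a <- cdsTranscriptAnchors(t)
    cds <- substr(S, a[1] + 1L, a[2])
    expect_identical(substr(cds, 1L, 3L), "ATG")
    expect_true(substr(cds, nchar(cds) - 2L, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
    expect_identical(nchar(cds) %% 3L, 0L)
  }
})

test_that("strand mirror: reverse-complemented genome reproduces spliced sequences", {
  mir <- mirrorFixture(FX)
  for (tid in names(FX$transcripts)) {
    expect_identical(splicedSequence(mir$transcripts[[tid]], mir$genome),
                     splicedSequence(FX$transcripts[[tid]], FX$genome),
                     info = tid)
  }
})

test_that("translation reads frame 0, marks stops, and agrees with an independent oracle", {
  expect_identical(translateDna("ATGTAA"), "M*")
  expect_identical(translateDna("ATGGCC"), "MA")
  expect_identical(translateDna("ATGNNGTAA"), "MX*")  # N codons become X
  expect_identical(translateDna("ATGGC"), "M")        # trailing bases dropped
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             collapse = "")
  oracle <- as.character(Biostrings::translate(
    Biostrings::DNAString(s), no.init.codon = TRUE))
  expect_identical(translateDna(s), oracle)
})

test_that("GTF loading recovers fixture transcripts and skips malformed entries", {
  txs <- NULL
  w <- capture_warnings(txs <- loadTranscripts(FX$paths$gtf))
  expect_true(any(grepl("TX_NOCDS", w)))
  expect_true(any(grepl("TX_BADCDS", w)))
  expect_false("TX_NOCDS" %in% names(txs))
  expect_false("TX_BADCDS" %in% names(txs))
  expect_setequal(names(txs), names(FX$transcripts))
  for (tid in names(txs)) {
    expect_identical(txs[[tid]]@exonStarts, FX$transcripts[[tid]]@exonStarts,
                     info = tid)
    expect_identical(txs[[tid]]@exonEnds, FX$transcripts[[tid]]@exonEnds)
    expect_identical(txs[[tid]]@cdsStartG, FX$transcripts[[tid]]@cdsStartG)
    expect_identical(txs[[tid]]@cdsEndG, FX$transcripts[[tid]]@cdsEndG)
    expect_identical(txs[[tid]]@strand, FX$transcripts[[tid]]@strand)
  }
  expect_error(suppressWarnings(loadTranscripts(FX$paths$gtf, strict = TRUE)))
})

test_that("transcript model validity catches malformed inputs", {
  expect_error(TranscriptModel("t", "g", "c", "+", c(10L, 5L), c(20L, 8L),
                               10L, 16L))
  expect_error(TranscriptModel("t", "g", "c", "+", 0L, 10L, 0L, 7L),
               "multiple of 3")
  expect_error(TranscriptModel("t", "g", "c", "*", 0L, 9L, 0L, 9L), "strand")
})
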