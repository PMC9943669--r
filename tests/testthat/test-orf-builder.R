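test_that("built ORFs reproduce the fixture truth on both strands", {
  for (oid in names(FX$orfs)) {
    tru <- FX$orfs[[oid]]
    t <- FX$transcripts[[tru@transcriptId]]
    got <- buildOrf(list(gpos = tru@tisGpos, codon = tru@startCodon), t,
                    FX$genome)
    expect_identical(got@orfClass, tru@orfClass, info = oid)
    expect_identical(got@stopTpos, tru@stopTpos, info = oid)
    expect_identical(got@blockStarts, tru@blockStarts, info = oid)
    expect_identical(got@blockEnds, tru@blockEnds, info = oid)
    expect_true(got@stopFound)
    expect_identical(orfLength(got) %% 3L, 0L)
  }
})

test_that("TIS errors are caught: intronic position, codon mismatch", {
  t <- FX$transcripts[["TX_NOV_P"]]
  intronic <- t@exonEnds[1L] + 5L
  expect_error(buildOrf(list(gpos = intronic, codon = "ATG"), t, FX$genome),
               "intronic")
  orf <- FX$orfs[["TX_NOV_P:421:ATG"]]
  expect_error(buildOrf(list(gpos = orf@tisGpos, codon = "CTG"), t,
                        FX$genome), "mismatch")
})

test_that("ORFs without a downstream in-frame stop run to the transcript end", {
  # CTG at position 0 in a frame that meets no stop before the transcript
  # end; it crosses the main start out of frame
  g <- toyGenome(paste0("CTG", strrep("GCA", 6), "C", "ATG",
                        strrep("GCA", 3), "TAA"))
  L <- length(g[[1]])
  t <- TranscriptModel("t", "g", "t1", "+", 0L, L, 22L, L)
  orf <- buildOrf(list(gpos = 0L, codon = "CTG"), t, g)
  expect_false(orf@stopFound)
  expect_true(is.na(orf@stopTpos))
  expect_identical(orfLength(orf), L)
  expect_identical(orf@orfClass, "overlapping_uORF")
})

test_that("a junction-spanning ORF re-translates like its single-exon control", {
  orf <- FX$orfs[["TX_NOV_P:421:ATG"]]
  t <- FX$transcripts[["TX_NOV_P"]]
  expect_identical(length(orf@blockStarts), 2L)
  pieces <- mapply(function(s, e) contigSequence(FX$genome, orf@chrom, s, e),
                   orf@blockStarts, orf@blockEnds)
  spliced <- paste0(pieces, collapse = "")
  # single-exon control: same spliced ORF sequence, fresh toy transcript
  ctl <- toyGenome(paste0(strrep("C", 12), spliced, "ATG", strrep("GCA", 4),
                          "TAA"))
  tc <- TranscriptModel("ctl", "g", "t1", "+", 0L, length(ctl[[1]]),
                        12L + nchar(spliced), length(ctl[[1]]))
  octl <- buildOrf(list(gpos = 12L, codon = "ATG"), tc, ctl)
  expect_identical(translateDna(splicedSequence(t, FX$genome) |>
                                  substr(orf@tisTpos + 1L, orf@stopTpos + 3L)),
                   translateDna(spliced))
  expect_identical(translateDna(spliced),
                   translateDna(splicedSequence(tc, ctl) |>
                                  substr(13L, 12L + nchar(spliced))))
  expect_identical(octl@orfClass, "non_overlapping_uORF")
})

test_that("multiple TISs in one frame share a common stop codon", {
  o1 <- FX$orfs[["TX_MTIS_P:3347:ATG"]]
  o2 <- FX$orfs[["TX_MTIS_P:3353:CTG"]]
  t <- FX$transcripts[["TX_MTIS_P"]]
  b1 <- buildOrf(list(gpos = o1@tisGpos, codon = "ATG"), t, FX$genome)
  b2 <- buildOrf(list(gpos = o2@tisGpos, codon = "CTG"), t, FX$genome)
  expect_identical(b1@stopTpos, b2@stopTpos)
  expect_identical((b2@tisTpos - b1@tisTpos) %% 3L, 0L)
})

test_that("classification is invariant under genome mirroring", {
  mir <- mirrorFixture(FX)
  for (oid in names(mir$orfTis)) {
    m <- mir$orfTis[[oid]]
    t <- mir$transcripts[[m$transcriptId]]
    got <- buildOrf(list(gpos = m$gpos, codon = m$codon), t, mir$genome)
    expect_identical(got@orfClass, m$class, info = oid)
  }
})

test_that("internal out-of-frame TISs are flagged, not forced into the four classes", {
  # ATG inside the CDS at offset 4 (frame +1)
  g <- toyGenome(paste0(strrep("C", 30), "ATGGATGGCAGCTAA"))
  t <- TranscriptModel("t", "g", "t1", "+", 0L, length(g[[1]]), 30L, 45L)
  orf <- buildOrf(list(gpos = 34L, codon = "ATG"), t, g)
  expect_identical(orf@orfClass, "internal_oof")
  expect_false(orf@stopFound)
})

test_that("catalog reconciliation applies the two-study rule with set semantics", {
  cc <- compareCatalogs(FX$catalogs)
  tru <- FX$manifest$catalogs
  expect_identical(nrow(cc$highConfidence), sum(tru$high_confidence))
  # membership matrix equals the planted structure
  key <- paste(tru$chrom, "+", tru$gpos, sep = "|")
  key[tru$chrom == "c2"] <- paste(tru$chrom[tru$chrom == "c2"], "-",
                                  tru$gpos[tru$chrom == "c2"], sep = "|")
  expect_setequal(rownames(cc$membership), key)
  counts <- rowSums(cc$membership)[key]
  expect_identical(unname(counts), tru$n_catalogs)
  # within-catalog duplicates count once: catalog A carries a duplicate row,
  # yet entries seen only in A stay excluded
  onlyA <- tru$n_catalogs == 1L
  expect_false(any(key[onlyA] %in% cc$highConfidence$key))
  # ATG / non-ATG partition
  expect_identical(nrow(cc$atg) + nrow(cc$nonAtg), nrow(cc$highConfidence))
  # permutation symmetry and idempotence under self-union
  cc2 <- compareCatalogs(rev(FX$catalogs))
  expect_identical(sort(cc2$highConfidence$key), sort(cc$highConfidence$key))
  dup <- FX$catalogs
  dup$A <- rbind(dup$A, dup$A)
  attr(dup$A, "assembly") <- "fixture1"
  cc3 <- compareCatalogs(dup)
  expect_identical(sort(cc3$highConfidence$key), sort(cc$highConfidence$key))
  # stop-coordinate matching mode runs on the same inputs
  cc4 <- compareCatalogs(FX$catalogs, mode = "stop")
  expect_identical(nrow(cc4$highConfidence), nrow(cc$highConfidence))
  # mixed assemblies are rejected
  bad <- FX$catalogs
  attr(bad$B, "assembly") <- "other"
  expect_error(compareCatalogs(bad), "mixed-assembly")
})

test_that("relative TIS signal is the planted peak ratio, NA on silent CDS starts", {
  t <- FX$transcripts[["TX_NOV_P"]]
  orf <- FX$orfs[["TX_NOV_P:421:ATG"]]
  expect_equal(relativeTisSignal(orf, t, FX$track), 2.0)
  # the second TIS of the multi-TIS pair has an equal-height peak
  t6 <- FX$transcripts[["TX_MTIS_P"]]
  expect_equal(relativeTisSignal(FX$orfs[["TX_MTIS_P:3353:CTG"]], t6,
                                 FX$track), 1.0)
  empty <- SignalTrack(data.frame(chrom = "c1", pos = 1L, count = 5))
  expect_warning(r <- relativeTisSignal(orf, t, empty), "no initiation")
  expect_true(is.na(r))
  # window widening keeps the planted ratio (peaks are single-base)
  expect_equal(relativeTisSignal(orf, t, FX$track, window = 3L), 2.0)
})

test_that("BED12 writing and reading compose to identity on fixture ORFs", {
  f <- tempfile(fileext = ".bed")
  writeOrfBed(FX$orfs, f)
  back <- readOrfBed(f, FX$transcripts, FX$genome)
  expect_identical(length(back), length(FX$orfs))
  for (i in seq_along(back)) {
    tru <- FX$orfs[[orfId(back[[i]])]]
    expect_identical(back[[i]]@blockStarts, tru@blockStarts)
    expect_identical(back[[i]]@blockEnds, tru@blockEnds)
    expect_identical(back[[i]]@orfClass, tru@orfClass)
    expect_identical(back[[i]]@startCodon, tru@startCodon)
  }
})
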