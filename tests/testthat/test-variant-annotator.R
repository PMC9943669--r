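annotateAll <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- FX$paths
      cache <<- suppressWarnings(annotateUorfVariants(
        p$vcf, p$bed, p$gtf, p$fasta,
        outPrefix = file.path(fixtureDir, "annot")))
    }
    cache
  }
})

test_that("VCF reading splits multiallelic records", {
  raw <- readVariants(FX$paths$vcf)
  multi <- raw$variants[raw$variants$id == "multi_p", ]
  expect_identical(nrow(multi), 2L)
  expect_setequal(multi$alt, c("A", "T"))
  expect_identical(unique(multi$pos), multi$pos[1])
})

test_that("normalization trims, left-aligns and verifies against the genome", {
  g <- toyGenome("CCGAAAATGCC")
  # right-shifted representation of a 1-nt deletion in the A-homopolymer
  v1 <- data.frame(chrom = "t1", pos = 6L, id = "a", ref = "AA", alt = "A",
                   orig_index = 1L)
  # same deletion written with a redundant shared suffix
  v2 <- data.frame(chrom = "t1", pos = 5L, id = "b", ref = "AAA", alt = "AA",
                   orig_index = 2L)
  n1 <- normalizeVariants(v1, g)$variants
  n2 <- normalizeVariants(v2, g)$variants
  expect_identical(n1$pos, 3L)           # leftmost: anchor at the G
  expect_identical(n1$ref, "GA")
  expect_identical(n1$alt, "G")
  expect_identical(n2[, c("pos", "ref", "alt")], n1[, c("pos", "ref", "alt")])
  # REF mismatch becomes a per-record error entry
  bad <- data.frame(chrom = "t1", pos = 1L, id = "c", ref = "T", alt = "A",
                    orig_index = 1L)
  nb <- normalizeVariants(bad, g)
  expect_identical(nrow(nb$variants), 0L)
  expect_identical(nb$errors$reason, "ref_mismatch")
  # indels beyond the length cutoff are dropped with a reason
  big <- data.frame(chrom = "t1", pos = 3L, id = "d", ref = "G",
                    alt = paste0("G", strrep("A", 60)), orig_index = 1L)
  expect_identical(normalizeVariants(big, g)$errors$reason, "large_indel")
  expect_identical(nrow(normalizeVariants(big, g, maxIndelLen = 100L)$variants),
                   1L)
})

test_that("variant location separates exonic, splice-site and deep-intronic", {
  t <- FX$transcripts[["TX_NOV_P"]]
  tab <- annotateAll()$table
  expect_identical(tab$location[tab$id == "mis_p"], "exonic")
  expect_identical(tab$location[tab$id == "spl_p"], "splice_site")
  expect_identical(tab$location[tab$id == "spl_m"], "splice_site")
  expect_identical(tab$location[tab$id == "deep_p"], "deep_intronic")
  # deep intronic rows carry no consequence
  expect_true(is.na(tab$consequence[tab$id == "deep_p"]))
})

test_that("the merged feature is the TIS-to-main-stop spliced substring", {
  for (oid in c("TX_NOV_P:421:ATG", "TX_OVL_P:1111:ATG", "TX_NOV_M:639:ATG")) {
    orf <- FX$orfs[[oid]]
    t <- FX$transcripts[[orf@transcriptId]]
    mf <- buildMergedFeature(orf, t, FX$genome)
    S <- splicedSequence(t, FX$genome)
    a <- cdsTranscriptAnchors(t)
    expect_identical(mf@sequence, substr(S, orf@tisTpos + 1L, a[2L]))
    expect_identical(nchar(mf@sequence), a[2L] - orf@tisTpos)
    expect_identical(substr(mf@sequence, mf@cdsStartIdx + 1L,
                            mf@cdsStartIdx + 3L), "ATG")
    # coordinate map round-trips through the transcript mapping, every base
    idx <- orf@tisTpos:(a[2L] - 1L)
    expect_identical(mf@gcoords, transcriptToGenomic(t, idx))
    if (orf@orfClass == "non_overlapping_uORF") {
      # uORF + gap + CDS lengths tile the feature exactly
      uorfLen <- orf@stopTpos + 3L - orf@tisTpos
      gapLen <- a[1L] - (orf@stopTpos + 3L)
      cdsLen <- a[2L] - a[1L]
      expect_identical(uorfLen + gapLen + cdsLen, nchar(mf@sequence))
    }
  }
})

test_that("the planted variant suite is annotated exactly as designed", {
  res <- annotateAll()
  tab <- res$table
  exp <- FX$variants
  for (i in seq_len(nrow(exp))) {
    e <- exp[i, ]
    got <- tab[tab$id == e$id, ]
    if (e$location %in% c("outside", "dropped")) {
      expect_identical(nrow(got), 0L, info = e$id)
      next
    }
    expect_gt(nrow(got), 0)
    g <- got[1L, ]
    expect_identical(g$location, e$location, info = e$id)
    if (!is.na(e$consequence))
      expect_identical(g$consequence, e$consequence, info = e$id)
    if (!is.na(e$impact))
      expect_identical(g$impact, e$impact, info = e$id)
    expect_identical(g$read_through, e$read_through, info = e$id)
  }
  expect_identical(res$errors$reason, "large_indel")
  # junction-spanning deletion is flagged
  expect_true(tab$junction_spanning[tab$id == "junc_p"])
  # impact is not_applicable exactly for non-length-affecting consequences
  la <- tab$consequence %in% c("stop_gained", "stop_lost", "frameshift")
  expect_identical(tab$impact != "not_applicable", la)
  # plus- and minus-strand plantings of the same design agree
  for (base in c("syn", "mis", "sg", "sl", "fs", "if", "stl", "sgo", "slo",
                 "sle", "fse")) {
    rp <- tab[tab$id == paste0(base, "_p"), ]
    rm <- tab[tab$id == paste0(base, "_m"), ]
    expect_identical(rp$consequence, rm$consequence, info = base)
    expect_identical(rp$impact, rm$impact, info = base)
  }
})

test_that("main-CDS exclusion drops exactly the CDS-overlapping variants", {
  p <- FX$paths
  res <- suppressWarnings(annotateUorfVariants(p$vcf, p$bed, p$gtf, p$fasta,
                                               excludeMainCds = TRUE))
  full <- annotateAll()$table
  dropped <- setdiff(full$id, res$table$id)
  # cds_p plus the overlapping-uORF variants located inside the CDS
  expect_true("cds_p" %in% dropped)
  for (id in dropped) {
    row <- full[full$id == id, ][1L, ]
    t <- FX$transcripts[[row$transcript_id]]
    expect_true(row$pos - 1L >= t@cdsStartG && row$pos - 1L < t@cdsEndG,
                info = id)
  }
})

test_that("two frameshifts restoring the frame leave the main CDS unaffected", {
  # apply the first frameshift (1-nt deletion) to the genome, then annotate
  # its 1-nt insertion partner on the edited genome
  vr <- FX$vcfRecords
  del <- vr[vr$id == "fs_p", ]
  ins <- vr[vr$id == "fr_ins_p", ]
  chr <- as.character(FX$genome[["c1"]])
  edited <- paste0(substr(chr, 1L, del$pos), substr(chr, del$pos + 2L,
                                                    nchar(chr)))
  genome2 <- Biostrings::DNAStringSet(c(c1 = edited,
                                        c2 = as.character(FX$genome[["c2"]])))
  t <- FX$transcripts[["TX_NOV_P"]]
  d0 <- del$pos                # 0-based position of the deleted base
  shift <- function(x) ifelse(x > d0, x - 1L, x)
  t2 <- TranscriptModel(t@transcriptId, t@geneId, t@chrom, t@strand,
                        shift(t@exonStarts), shift(t@exonEnds),
                        shift(t@cdsStartG), shift(t@cdsEndG))
  orf2 <- buildOrf(list(gpos = FX$orfs[["TX_NOV_P:421:ATG"]]@tisGpos,
                        codon = "ATG"), t2, genome2)
  # the lone frameshift ends at the stop planted in the shifted-frame gap
  expect_identical(orf2@orfClass, "non_overlapping_uORF")
  mf2 <- buildMergedFeature(orf2, t2, genome2)
  v2 <- data.frame(chrom = "c1", pos = ins$pos - 1L, ref = ins$ref,
                   alt = ins$alt)
  v2$ref <- substr(edited, v2$pos, v2$pos)
  v2$alt <- paste0(v2$ref, "G")
  cons <- uorfConsequence(mf2, v2)
  expect_identical(cons, "frameshift")
  scan <- scanNewStop(mf2, v2)
  expect_identical(classifyImpact(orf2, mf2, scan), "main_CDS_unaffected")
  # the combined edit restores the original stop position (deletion and
  # insertion cancel)
  origStop <- FX$orfs[["TX_NOV_P:421:ATG"]]@stopTpos -
    FX$orfs[["TX_NOV_P:421:ATG"]]@tisTpos
  expect_identical(scan$newStopIdx, origStop)
})

test_that("annotation outputs are written, gated and idempotent", {
  res <- annotateAll()
  paths <- res$paths
  expect_true(all(file.exists(unlist(paths))))
  tsv <- utils::read.delim(paths$tsv)
  expect_identical(nrow(tsv), nrow(res$table))
  # BED pairs exist only for length-affecting variants, as black/red pairs
  atg <- utils::read.delim(paths$atgBed, header = FALSE)
  expect_identical(nrow(atg) %% 2L, 0L)
  expect_setequal(unique(atg$V9), c("0,0,0", "255,0,0"))
  nLa <- sum(res$table$consequence %in% c("stop_gained", "stop_lost",
                                          "frameshift"), na.rm = TRUE)
  nonAtg <- tryCatch(utils::read.delim(paths$nonAtgBed, header = FALSE),
                     error = function(e) NULL)
  expect_identical(nrow(atg) / 2L + (if (is.null(nonAtg)) 0L else
    nrow(nonAtg) / 2L), as.numeric(nLa))
  # VCF carries the UORF INFO tag for annotated records only
  vcfLines <- readLines(paths$vcf)
  expect_true(any(grepl("##INFO=<ID=UORF", vcfLines)))
  body <- vcfLines[!startsWith(vcfLines, "#")]
  tagged <- grepl("UORF=", body)
  expect_identical(sum(tagged), length(unique(res$table$orig_index)))
  # re-annotating the annotated VCF reproduces identical tags
  res2 <- suppressWarnings(annotateUorfVariants(
    paths$vcf, FX$paths$bed, FX$paths$gtf, FX$paths$fasta,
    outPrefix = file.path(fixtureDir, "annot2")))
  v1 <- grep("UORF=", readLines(paths$vcf), value = TRUE)
  v2 <- grep("UORF=", readLines(res2$paths$vcf), value = TRUE)
  getTag <- function(x) sub(".*UORF=([^;\t]*).*", "\\1", x)
  expect_identical(getTag(v2), getTag(v1))
})

test_that("class summaries count consequence x impact x start type", {
  res <- annotateAll()
  s <- res$summary
  tab <- res$table
  expect_identical(sum(s$byClass$n), sum(!is.na(tab$consequence)))
  expect_equal(sum(s$byClass$proportion), 1)
  expect_identical(sum(s$pLoF$n),
                   sum(tab$consequence %in% c("stop_gained", "stop_lost",
                                              "frameshift")))
  # empty input gives an all-zero table
  s0 <- summarizeClasses(tab[0, ])
  expect_identical(nrow(s0$byClass), 0L)
  # contingency comparison returns a probability
  p <- compareSummaries(s$byClass, s$byClass)
  expect_true(p >= 0 && p <= 1)
})
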