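test_that("one-hot encoding matches the worked example and pads with zeros", {
  v <- oneHotWindow("ACGTX", windowLen = 5L)
  expect_identical(as.numeric(v),
                   c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1,
                     0, 0, 0, 0))
  expect_identical(sum(oneHotWindow(strrep("X", 7), 7L)), 0)
  expect_identical(oneHotWindow("NNN", 3L), oneHotWindow("XXX", 3L))
  expect_identical(ncol(oneHotWindow(strrep("A", 101), 101L)), 404L)
  expect_error(oneHotWindow("ACGT", 5L), "length")
  expect_error(oneHotWindow("ACGTZ", 5L), "characters")
})

test_that("signal scaling caps at 5000 reads onto [0, 10]", {
  expect_identical(scaleSignal(5000), 10)
  expect_identical(scaleSignal(0), 0)
  expect_identical(scaleSignal(2500), 5)
  expect_identical(scaleSignal(99999), 10)
  x <- sort(stats::runif(100, 0, 10000))
  y <- scaleSignal(x)
  expect_true(all(diff(y) >= 0))          # monotone
  expect_true(all(y >= 0 & y <= 10))      # bounded
  expect_error(scaleSignal(-1), "negative")
})

test_that("window extraction pads, samples planted signal and filters by UTR length", {
  ml <- makeMlDataset(nGenes = 6L, perGene = 4L, seed = 3L)
  spec <- encodingSpec(nExpression = 8L)
  ew <- extractWindows(ml$candidates, ml$transcripts, ml$genome, ml$track,
                       expression = standardizeExpression(ml$expression),
                       spec = spec)
  expect_identical(ncol(ew$features), spec$totalLen)
  expect_identical(nrow(ew$features), nrow(ml$candidates))
  # the planted rule is readable off the features: center signal >= 8 AND
  # the GCCACC context immediately 5' of the codon
  sig <- ew$features[, spec$oneHotLen + seq_len(spec$windowLen)]
  center <- spec$flank + 1L
  decode <- function(row, p) {   # window position p (1-based) -> base
    blk <- row[(p - 1L) * 4L + 1:4]
    if (sum(blk) == 0) "X" else c("A", "C", "G", "T")[which(blk == 1)]
  }
  motifHit <- vapply(seq_len(nrow(ew$features)), function(i) {
    paste0(vapply((center - 6L):(center - 1L),
                  function(p) decode(ew$features[i, seq_len(spec$oneHotLen)],
                                     p), character(1)),
           collapse = "") == "GCCACC"
  }, logical(1))
  expect_identical(ew$meta$rule, sig[, center] >= 8 & motifHit)
  # a candidate near the transcript 5' end gets X padding
  t1 <- ml$transcripts[[1L]]
  nearEnd <- data.frame(gene_id = geneId(t1), transcript_id = transcriptId(t1),
                        chrom = txChrom(t1),
                        gpos = transcriptToGenomic(t1, 10L),
                        strand = txStrand(t1), codon = "ATG", label = 0L)
  ew2 <- extractWindows(nearEnd, ml$transcripts, ml$genome, ml$track,
                        expression = standardizeExpression(ml$expression),
                        spec = spec)
  oh <- ew2$features[1L, seq_len(spec$oneHotLen)]
  expect_identical(sum(oh[seq_len(4L * 40L)]), 0)   # 40 leading X positions
  expect_gt(sum(oh), 0)
  # transcripts with short 5'UTRs are excluded
  gShort <- toyGenome(paste0(strrep("C", 20), "ATG", strrep("GCA", 4), "TAA"))
  tShort <- TranscriptModel("short", "gS", "t1", "+", 0L,
                            length(gShort[[1]]), 20L, 38L)
  candS <- data.frame(gene_id = "gS", transcript_id = "short", chrom = "t1",
                      gpos = 5L, strand = "+", codon = "ATG", label = 0L)
  ewS <- extractWindows(candS, list(short = tShort), gShort,
                        SignalTrack(data.frame(chrom = "t1", pos = 0L,
                                               count = 0)),
                        spec = encodingSpec())
  expect_identical(nrow(ewS$features), 0L)
  expect_identical(ewS$excluded, 1L)
})

test_that("gene-aware splits partition genes and co-assign overlapping genes", {
  meta <- data.frame(gene_id = rep(sprintf("g%02d", 1:10), each = 3),
                     chrom = "c", gpos = rep(seq(0, 9000, by = 1000), each = 3) +
                       c(0L, 10L, 20L))
  sp <- splitByGene(meta, seed = 5L)
  expect_identical(unname(sort(c(sp$train, sp$val, sp$test))),
                   seq_len(nrow(meta)))
  byGene <- function(ix) unique(meta$gene_id[ix])
  expect_identical(length(byGene(sp$train)), 8L)
  expect_identical(length(byGene(sp$val)), 1L)
  expect_identical(length(byGene(sp$test)), 1L)
  # overlapping genes always travel together
  meta2 <- meta
  meta2$gpos[meta2$gene_id == "g02"] <- meta2$gpos[meta2$gene_id == "g01"]
  sp2 <- splitByGene(meta2, seed = 5L)
  for (part in sp2) {
    g <- unique(meta2$gene_id[part])
    expect_identical("g01" %in% g, "g02" %in% g)
  }
  # determinism in the seed
  expect_identical(splitByGene(meta, seed = 5L), sp)
  expect_false(identical(splitByGene(meta, seed = 6L)$train, sp$train))
  expect_error(splitByGene(meta, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("confusion metrics reproduce published worked examples", {
  m <- metricsFromConfusion(tn = 5600, fn = 40, fp = 75, tp = 154)
  expect_equal(round(unlist(m), 2),
               c(f1 = 0.73, prc = 0.67, rec = 0.79, bac = 0.89))
  m2 <- metricsFromConfusion(tn = 3762, fn = 2, fp = 1, tp = 0)
  expect_equal(round(m2$f1, 2), 0)
  expect_equal(round(m2$bac, 2), 0.5)
  expect_equal(metricsFromConfusion(0, 0, 0, 7)$f1, 1)
  expect_error(metricsFromConfusion(-1, 0, 0, 0), "negative")
})

test_that("probability aggregation averages by coordinate and calls at 0.5", {
  meta <- data.frame(chrom = "c", gpos = c(1L, 1L, 2L, 3L, 3L, 4L),
                     strand = "+", codon = "ATG",
                     label = c(1L, 1L, 1L, 0L, 0L, 0L))
  out <- aggregateCalls(c(0.4, 0.8, 0.5, 0.2, 0.2, 0.9), meta, 0.5)
  expect_identical(nrow(out), 4L)
  expect_equal(out$prob[out$gpos == 1L], 0.6)
  expect_identical(out$call[out$gpos == 1L], 1L)
  expect_identical(out$call[out$gpos == 2L], 1L)   # exactly 0.5 is positive
  expect_identical(out$call[out$gpos == 3L], 0L)
})

test_that("per-codon evaluation tallies hand-checkable confusion counts", {
  calls <- data.frame(codon = c("ATG", "ATG", "CTG", "CTG", "GTG"),
                      call = c(1L, 0L, 1L, 0L, 0L),
                      label = c(1L, 1L, 0L, 0L, 0L))
  tab <- evaluatePerCodon(calls)
  atg <- tab[tab$codon == "ATG", ]
  expect_identical(c(atg$tn, atg$fn, atg$fp, atg$tp), c(0L, 1L, 0L, 1L))
  gtg <- tab[tab$codon == "GTG", ]
  expect_equal(gtg$f1, 0)
  expect_equal(gtg$bac, 0.5)                        # no positives either way
  all_ <- tab[tab$codon == "ALL", ]
  expect_identical(all_$tp + all_$fn + all_$fp + all_$tn, 5L)
  # row order of the input does not matter
  tab2 <- evaluatePerCodon(calls[sample(nrow(calls)), ])
  expect_identical(tab2, tab)
})

test_that("training refuses single-class input and records its artifact", {
  X <- matrix(stats::rnorm(40), 10)
  expect_error(trainTisModel(X, rep(1L, 10), X, rep(1L, 10)), "single class")
})
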