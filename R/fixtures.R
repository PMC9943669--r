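# Deterministic synthetic-fixture generator: a small two-contig genome with
# multi-exon transcripts on both strands, planted uORFs of every class, a
# variant suite with known expected annotations, an initiating-ribosome
# signal track and an expression table -- plus a truth manifest.
#
# All ground truth (ORF blocks, expected consequences/impacts) is computed
# here with per-base brute-force mapping and string surgery, independent of
# the package's interval-arithmetic code paths, so tests against the
# manifest are non-circular.

.randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# design-time assertion helpers (generator-internal brute force)
.codonsOf <- function(s, from = 1L) {
  n <- nchar(s)
  if (n - from + 1L < 3L) return(character(0))
  st <- seq.int(from, n - 2L, by = 3L)
  substring(s, st, st + 2L)
}
.hasStopInFrame <- function(s, offset0) {
  any(.codonsOf(s, from = offset0 + 1L) %in% c("TAA", "TAG", "TGA"))
}

# one transcript design in transcript space
.txDesign <- function(tid, gid, utr5, cds, utr3, cuts = integer(0),
                      intronLens = integer(0)) {
  S <- paste0(utr5, cds, utr3)
  stopifnot(nchar(cds) %% 3L == 0L,
            substr(cds, nchar(cds) - 2L, nchar(cds)) %in% c("TAA", "TAG", "TGA"),
            length(cuts) == length(intronLens),
            !is.unsorted(cuts, strictly = TRUE))
  list(tid = tid, gid = gid, S = S, utrLen = nchar(utr5),
       cdsLen = nchar(cds), cuts = as.integer(cuts),
       intronLens = as.integer(intronLens))
}

# place a design on a contig at `offset`; returns the genomic segment and the
# per-base transcript->genomic map (absolute coordinates, 0-based)
.placeTx <- function(d, strand, offset) {
  L <- nchar(d$S)
  bounds <- c(0L, d$cuts, L)
  exonSeqs <- substring(d$S, bounds[-length(bounds)] + 1L, bounds[-1L])
  introns <- vapply(d$intronLens, function(n) {
    stopifnot(n >= 8L)
    paste0("GT", .randomDna(n - 4L), "AG")
  }, character(1))
  pieces <- character(0)
  senseMap <- integer(L)           # tpos -> offset within sense segment
  at <- 0L
  for (i in seq_along(exonSeqs)) {
    exLen <- nchar(exonSeqs[i])
    t0 <- bounds[i]
    senseMap[(t0 + 1L):(t0 + exLen)] <- at + seq_len(exLen) - 1L
    pieces <- c(pieces, exonSeqs[i])
    at <- at + exLen
    if (i <= length(introns)) {
      pieces <- c(pieces, introns[i])
      at <- at + nchar(introns[i])
    }
  }
  segment <- paste0(pieces, collapse = "")
  segLen <- nchar(segment)
  if (strand == "+") {
    map <- offset + senseMap
  } else {
    segment <- .revcompChr(segment)
    map <- offset + (segLen - 1L) - senseMap
  }
  # exon genomic intervals from the per-base map (ascending)
  g <- sort(map)
  brk <- which(diff(g) != 1L)
  exS <- g[c(1L, brk + 1L)]
  exE <- g[c(brk, length(g))] + 1L
  list(segment = segment, map = map, exonStarts = exS, exonEnds = exE,
       segLen = segLen)
}

# genomic blocks of transcript interval [t1, t2) via the per-base map
.blocksFromMap <- function(map, t1, t2) {
  g <- sort(map[(t1 + 1L):t2])
  brk <- which(diff(g) != 1L)
  data.frame(start = g[c(1L, brk + 1L)], end = g[c(brk, length(g))] + 1L)
}

# VCF record helpers operating in genomic space ------------------------------

# SNV changing transcript base at tpos to `altT` (transcript orientation)
.snvRecord <- function(pl, strand, contig, tpos, altT) {
  g <- pl$map[tpos + 1L]
  ref <- substr(contig, g + 1L, g + 1L)
  alt <- if (strand == "+") altT else chartr("ACGT", "TGCA", altT)
  list(pos = g + 1L, ref = ref, alt = alt)
}

# deletion of transcript bases [tpos, tpos + n): genomic bases are contiguous
# when the range does not span a junction
.delRecord <- function(pl, contig, tpos, n) {
  g <- sort(pl$map[(tpos + 1L):(tpos + n)])
  stopifnot(all(diff(g) == 1L))
  a <- g[1L] - 1L                      # 0-based anchor
  list(pos = a + 1L, ref = substr(contig, a + 1L, a + 1L + n),
       alt = substr(contig, a + 1L, a + 1L))
}

# insertion of transcript-orientation string `insT` between tpos-1 and tpos
.insRecord <- function(pl, strand, contig, tpos, insT) {
  if (strand == "+") {
    a <- pl$map[tpos + 1L] - 1L        # anchor: base genomically before
    ins <- insT
  } else {
    a <- pl$map[tpos + 1L]             # minus: insertion lands after g(tpos)
    ins <- .revcompChr(insT)
  }
  ref <- substr(contig, a + 1L, a + 1L)
  list(pos = a + 1L, ref = ref, alt = paste0(ref, ins))
}

#' Generate the synthetic fixture set
#'
#' Builds a two-contig genome (~50 kb) carrying nine engineered transcripts:
#' plus- and minus-strand, single- and multi-exon, with planted uORFs of all
#' four classes (non-overlapping, overlapping, CDS extension, CDS
#' truncation), a multi-TIS/common-stop pair, junction-spanning uORFs, and a
#' stop-loss geometry whose variant creates an out-of-frame CDS overlap. A
#' planted variant suite covers every consequence and impact class on both
#' strands, plus normalization and filtering edge cases. The same seed
#' yields byte-identical files.
#'
#' @param seed Integer seed (drives only the filler sequence).
#' @param dir Output directory (created); `NULL` skips file output.
#' @return List: `genome`, `transcripts`, `orfs` (truth [OrfRecord]s built
#'   from per-base maps), `tisTable`, `variants` (expected-annotation
#'   data.frame), `catalogs`, `track`, `expression`, `manifest`, `paths`.
#' @export
makeFixture <- function(seed = 1L, dir = NULL) {
  .withSeed(seed, .makeFixtureImpl(dir))
}

.makeFixtureImpl <- function(dir) {
  U27 <- "ATGGCTGCAGCCGCACAAGCTGCATAA"      # 27-nt uORF body, CAA at offset 15
  stopifnot(nchar(U27) == 27L, !.hasStopInFrame(substr(U27, 1, 24), 0L))
  GAP21 <- "GCAGCACTAACTAGCGCAGCA"          # frame-0 clean; stops in frames 1/2
  stopifnot(nchar(GAP21) == 21L, !.hasStopInFrame(GAP21, 0L),
            .hasStopInFrame(GAP21, 1L), .hasStopInFrame(GAP21, 2L))
  F21 <- "CCTCCTCCTCCTCCTCCTCCT"
  CDS42 <- paste0("ATG", strrep("GCA", 12L), "TAA")

  # T1/T7 geometry: uORF at utr pos 21, in frame with the CDS (gap 21 nt),
  # stop-loss reads a stop-free frame-0 gap into the CDS -> N-term extension
  utr1 <- paste0(F21, U27, GAP21)           # 69 nt, CDS starts at 69
  stopifnot((69L - 21L) %% 3L == 0L)
  d1 <- function(tid, gid) .txDesign(tid, gid, utr1, CDS42,
                                     strrep("CCTTC", 6L),
                                     cuts = 31L, intronLens = 120L)

  # T2/T8 geometry: overlapping uORF; TIS at utr pos 50 of a 60-nt UTR
  # (frame +1 vs CDS); its in-frame stop sits at CDS offset 5 ("TAA" inside
  # ATGGCTAAG)
  utr2 <- paste0(strrep("CCTTC", 10L), "ATGCAAGGCG")
  cds2 <- paste0("ATGGCTAAG", strrep("GCA", 10L), "TAA")
  stopifnot(nchar(utr2) == 60L, !.hasStopInFrame(substr(cds2, 1, 39), 0L))
  d2 <- function(tid, gid) .txDesign(tid, gid, utr2, cds2, strrep("CT", 15L))

  # T3 geometry: GTG alternative TIS at utr pos 51 (in frame, stop-free gap)
  utr3 <- paste0(strrep("CCTTC", 10L), "TGTGGCAGCA")  # GTG at pos 51
  d3 <- .txDesign("TX_EXT_P", "G3", utr3, CDS42, strrep("GA", 15L),
                  cuts = 80L, intronLens = 90L)
  stopifnot(substr(utr3, 52L, 54L) == "GTG", (60L - 51L) %% 3L == 0L)

  # T4 geometry: internal in-frame ATG at CDS offset 9 -> truncation
  cds4 <- paste0("ATGGCAGCAATG", strrep("GCA", 8L), "TAA")
  d4 <- .txDesign("TX_TRN_P", "G4", strrep("CCTTC", 8L), cds4,
                  strrep("TC", 12L))

  # T5/T9 geometry: non-overlapping uORF out of frame with the CDS
  # (gap 13 nt); stop-loss reads a stop-free gap and meets a planted
  # uORF-frame stop inside the CDS -> out-of-frame overlap
  utr5 <- paste0(strrep("CT", 10L), U27, "GCAGCAGCAGCAG")  # TIS at 20
  stopifnot(nchar(utr5) == 60L, (60L - 20L) %% 3L == 1L)
  # CDS with a TAA at offset 20 (uORF frame: offsets congruent 2 mod 3)
  cds5 <- paste0("ATGGCAGCAGCAGCAGCAGC", "TAA", "CAGCAGCAGCAGC", "TAA")
  stopifnot(nchar(cds5) %% 3L == 0L,
            !.hasStopInFrame(substr(cds5, 1, nchar(cds5) - 3L), 0L),
            substr(cds5, 21L, 23L) == "TAA")
  d5 <- function(tid, gid) .txDesign(tid, gid, utr5, cds5, strrep("AG", 15L),
                                     cuts = 30L, intronLens = 80L)

  # T6 geometry: two TISs (ATG at 20, CTG at 26, same frame) sharing a stop
  utr6 <- paste0(strrep("CT", 10L), "ATGGCACTGGCAGCATAA", "CCTTCCTTCCTTCCTTCCTTCC")
  stopifnot(nchar(utr6) == 60L, substr(utr6, 27L, 29L) == "CTG")
  d6 <- .txDesign("TX_MTIS_P", "G6", utr6, CDS42, strrep("GT", 10L))

  designsP <- list(d1("TX_NOV_P", "G1"), d2("TX_OVL_P", "G2"), d3, d4,
                   d5("TX_ETF_P", "G5"), d6)
  designsM <- list(d1("TX_NOV_M", "G7"), d2("TX_OVL_M", "G8"),
                   d5("TX_ETF_M", "G9"))

  buildContig <- function(designs, strand, spacer = 400L) {
    seqs <- character(0); at <- 0L; placed <- list()
    for (d in designs) {
      sp <- .randomDna(spacer)
      seqs <- c(seqs, sp); at <- at + spacer
      pl <- .placeTx(d, strand, at)
      pl$design <- d; pl$strand <- strand
      placed[[d$tid]] <- pl
      seqs <- c(seqs, pl$segment); at <- at + pl$segLen
    }
    seqs <- c(seqs, .randomDna(spacer))
    list(seq = paste0(seqs, collapse = ""), placed = placed)
  }
  c1 <- buildContig(designsP, "+")
  c2 <- buildContig(designsM, "-")
  # pad contigs towards the ~50 kb genome scale
  c1$seq <- paste0(c1$seq, .randomDna(max(0L, 24000L - nchar(c1$seq))))
  c2$seq <- paste0(c2$seq, .randomDna(max(0L, 24000L - nchar(c2$seq))))
  contigs <- c(c1 = c1$seq, c2 = c2$seq)
  placed <- c(lapply(c1$placed, function(p) c(p, list(chrom = "c1"))),
              lapply(c2$placed, function(p) c(p, list(chrom = "c2"))))

  transcripts <- lapply(placed, function(p) {
    d <- p$design
    cdsT <- d$utrLen:(d$utrLen + d$cdsLen - 1L)
    g <- p$map[cdsT + 1L]
    TranscriptModel(d$tid, d$gid, p$chrom, p$strand,
                    p$exonStarts, p$exonEnds, min(g), max(g) + 1L)
  })
  names(transcripts) <- vapply(placed, function(p) p$design$tid, character(1))

  # planted TISs: tid, utr-relative tpos of TIS, codon, expected class,
  # expected stop tpos (NA = read-through)
  tisPlan <- data.frame(
    tid = c("TX_NOV_P", "TX_OVL_P", "TX_EXT_P", "TX_TRN_P", "TX_ETF_P",
            "TX_MTIS_P", "TX_MTIS_P", "TX_NOV_M", "TX_OVL_M", "TX_ETF_M"),
    tpos = c(21L, 50L, 51L, 49L, 20L, 20L, 26L, 21L, 50L, 20L),
    codon = c("ATG", "ATG", "GTG", "ATG", "ATG", "ATG", "CTG", "ATG", "ATG",
              "ATG"),
    class = c("non_overlapping_uORF", "overlapping_uORF", "cds_extension",
              "cds_truncation", "non_overlapping_uORF",
              "non_overlapping_uORF", "non_overlapping_uORF",
              "non_overlapping_uORF", "overlapping_uORF",
              "non_overlapping_uORF"),
    stopT = c(45L, 65L, 99L, 76L, 44L, 35L, 35L, 45L, 65L, 44L),
    stringsAsFactors = FALSE)

  orfs <- list(); tisRows <- list()
  for (i in seq_len(nrow(tisPlan))) {
    p <- placed[[tisPlan$tid[i]]]
    d <- p$design
    tis <- tisPlan$tpos[i]; stopT <- tisPlan$stopT[i]
    stopifnot(substr(d$S, tis + 1L, tis + 3L) == tisPlan$codon[i],
              substr(d$S, stopT + 1L, stopT + 3L) %in% c("TAA", "TAG", "TGA"),
              (stopT - tis) %% 3L == 0L,
              !.hasStopInFrame(substr(d$S, tis + 1L, stopT), 0L))
    blk <- .blocksFromMap(p$map, tis, stopT + 3L)
    gpos <- p$map[tis + 1L]
    orf <- new("OrfRecord",
               orfId = paste(d$tid, gpos, tisPlan$codon[i], sep = ":"),
               transcriptId = d$tid, chrom = p$chrom, strand = p$strand,
               blockStarts = as.integer(blk$start),
               blockEnds = as.integer(blk$end),
               startCodon = tisPlan$codon[i], stopFound = TRUE,
               orfClass = tisPlan$class[i], tisTpos = tis, stopTpos = stopT,
               tisGpos = gpos)
    orfs[[orf@orfId]] <- orf
    tisRows[[i]] <- data.frame(
      transcript_id = d$tid, gene_id = d$gid, chrom = p$chrom, gpos = gpos,
      strand = p$strand, codon = tisPlan$codon[i],
      stop_gpos = p$map[stopT + 1L], source = "manual",
      stringsAsFactors = FALSE)
  }
  tisTable <- do.call(rbind, tisRows)

  variants <- .plantVariants(placed, contigs)
  catalogs <- .plantCatalogs(tisTable)
  signal <- .plantSignal(placed, tisPlan, transcripts)
  genes <- unique(vapply(placed, function(p) p$design$gid, character(1)))
  expression <- matrix(stats::rnorm(length(genes) * 8L), nrow = length(genes),
                       dimnames = list(genes, paste0("cell", 1:8)))

  genome <- Biostrings::DNAStringSet(contigs)
  track <- SignalTrack(signal)
  manifest <- list(
    seed_note = "same seed reproduces byte-identical files",
    n_transcripts = length(transcripts),
    orfs = data.frame(orf_id = names(orfs),
                      class = vapply(orfs, orfClass, character(1)),
                      tis_tpos = vapply(orfs, function(o) o@tisTpos, integer(1)),
                      stop_tpos = vapply(orfs, function(o) o@stopTpos, integer(1)),
                      n_blocks = vapply(orfs, function(o)
                        length(o@blockStarts), integer(1)),
                      stringsAsFactors = FALSE),
    variants = variants$expected,
    catalogs = catalogs$expected)

  res <- list(genome = genome, transcripts = transcripts, orfs = orfs,
              tisTable = tisTable, variants = variants$expected,
              vcfRecords = variants$vcf, catalogs = catalogs$catalogs,
              track = track, expression = expression, manifest = manifest)
  if (!is.null(dir)) res$paths <- .writeFixture(res, signal, dir)
  res
}

# ---- variant planting ------------------------------------------------------

.plantVariants <- function(placed, contigs) {
  vcf <- list(); expected <- list()
  add <- function(id, chrom, rec, tid = NA, orfKey = NA, location = NA,
                  consequence = NA, impact = NA, readThrough = FALSE,
                  note = "") {
    vcf[[length(vcf) + 1L]] <<- data.frame(
      chrom = chrom, pos = rec$pos, id = id, ref = rec$ref, alt = rec$alt,
      stringsAsFactors = FALSE)
    expected[[length(expected) + 1L]] <<- data.frame(
      id = id, chrom = chrom, pos = rec$pos, ref = rec$ref, alt = rec$alt,
      transcript_id = tid, orf_key = orfKey, location = location,
      consequence = consequence, impact = impact,
      read_through = readThrough, note = note, stringsAsFactors = FALSE)
  }
  for (side in list(list(tid = "TX_NOV_P", ovl = "TX_OVL_P", etf = "TX_ETF_P",
                         chrom = "c1", tag = "p"),
                    list(tid = "TX_NOV_M", ovl = "TX_OVL_M", etf = "TX_ETF_M",
                         chrom = "c2", tag = "m"))) {
    chrom <- side$chrom; contig <- contigs[[chrom]]
    pn <- placed[[side$tid]]; st <- pn$strand
    tis <- 21L   # TIS of the NOV design within its transcript
    # synonymous: GCT -> GCC at uORF offset 5
    add(paste0("syn_", side$tag), chrom,
        .snvRecord(pn, st, contig, tis + 5L, "C"), side$tid, side$tid,
        "exonic", "synonymous", "not_applicable")
    # missense: GCC -> GAC at uORF offset 10
    add(paste0("mis_", side$tag), chrom,
        .snvRecord(pn, st, contig, tis + 10L, "A"), side$tid, side$tid,
        "exonic", "missense", "not_applicable")
    # stop gained: CAA -> TAA at uORF offset 15 (non-overlapping uORF)
    add(paste0("sg_", side$tag), chrom,
        .snvRecord(pn, st, contig, tis + 15L, "T"), side$tid, side$tid,
        "exonic", "stop_gained", "main_CDS_unaffected")
    # stop lost: TAA -> CAA; in-frame stop-free gap -> N-terminal extension
    add(paste0("sl_", side$tag), chrom,
        .snvRecord(pn, st, contig, tis + 24L, "C"), side$tid, side$tid,
        "exonic", "stop_lost", "N-terminal_extension")
    # frameshift (1-nt deletion at uORF offset 7): stop in the shifted gap
    add(paste0("fs_", side$tag), chrom,
        .delRecord(pn, contig, tis + 7L, 1L), side$tid, side$tid,
        "exonic", "frameshift", "main_CDS_unaffected")
    # in-frame deletion of one whole codon (uORF offsets 12-14, clear of the
    # exon junction at transcript position 31)
    add(paste0("if_", side$tag), chrom,
        .delRecord(pn, contig, tis + 12L, 3L), side$tid, side$tid,
        "exonic", "inframe_indel", "not_applicable")
    # start lost: ATG -> ACG
    add(paste0("stl_", side$tag), chrom,
        .snvRecord(pn, st, contig, tis + 1L, "C"), side$tid, side$tid,
        "exonic", "start_lost", "not_applicable")
    # splice site: donor +2 of the intron inside the uORF (after tpos 30)
    donor2 <- if (st == "+") pn$map[31L] + 2L else pn$map[31L] - 2L
    ref <- substr(contig, donor2 + 1L, donor2 + 1L)
    altBase <- if (ref == "A") "G" else "A"
    add(paste0("spl_", side$tag), chrom,
        list(pos = donor2 + 1L, ref = ref, alt = altBase), side$tid,
        side$tid, "splice_site", "splice_site", "not_applicable")
    # deep intronic: +50 into the same intron
    deep <- if (st == "+") pn$map[31L] + 50L else pn$map[31L] - 50L
    refd <- substr(contig, deep + 1L, deep + 1L)
    add(paste0("deep_", side$tag), chrom,
        list(pos = deep + 1L, ref = refd,
             alt = if (refd == "C") "G" else "C"),
        side$tid, side$tid, "deep_intronic", NA, "not_applicable")
    # overlapping uORF: stop gained upstream of the CDS -> overlap removal
    po <- placed[[side$ovl]]
    add(paste0("sgo_", side$tag), chrom,
        .snvRecord(po, st, contig, 53L, "T"), side$ovl, side$ovl,
        "exonic", "stop_gained", "overlap_removal")
    # overlapping uORF: stop lost (overlap persists, same frame)
    add(paste0("slo_", side$tag), chrom,
        .snvRecord(po, st, contig, 65L, "C"), side$ovl, side$ovl,
        "exonic", "stop_lost", "main_CDS_unaffected", readThrough = TRUE)
    # out-of-frame geometry: stop lost meets a planted in-frame stop inside
    # the CDS -> out-of-frame overlap
    pe <- placed[[side$etf]]
    add(paste0("sle_", side$tag), chrom,
        .snvRecord(pe, st, contig, 44L, "C"), side$etf, side$etf,
        "exonic", "stop_lost", "out_of_frame_overlap")
    # frameshift (+1 insertion) reading through the whole feature: the
    # shifted frame meets no stop before the feature end
    add(paste0("fse_", side$tag), chrom,
        .insRecord(pe, st, contig, 23L, "G"), side$etf, side$etf,
        "exonic", "frameshift", "out_of_frame_overlap", readThrough = TRUE)
  }
  pn <- placed[["TX_NOV_P"]]; contig <- contigs[["c1"]]
  # frame-restoring insertion partner for fs_p (1-nt insertion before uORF
  # offset 20, i.e. between offsets 19 and 20)
  add("fr_ins_p", "c1", .insRecord(pn, "+", contig, 21L + 20L, "G"),
      "TX_NOV_P", "TX_NOV_P", "exonic", "frameshift", "main_CDS_unaffected")
  # multiallelic missense record on the uORF (both ALTs missense)
  g <- pn$map[21L + 10L + 1L]
  add("multi_p", "c1",
      list(pos = g + 1L, ref = substr(contig, g + 1L, g + 1L), alt = "A,T"),
      "TX_NOV_P", "TX_NOV_P", "exonic", "missense", "not_applicable",
      note = "multiallelic")
  # junction-spanning deletion: last 2 exonic bases of exon 1 + 2 intronic
  a <- pn$map[30L] - 1L
  add("junc_p", "c1",
      list(pos = a + 1L, ref = substr(contig, a + 1L, a + 5L),
           alt = substr(contig, a + 1L, a + 1L)),
      "TX_NOV_P", "TX_NOV_P", "splice_site", "splice_site", "not_applicable",
      note = "junction_spanning")
  # large insertion (dropped with reason large_indel)
  g2 <- pn$map[21L + 12L + 1L]
  add("large_p", "c1",
      list(pos = g2 + 1L, ref = substr(contig, g2 + 1L, g2 + 1L),
           alt = paste0(substr(contig, g2 + 1L, g2 + 1L),
                        strrep("ACGT", 50L))),
      NA, NA, "dropped", NA, NA, note = "large_indel")
  # 3'UTR variant outside every uORF: absent from all outputs
  d <- placed[["TX_NOV_P"]]$design
  gu <- pn$map[nchar(d$S) - 5L]
  add("out_p", "c1",
      list(pos = gu + 1L, ref = substr(contig, gu + 1L, gu + 1L),
           alt = if (substr(contig, gu + 1L, gu + 1L) == "A") "C" else "A"),
      NA, NA, "outside", NA, NA, note = "no_uorf_overlap")
  # main-CDS missense inside the overlapping uORF (exercises
  # --exclude-main-cds)
  po <- placed[["TX_OVL_P"]]
  add("cds_p", "c1", .snvRecord(po, "+", contig, 61L, "G"),
      "TX_OVL_P", "TX_OVL_P", "exonic", "missense", "not_applicable",
      note = "in_main_cds")
  vcfDf <- do.call(rbind, vcf)
  expDf <- do.call(rbind, expected)
  ord <- order(vcfDf$chrom, vcfDf$pos)
  list(vcf = vcfDf[ord, ], expected = expDf)
}

# ---- catalogs, signal, files ----------------------------------------------

# four catalogs with a known membership structure over the planted TISs
.plantCatalogs <- function(tisTable) {
  u <- tisTable[tisTable$transcript_id != "TX_TRN_P", ]  # uORF-type TISs
  n <- nrow(u)
  member <- matrix(FALSE, n, 4L, dimnames = list(NULL, c("A", "B", "C", "D")))
  member[, "A"] <- TRUE                          # A sees everything
  member[seq(1L, n, by = 2L), "B"] <- TRUE       # B every other
  member[seq(1L, n, by = 3L), "C"] <- TRUE       # C every third
  member[1L, "D"] <- TRUE                        # D only the first
  catalogs <- lapply(colnames(member), function(cl) {
    d <- u[member[, cl], c("chrom", "strand", "gpos", "codon", "stop_gpos")]
    # within-catalog duplicate: repeat the first row of A
    if (cl == "A") d <- rbind(d, d[1L, ])
    attr(d, "assembly") <- "fixture1"
    d
  })
  names(catalogs) <- colnames(member)
  expInAtLeast2 <- rowSums(member) >= 2L
  list(catalogs = catalogs,
       expected = data.frame(chrom = u$chrom, gpos = u$gpos,
                             codon = u$codon,
                             n_catalogs = rowSums(member),
                             high_confidence = expInAtLeast2,
                             stringsAsFactors = FALSE))
}

# initiation peaks: 60 reads at each uORF TIS, 30 at each main-CDS start
# (ratio 2), except the second TIS of the multi-TIS pair (30: ratio 1)
.plantSignal <- function(placed, tisPlan, transcripts) {
  rows <- list()
  for (i in seq_len(nrow(tisPlan))) {
    p <- placed[[tisPlan$tid[i]]]
    h <- if (tisPlan$tid[i] == "TX_MTIS_P" && tisPlan$codon[i] == "CTG")
      30 else 60
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = p$chrom, pos = p$map[tisPlan$tpos[i] + 1L], count = h)
  }
  for (tid in names(placed)) {
    p <- placed[[tid]]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = p$chrom, pos = p$map[p$design$utrLen + 1L], count = 30)
  }
  d <- do.call(rbind, rows)
  d <- stats::aggregate(count ~ chrom + pos, data = d, FUN = max)
  d[order(d$chrom, d$pos), ]
}

.writeFixture <- function(res, signal, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    bed = file.path(dir, "uorfs.bed"),
    vcf = file.path(dir, "variants.vcf"),
    bedgraph = file.path(dir, "signal.bedgraph"),
    expression = file.path(dir, "expression.tsv"),
    tis = file.path(dir, "tis_table.tsv"),
    manifest = file.path(dir, "manifest.json"))
  Biostrings::writeXStringSet(res$genome, paths$fasta)
  .writeEdgeGtf(res$transcripts, paths$gtf)
  writeOrfBed(res$orfs, paths$bed)
  .writeVcfLines(res$vcfRecords, names(res$genome), paths$vcf)
  with(signal, writeLines(sprintf("%s\t%d\t%d\t%g", chrom, pos, pos + 1L,
                                  count), paths$bedgraph))
  utils::write.table(cbind(gene_id = rownames(res$expression),
                           as.data.frame(res$expression)),
                     paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$tisTable, paths$tis, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(res$manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (cl in names(res$catalogs)) {
    paths[[paste0("catalog_", cl)]] <- file.path(dir,
                                                 paste0("catalog_", cl, ".tsv"))
    utils::write.table(res$catalogs[[cl]], paths[[paste0("catalog_", cl)]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths
}

# the GTF additionally carries two malformed entries the loader must skip:
# an exon-only transcript and a CDS whose length is not a multiple of 3
.writeEdgeGtf <- function(transcripts, path) {
  writeTranscriptsGtf(transcripts, path)
  t1 <- transcripts[[1L]]
  extra <- c(
    paste("c1", "uORFtools", "exon", 10, 80, ".", "+", ".",
          'gene_id "G_NOCDS"; transcript_id "TX_NOCDS";', sep = "\t"),
    paste("c1", "uORFtools", "exon", 110, 200, ".", "+", ".",
          'gene_id "G_BADCDS"; transcript_id "TX_BADCDS";', sep = "\t"),
    paste("c1", "uORFtools", "CDS", 120, 123, ".", "+", "0",
          'gene_id "G_BADCDS"; transcript_id "TX_BADCDS";', sep = "\t"))
  cat(paste0(extra, "\n", collapse = ""), file = path, append = TRUE)
}

.writeVcfLines <- function(vcfDf, contigNames, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", contigNames),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", vcfDf$chrom, vcfDf$pos,
                  vcfDf$id, vcfDf$ref, vcfDf$alt)
  writeLines(c(hdr, body), path)
}
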