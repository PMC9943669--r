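#' @importFrom Biostrings readDNAStringSet DNAStringSet DNAString
#'   reverseComplement subseq GENETIC_CODE writeXStringSet
NULL

#' Load a reference genome from FASTA
#'
#' Sequences are uppercased; `N` is preserved. Bases outside `{A,C,G,T,N}`
#' and duplicated contig names are errors.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] (one entry per contig).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), fa)
#' as.character(loadGenome(fa)[["c1"]])
#' @export
loadGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  # first whitespace-delimited token is the contig name
  names(ss) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(ss)))
    stop("duplicate contig names in FASTA: ",
         paste(unique(names(ss)[duplicated(names(ss))]), collapse = ", "))
  up <- Biostrings::DNAStringSet(toupper(as.character(ss)))
  names(up) <- names(ss)
  bad <- grepl("[^ACGTN]", as.character(up))
  if (any(bad))
    stop("contig(s) contain bases outside {A,C,G,T,N}: ",
         paste(names(up)[bad], collapse = ", "))
  up
}

#' Fetch a genomic subsequence with bounds checking
#'
#' @param genome A `DNAStringSet` from [loadGenome()].
#' @param chrom Contig name.
#' @param start,end 0-based half-open genomic interval.
#' @return Character scalar (forward strand).
#' @export
contigSequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("contig not in genome: ", chrom)
  w <- length(genome[[chrom]])
  if (start < 0L || end > w || start >= end)
    stop(sprintf("interval [%d,%d) outside contig %s (length %d)",
                 start, end, chrom, w))
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

.revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Standard codon table
#'
#' All 64 codons; the three stops TAA, TAG, TGA are `"*"`. Codons containing
#' `N` translate to `"X"` and are never a valid start or stop.
#'
#' @return Named character vector codon -> amino acid.
#' @export
standardCodonTable <- function() {
  tab <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(tab), names(tab))
}

.STOPS <- c("TAA", "TAG", "TGA")

#' Translate a DNA string in frame 0
#'
#' Codons are read from the first base; a trailing partial codon is ignored.
#' Stops are rendered as `*`; codons containing `N` as `X`.
#'
#' @param seq DNA character scalar (length >= 3).
#' @param table Codon table from [standardCodonTable()].
#' @return Amino-acid string.
#' @examples
#' translateDna("ATGTAA")  # "M*"
#' @export
translateDna <- function(seq, table = standardCodonTable()) {
  n <- nchar(seq)
  if (n < 3L) stop("sequence shorter than one codon")
  starts <- seq.int(1L, n - 2L, by = 3L)
  cod <- substring(seq, starts, starts + 2L)
  aa <- unname(table[cod])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

#' Map a genomic position to a transcript position
#'
#' @param t A [TranscriptModel].
#' @param g Integer vector of 0-based genomic positions.
#' @return Integer vector of 0-based transcript positions (5' to 3'); `NA`
#'   where `g` is intronic or outside the transcript.
#' @export
genomicToTranscript <- function(t, g) {
  s <- t@exonStarts; e <- t@exonEnds
  cum <- c(0L, cumsum(e - s))
  idx <- findInterval(g, s)
  ok <- idx >= 1L & g < e[pmax(idx, 1L)] & g >= s[pmax(idx, 1L)]
  asc <- rep(NA_integer_, length(g))
  asc[ok] <- cum[idx[ok]] + (g[ok] - s[idx[ok]])
  if (t@strand == "+") asc else splicedLength(t) - 1L - asc
}

#' Map a transcript position to a genomic position
#'
#' Inverse of [genomicToTranscript()] on exonic positions.
#'
#' @param t A [TranscriptModel].
#' @param p Integer vector of 0-based transcript positions.
#' @return Integer vector of genomic positions.
#' @export
transcriptToGenomic <- function(t, p) {
  L <- splicedLength(t)
  if (any(p < 0L | p >= L)) stop("transcript position out of range [0, ", L, ")")
  asc <- if (t@strand == "+") p else L - 1L - p
  s <- t@exonStarts; e <- t@exonEnds
  cum <- c(0L, cumsum(e - s))
  idx <- findInterval(asc, cum, rightmost.closed = FALSE)
  idx[idx > length(s)] <- length(s)
  s[idx] + (asc - cum[idx])
}

#' Spliced transcript sequence
#'
#' Exonic sequences concatenated 5' to 3'; reverse-complemented for
#' minus-strand transcripts.
#'
#' @param t A [TranscriptModel].
#' @param genome Genome from [loadGenome()].
#' @return Character scalar of length [splicedLength()].
#' @export
splicedSequence <- function(t, genome) {
  pieces <- mapply(function(a, b) contigSequence(genome, t@chrom, a, b),
                   t@exonStarts, t@exonEnds)
  seqp <- paste0(pieces, collapse = "")
  if (t@strand == "+") seqp else .revcompChr(seqp)
}

#' Main-CDS anchors in transcript coordinates
#'
#' @param t A [TranscriptModel].
#' @return Integer vector `c(start, end)`: 0-based transcript position of the
#'   main start codon first base and one past the main stop codon.
#' @export
cdsTranscriptAnchors <- function(t) {
  if (t@strand == "+") {
    c(genomicToTranscript(t, t@cdsStartG),
      genomicToTranscript(t, t@cdsEndG - 1L) + 1L)
  } else {
    c(genomicToTranscript(t, t@cdsEndG - 1L),
      genomicToTranscript(t, t@cdsStartG) + 1L)
  }
}

#' Project a transcript interval onto genomic exon blocks
#'
#' @param t A [TranscriptModel].
#' @param tstart,tend 0-based half-open transcript interval.
#' @return data.frame with ascending 0-based half-open `start`, `end` blocks.
#' @export
transcriptIntervalToBlocks <- function(t, tstart, tend) {
  stopifnot(tstart >= 0L, tend > tstart, tend <= splicedLength(t))
  L <- splicedLength(t)
  if (t@strand == "+") { a1 <- tstart; a2 <- tend } else {
    a1 <- L - tend; a2 <- L - tstart
  }
  s <- t@exonStarts; e <- t@exonEnds
  cum <- c(0L, cumsum(e - s))
  bs <- integer(0); be <- integer(0)
  for (i in seq_along(s)) {
    lo <- max(a1, cum[i]); hi <- min(a2, cum[i + 1L])
    if (lo < hi) {
      bs <- c(bs, s[i] + (lo - cum[i]))
      be <- c(be, s[i] + (hi - cum[i]))
    }
  }
  data.frame(start = bs, end = be)
}

#' Load transcript models from GTF
#'
#' Expects `exon` and `CDS` features carrying `transcript_id` and `gene_id`
#' attributes. CDS features are taken at face value and must span the main ORF
#' *including* its stop codon. Transcripts without CDS features, with CDS
#' outside the exon union, or with a spliced CDS length that is not a positive
#' multiple of 3 are skipped with a warning (or rejected when
#' `strict = TRUE`).
#'
#' @param path GTF file path.
#' @param strict Hard-fail instead of warn-and-skip on malformed transcripts.
#' @return Named list of [TranscriptModel] objects.
#' @export
loadTranscripts <- function(path, strict = FALSE) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  need <- c("type", "transcript_id", "gene_id")
  if (!all(need %in% names(df)))
    stop("GTF must provide type, transcript_id and gene_id")
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  out <- list()
  for (tid in unique(df$transcript_id)) {
    d <- df[df$transcript_id == tid, , drop = FALSE]
    ex <- d[d$type == "exon", , drop = FALSE]
    cds <- d[d$type == "CDS", , drop = FALSE]
    bail <- function(reason) {
      if (strict) stop("transcript ", tid, ": ", reason)
      warning("skipping transcript ", tid, ": ", reason, call. = FALSE)
      NULL
    }
    if (!nrow(cds)) { bail("no CDS features"); next }
    if (!nrow(ex)) { bail("no exon features"); next }
    ord <- order(ex$start)
    tm <- tryCatch(
      TranscriptModel(tid, cds$gene_id[1L], as.character(ex$seqnames[1L]),
                      as.character(ex$strand[1L]),
                      ex$start[ord] - 1L, ex$end[ord],
                      min(cds$start) - 1L, max(cds$end)),
      error = function(e) { bail(conditionMessage(e)); NULL })
    if (!is.null(tm)) out[[tid]] <- tm
  }
  out
}

#' Write transcript models as GTF
#'
#' Emits `exon` and `CDS` features (CDS includes the stop codon), quoted
#' Ensembl-style attributes; 1-based closed coordinates per the GTF
#' convention.
#'
#' @param transcripts List of [TranscriptModel].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeTranscriptsGtf <- function(transcripts, path) {
  lines <- character(0)
  for (t in transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', t@geneId,
                     t@transcriptId)
    for (i in seq_along(t@exonStarts)) {
      lines <- c(lines, paste(t@chrom, "uORFtools", "exon",
                              t@exonStarts[i] + 1L, t@exonEnds[i], ".",
                              t@strand, ".", attrs, sep = "\t"))
    }
    blk <- transcriptIntervalToBlocks(
      t, cdsTranscriptAnchors(t)[1L], cdsTranscriptAnchors(t)[2L])
    for (i in seq_len(nrow(blk))) {
      lines <- c(lines, paste(t@chrom, "uORFtools", "CDS",
                              blk$start[i] + 1L, blk$end[i], ".",
                              t@strand, "0", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
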