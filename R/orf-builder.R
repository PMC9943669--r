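# Building ORFs from translation initiation sites on spliced transcripts,
# classifying them against the main CDS, reconciling catalogs, and relative
# TIS signal.

#' Build an ORF from a translation initiation site
#'
#' Reads codons 5' to 3' from the TIS along the spliced transcript to the
#' first in-frame stop. When the transcript ends before a stop the ORF is
#' retained open-ended with `stopFound = FALSE` (these are exactly the
#' read-through cases the variant annotator reasons about). Genomic blocks
#' are computed by projecting the transcript interval back onto exons.
#'
#' @param tis A list/one-row data.frame with `gpos` (genomic coordinate of
#'   the codon's first base in transcript orientation) and `codon`.
#' @param t A [TranscriptModel].
#' @param genome Genome from [loadGenome()].
#' @param splicedSeq Optional precomputed [splicedSequence()] (speed).
#' @return An [OrfRecord] with `orfClass` set by [classifyOrf()].
#' @export
buildOrf <- function(tis, t, genome, splicedSeq = NULL) {
  gpos <- as.integer(tis$gpos)
  tisT <- genomicToTranscript(t, gpos)
  if (is.na(tisT)) stop("TIS at ", t@chrom, ":", gpos, " is intronic or outside transcript ",
                        t@transcriptId)
  S <- if (is.null(splicedSeq)) splicedSequence(t, genome) else splicedSeq
  L <- nchar(S)
  if (tisT + 3L > L) stop("TIS too close to transcript 3' end")
  obs <- substr(S, tisT + 1L, tisT + 3L)
  if (!is.null(tis$codon) && !is.na(tis$codon) && nzchar(tis$codon) &&
      obs != tis$codon)
    stop(sprintf("TIS codon mismatch on %s at %d: declared %s, genome has %s",
                 t@transcriptId, gpos, tis$codon, obs))
  starts0 <- seq.int(tisT, L - 3L, by = 3L)
  cods <- substring(S, starts0 + 1L, starts0 + 3L)
  stopAt <- which(cods %in% .STOPS)
  if (length(stopAt)) {
    stopT <- starts0[stopAt[1L]]
    endT <- stopT + 3L
    found <- TRUE
  } else {
    stopT <- NA_integer_
    endT <- L           # open-ended: to transcript end
    found <- FALSE
  }
  blk <- transcriptIntervalToBlocks(t, tisT, endT)
  orf <- new("OrfRecord",
             orfId = paste(t@transcriptId, gpos, obs, sep = ":"),
             transcriptId = t@transcriptId, chrom = t@chrom,
             strand = t@strand,
             blockStarts = as.integer(blk$start),
             blockEnds = as.integer(blk$end),
             startCodon = obs, stopFound = found,
             orfClass = "non_overlapping_uORF",  # placeholder, set below
             tisTpos = as.integer(tisT), stopTpos = stopT,
             tisGpos = gpos)
  orf@orfClass <- classifyOrf(orf, t)
  methods::validObject(orf)
  orf
}

#' Classify an ORF against the main CDS
#'
#' With `c` the transcript position of the main-CDS start and frame
#' congruence `(tisTpos - c) mod 3`: an ORF whose stop lies entirely before
#' `c` is a `non_overlapping_uORF`; one that crosses `c` out of frame is an
#' `overlapping_uORF`; an upstream in-frame TIS with no intervening stop is a
#' `cds_extension`; a downstream in-frame TIS is a `cds_truncation`. A
#' downstream out-of-frame TIS is flagged `internal_oof` (not one of the four
#' standard groups, retained rather than silently dropped).
#'
#' @param orf An [OrfRecord] built on `t`.
#' @param t A [TranscriptModel].
#' @return Character scalar, one of [orfClasses()].
#' @export
classifyOrf <- function(orf, t) {
  cc <- cdsTranscriptAnchors(t)[1L]
  tis <- orf@tisTpos
  endT <- if (orf@stopFound) orf@stopTpos + 3L else
    tis + orfLength(orf)
  inframe <- (tis - cc) %% 3L == 0L
  if (tis >= cc) {
    if (inframe) return("cds_truncation")
    return("internal_oof")
  }
  if (orf@stopFound && endT <= cc) return("non_overlapping_uORF")
  if (inframe) return("cds_extension")
  "overlapping_uORF"
}

#' Reconcile uORF catalogs into a high-confidence set
#'
#' Entries are matched across catalogs by exact TIS genomic coordinate
#' (default) or by exact stop-codon coordinate; a uORF is high-confidence
#' when its key occurs in at least two distinct catalogs. Duplicates within
#' one catalog count once. The high-confidence set is additionally split into
#' ATG-started and non-ATG-started subsets.
#'
#' @param catalogs Named list (>= 2) of data.frames with columns `chrom`,
#'   `strand`, `gpos`, `codon` (and `stop_gpos` for `mode = "stop"`). An
#'   optional `assembly` attribute per catalog is checked for consistency.
#' @param mode `"tis"` or `"stop"` matching key.
#' @return List with `membership` (logical key x catalog matrix),
#'   `highConfidence`, `atg`, `nonAtg` data.frames.
#' @export
compareCatalogs <- function(catalogs, mode = c("tis", "stop")) {
  mode <- match.arg(mode)
  if (length(catalogs) < 2L) stop("need at least two catalogs")
  if (is.null(names(catalogs)) || any(!nzchar(names(catalogs))))
    stop("catalogs must be named")
  asm <- unlist(lapply(catalogs, function(x) attr(x, "assembly") %||% NA_character_))
  asm <- asm[!is.na(asm)]
  if (length(unique(asm)) > 1L)
    stop("mixed-assembly input: ", paste(unique(asm), collapse = " vs "))
  keyOf <- function(d) {
    pos <- if (mode == "tis") d$gpos else d$stop_gpos
    paste(d$chrom, d$strand, pos, sep = "|")
  }
  keyed <- lapply(catalogs, function(d) {
    k <- keyOf(d)
    dup <- !duplicated(k)
    data.frame(key = k[dup], chrom = d$chrom[dup], strand = d$strand[dup],
               gpos = d$gpos[dup], codon = d$codon[dup],
               stringsAsFactors = FALSE)
  })
  allKeys <- sort(unique(unlist(lapply(keyed, `[[`, "key"))))
  membership <- vapply(keyed, function(d) allKeys %in% d$key,
                       logical(length(allKeys)))
  dimnames(membership) <- list(allKeys, names(catalogs))
  hcKeys <- allKeys[rowSums(membership) >= 2L]
  lookup <- do.call(rbind, keyed)
  lookup <- lookup[!duplicated(lookup$key), , drop = FALSE]
  hc <- lookup[match(hcKeys, lookup$key), , drop = FALSE]
  rownames(hc) <- NULL
  hc$n_catalogs <- rowSums(membership)[match(hcKeys, allKeys)]
  list(membership = membership,
       highConfidence = hc,
       atg = hc[hc$codon == "ATG", , drop = FALSE],
       nonAtg = hc[hc$codon != "ATG", , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a SignalTrack from a data.frame
#'
#' @param df data.frame with `chrom`, `pos` (0-based), `count` and optionally
#'   `strand` (defaults to `"*"`, unstranded).
#' @return A [SignalTrack].
#' @export
SignalTrack <- function(df) {
  if (is.null(df$strand)) df$strand <- "*"
  dt <- data.table::as.data.table(
    df[, c("chrom", "strand", "pos", "count")])
  dt <- dt[dt$count != 0, ]
  data.table::setkeyv(dt, c("chrom", "strand", "pos"))
  new("SignalTrack", data = dt)
}

#' Read an initiating-ribosome signal track (bedGraph or wiggle)
#'
#' @param path File path; format inferred from the extension by
#'   rtracklayer (`.bedgraph`/`.bg`/`.wig`).
#' @param strand Strand to assign (`"*"` for unstranded tracks).
#' @return A [SignalTrack] with one row per covered base.
#' @export
loadSignalTrack <- function(path, strand = "*") {
  fmt <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  df <- as.data.frame(gr)
  pos <- unlist(mapply(function(a, b) seq.int(a, b), df$start - 1L,
                       df$end - 1L, SIMPLIFY = FALSE))
  cnt <- rep(df$score, df$end - df$start + 1L)
  chr <- rep(as.character(df$seqnames), df$end - df$start + 1L)
  SignalTrack(data.frame(chrom = chr, pos = as.integer(pos), count = cnt,
                         strand = strand, stringsAsFactors = FALSE))
}

#' Query read counts at genomic positions
#'
#' Counts on matching-strand and unstranded (`"*"`) entries are summed, so
#' stranded tracks are honoured when present and collapsed otherwise.
#'
#' @param track A [SignalTrack].
#' @param chrom Contig name (scalar).
#' @param positions Integer vector of 0-based positions.
#' @param strand Query strand (`"+"`, `"-"` or `"*"`).
#' @return Numeric vector of counts (0 where uncovered).
#' @export
signalAt <- function(track, chrom, positions, strand = "*") {
  if (!length(positions)) return(numeric(0))
  strands <- unique(c(strand, "*"))
  q <- data.table::CJ(chrom = chrom, strand = strands,
                      pos = as.integer(positions), sorted = FALSE)
  hit <- track@data[q, on = c("chrom", "strand", "pos")]
  hit$count[is.na(hit$count)] <- 0
  out <- tapply(hit$count, hit$pos, sum)
  as.numeric(out[as.character(positions)])
}

#' Translation initiation signal of a uORF relative to the main CDS
#'
#' Ratio of summed counts over the uORF start codon (+/- `window` nt in
#' transcript space) to the same sum at the main-CDS start codon. `NA` with a
#' warning when the denominator is zero.
#'
#' @param orf An [OrfRecord].
#' @param t Its [TranscriptModel].
#' @param track A [SignalTrack].
#' @param window Flank in nt around the 3-nt codon (default 0: codon only).
#' @return Numeric ratio, or `NA` when the CDS start has no signal.
#' @export
relativeTisSignal <- function(orf, t, track, window = 0L) {
  sumAt <- function(tpos) {
    rng <- (tpos - window):(tpos + 2L + window)
    rng <- rng[rng >= 0L & rng < splicedLength(t)]
    g <- transcriptToGenomic(t, rng)
    sum(signalAt(track, t@chrom, g, t@strand))
  }
  num <- sumAt(orf@tisTpos)
  den <- sumAt(cdsTranscriptAnchors(t)[1L])
  if (den == 0) {
    warning("no initiation signal at the main-CDS start of ", t@transcriptId)
    return(NA_real_)
  }
  num / den
}
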