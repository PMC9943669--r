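#' @import methods
#' @importFrom S4Vectors isSorted
NULL

# data.table joins are used for signal lookups
.datatable.aware <- TRUE

# Internal coordinate convention: 0-based half-open genomic intervals and
# 0-based transcript positions (position 0 = spliced 5' end). BED stays
# 0-based half-open; GTF (1-based closed) and VCF (1-based) are converted at
# the I/O boundary only.

#' The ten start codons considered for translation initiation
#'
#' The canonical ATG plus the nine near-cognate codons (single-base
#' substitutions of ATG) that can initiate translation.
#'
#' @return Character vector of ten codons.
#' @export
nearCognateCodons <- function() {
  c("ATG", "TTG", "GTG", "CTG", "AAG", "AGG", "ACG", "ATA", "ATT", "ATC")
}

#' The four ORF classes plus the out-of-frame internal flag class
#' @return Character vector of class labels.
#' @export
orfClasses <- function() {
  c("non_overlapping_uORF", "overlapping_uORF", "cds_extension",
    "cds_truncation", "internal_oof")
}

#' uORF-level variant consequence labels
#' @return Character vector of consequence labels.
#' @export
uorfConsequences <- function() {
  c("synonymous", "missense", "inframe_indel", "stop_gained", "stop_lost",
    "frameshift", "start_lost", "splice_site")
}

#' Main-CDS impact categories for length-affecting uORF variants
#' @return Character vector of impact labels.
#' @export
mainCdsImpacts <- function() {
  c("main_CDS_unaffected", "overlap_removal", "N-terminal_extension",
    "out_of_frame_overlap", "not_applicable")
}

#' TranscriptModel: a spliced transcript with main-CDS anchors
#'
#' Exons are stored in ascending genomic order on both strands (the BED12
#' block convention); all 5'/3' logic goes through [genomicToTranscript()] and
#' [transcriptToGenomic()]. `cdsStartG`/`cdsEndG` delimit the main ORF
#' *including* its stop codon, as a 0-based half-open genomic interval.
#'
#' @slot transcriptId,geneId,chrom character scalars.
#' @slot strand `"+"` or `"-"`.
#' @slot exonStarts,exonEnds integer vectors, 0-based half-open, ascending,
#'   disjoint.
#' @slot cdsStartG,cdsEndG integer scalars (0-based half-open CDS span,
#'   stop codon included).
#' @export
setClass("TranscriptModel", representation(
  transcriptId = "character",
  geneId = "character",
  chrom = "character",
  strand = "character",
  exonStarts = "integer",
  exonEnds = "integer",
  cdsStartG = "integer",
  cdsEndG = "integer"
))

setValidity("TranscriptModel", function(object) {
  msg <- character()
  s <- object@exonStarts; e <- object@exonEnds
  if (length(s) != length(e) || length(s) == 0L)
    msg <- c(msg, "exonStarts/exonEnds must be non-empty and equal length")
  if (!(object@strand %in% c("+", "-")))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(s) && any(e <= s))
    msg <- c(msg, "each exon must satisfy start < end")
  if (length(s) > 1L && (is.unsorted(s, strictly = TRUE) ||
                         any(s[-1L] < e[-length(e)])))
    msg <- c(msg, "exons must be sorted and disjoint")
  if (length(s)) {
    inside <- function(g) any(g >= s & g < e)
    if (!inside(object@cdsStartG) || !inside(object@cdsEndG - 1L))
      msg <- c(msg, "CDS anchors must fall inside the exon union")
    else {
      len <- .splicedSpanLength(s, e, object@cdsStartG, object@cdsEndG)
      if (len <= 0L || len %% 3L != 0L)
        msg <- c(msg, "spliced main-CDS length must be a positive multiple of 3")
    }
  }
  if (length(msg)) msg else TRUE
})

# spliced length of genomic interval [g1, g2) intersected with the exon union
.splicedSpanLength <- function(starts, ends, g1, g2) {
  sum(pmax(0L, pmin(ends, g2) - pmax(starts, g1)))
}

#' @describeIn TranscriptModel spliced transcript length in nucleotides
#' @param t A `TranscriptModel`.
#' @export
splicedLength <- function(t) sum(t@exonEnds - t@exonStarts)

#' Accessors for TranscriptModel
#'
#' @param t A `TranscriptModel`.
#' @return The corresponding slot value.
#' @name transcript-accessors
NULL

#' @rdname transcript-accessors
#' @export
transcriptId <- function(t) t@transcriptId
#' @rdname transcript-accessors
#' @export
geneId <- function(t) t@geneId
#' @rdname transcript-accessors
#' @export
txChrom <- function(t) t@chrom
#' @rdname transcript-accessors
#' @export
txStrand <- function(t) t@strand
#' @rdname transcript-accessors
#' @export
exonTable <- function(t) data.frame(start = t@exonStarts, end = t@exonEnds)

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel %s (gene %s) %s:%s exons=%d spliced=%dnt CDS=[%d,%d)\n",
              object@transcriptId, object@geneId, object@chrom, object@strand,
              length(object@exonStarts), splicedLength(object),
              object@cdsStartG, object@cdsEndG))
})

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneId,chrom Character scalars.
#' @param strand `"+"` or `"-"`.
#' @param exonStarts,exonEnds Integer vectors (0-based half-open, ascending).
#' @param cdsStartG,cdsEndG CDS genomic span including the stop codon
#'   (0-based half-open).
#' @return A validated `TranscriptModel`.
#' @export
TranscriptModel <- function(transcriptId, geneId, chrom, strand,
                            exonStarts, exonEnds, cdsStartG, cdsEndG) {
  new("TranscriptModel", transcriptId = as.character(transcriptId),
      geneId = as.character(geneId), chrom = as.character(chrom),
      strand = strand, exonStarts = as.integer(exonStarts),
      exonEnds = as.integer(exonEnds), cdsStartG = as.integer(cdsStartG),
      cdsEndG = as.integer(cdsEndG))
}

#' OrfRecord: an ORF as genomic blocks with class and stop status
#'
#' @slot orfId,transcriptId,chrom,strand,startCodon,orfClass character.
#' @slot blockStarts,blockEnds integer, 0-based half-open ascending genomic
#'   blocks (exonic pieces of the ORF).
#' @slot stopFound logical; `FALSE` when the transcript ends before an
#'   in-frame stop codon.
#' @slot tisTpos,stopTpos integer transcript coordinates of the first base of
#'   the start codon and of the stop codon (`NA` when `stopFound` is `FALSE`).
#' @slot tisGpos integer genomic coordinate of the first base (transcript
#'   orientation) of the start codon.
#' @export
setClass("OrfRecord", representation(
  orfId = "character", transcriptId = "character", chrom = "character",
  strand = "character", blockStarts = "integer", blockEnds = "integer",
  startCodon = "character", stopFound = "logical", orfClass = "character",
  tisTpos = "integer", stopTpos = "integer", tisGpos = "integer"
))

setValidity("OrfRecord", function(object) {
  msg <- character()
  if (length(object@blockStarts) != length(object@blockEnds) ||
      !length(object@blockStarts))
    msg <- c(msg, "blocks must be non-empty, equal-length vectors")
  else if (any(object@blockEnds <= object@blockStarts))
    msg <- c(msg, "each block must satisfy start < end")
  if (!object@startCodon %in% nearCognateCodons())
    msg <- c(msg, "startCodon must be ATG or a near-cognate codon")
  if (!object@orfClass %in% orfClasses())
    msg <- c(msg, "unknown orfClass")
  len <- sum(object@blockEnds - object@blockStarts)
  if (isTRUE(object@stopFound) && len %% 3L != 0L)
    msg <- c(msg, "ORF length must be divisible by 3 when a stop was found")
  if (length(msg)) msg else TRUE
})

#' @describeIn OrfRecord spliced ORF length in nucleotides
#' @param orf An `OrfRecord`.
#' @export
orfLength <- function(orf) sum(orf@blockEnds - orf@blockStarts)

#' Accessors for OrfRecord
#' @param orf An `OrfRecord`.
#' @return The corresponding slot value.
#' @name orf-accessors
NULL

#' @rdname orf-accessors
#' @export
orfId <- function(orf) orf@orfId
#' @rdname orf-accessors
#' @export
orfClass <- function(orf) orf@orfClass
#' @rdname orf-accessors
#' @export
startCodon <- function(orf) orf@startCodon
#' @rdname orf-accessors
#' @export
stopFound <- function(orf) orf@stopFound
#' @rdname orf-accessors
#' @export
orfBlocks <- function(orf) data.frame(start = orf@blockStarts,
                                      end = orf@blockEnds)

setMethod("show", "OrfRecord", function(object) {
  cat(sprintf("OrfRecord %s [%s] %s:%s %s blocks=%d len=%dnt stop=%s\n",
              object@orfId, object@orfClass, object@chrom, object@strand,
              object@startCodon, length(object@blockStarts),
              orfLength(object),
              if (object@stopFound) "found" else "none"))
})

#' KozakPWM: a position frequency table with the codon positions masked
#'
#' Offsets are relative to the first base of the start codon; the codon
#' offsets 0, 1, 2 are never scored, so the score reflects only the
#' surrounding context of a candidate start codon, never the codon itself.
#'
#' @slot offsets integer vector of window offsets (default -6..+5).
#' @slot freqs numeric matrix, one row per offset, columns A, C, G, T; each
#'   row sums to 1 and is strictly positive (pseudocount enforced at load).
#' @export
setClass("KozakPWM", representation(offsets = "integer", freqs = "matrix"))

setValidity("KozakPWM", function(object) {
  msg <- character()
  if (!identical(colnames(object@freqs), c("A", "C", "G", "T")))
    msg <- c(msg, "freqs columns must be A, C, G, T")
  if (nrow(object@freqs) != length(object@offsets))
    msg <- c(msg, "one frequency row per offset required")
  if (any(object@freqs <= 0))
    msg <- c(msg, "all frequencies must be > 0 (pseudocount at load)")
  if (any(abs(rowSums(object@freqs) - 1) > 1e-9))
    msg <- c(msg, "each offset's frequencies must sum to 1")
  if (anyDuplicated(object@offsets))
    msg <- c(msg, "offsets must be unique")
  if (length(msg)) msg else TRUE
})

#' @describeIn KozakPWM offsets that contribute to the score (codon masked)
#' @param pwm A `KozakPWM`.
#' @export
scoredOffsets <- function(pwm) setdiff(pwm@offsets, 0:2)

setMethod("show", "KozakPWM", function(object) {
  cat(sprintf("KozakPWM: offsets %d..%d (%d scored, codon positions masked)\n",
              min(object@offsets), max(object@offsets),
              length(scoredOffsets(object))))
})

#' SignalTrack: sparse per-position read counts
#'
#' Wraps a keyed [data.table::data.table] with columns `chrom`, `strand`
#' (`"+"`, `"-"` or `"*"` for unstranded), `pos` (0-based) and `count`.
#'
#' @slot data a `data.table` keyed by chrom, strand, pos.
#' @export
setClass("SignalTrack", representation(data = "ANY"))

setValidity("SignalTrack", function(object) {
  d <- object@data
  if (!all(c("chrom", "strand", "pos", "count") %in% names(d)))
    return("data must have columns chrom, strand, pos, count")
  if (nrow(d) && any(d$count < 0)) return("counts must be >= 0")
  TRUE
})

setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack: %d covered positions on %d contig(s)\n",
              nrow(object@data), length(unique(object@data$chrom))))
})

#' MergedFeature: the sequence scanned for a new stop after an edit
#'
#' Concatenation of the uORF exonic sequence, the exonic transcript sequence
#' between the uORF stop codon and the main start codon, and the main CDS --
#' equivalently the spliced transcript substring from the uORF TIS to the end
#' of the main stop codon, with a per-base genomic coordinate map.
#'
#' @slot sequence character scalar (transcript orientation).
#' @slot gcoords integer vector; genomic coordinate of every base.
#' @slot cdsStartIdx,cdsEndIdx 0-based indices of the main-CDS start codon
#'   first base and one past the main stop codon within `sequence`.
#' @slot uorfStopIdx 0-based index of the original uORF stop codon first base,
#'   or `NA` when the uORF has no stop before the transcript/feature end.
#' @slot orfId,transcriptId,chrom,strand provenance.
#' @slot tisTpos transcript coordinate of the uORF TIS (feature index 0).
#' @export
setClass("MergedFeature", representation(
  sequence = "character", gcoords = "integer",
  cdsStartIdx = "integer", cdsEndIdx = "integer", uorfStopIdx = "integer",
  orfId = "character", transcriptId = "character", chrom = "character",
  strand = "character", tisTpos = "integer"
))

setValidity("MergedFeature", function(object) {
  msg <- character()
  n <- nchar(object@sequence)
  if (length(object@gcoords) != n)
    msg <- c(msg, "gcoords must map every base of sequence")
  if (length(object@gcoords) > 1L && object@strand == "+" &&
      is.unsorted(object@gcoords, strictly = TRUE))
    msg <- c(msg, "gcoords must be strictly increasing on '+'")
  if (length(object@gcoords) > 1L && object@strand == "-" &&
      is.unsorted(rev(object@gcoords), strictly = TRUE))
    msg <- c(msg, "gcoords must be strictly decreasing on '-'")
  # cdsStartIdx may be negative for internal (downstream-of-start) TISs
  if (object@cdsStartIdx + 3L > n)
    msg <- c(msg, "cdsStartIdx out of range")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MergedFeature", function(object) {
  cat(sprintf("MergedFeature %s: %dnt, CDS start at index %d, uORF stop %s\n",
              object@orfId, nchar(object@sequence), object@cdsStartIdx,
              ifelse(is.na(object@uorfStopIdx), "none (read-through)",
                     as.character(object@uorfStopIdx))))
})
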