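# BED12 dialect for ORF records: name = orf_id|start_codon|orf_class, with
# orf_id = <transcript_id>:<tisGpos>:<codon>; thickStart/thickEnd delimit the
# TIS codon; blocks are the exonic pieces of the ORF. Coordinates follow the
# BED 0-based half-open convention.

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges IRangesList
NULL

.orfToGRanges <- function(orfs, itemRgb = NULL) {
  spanStart <- vapply(orfs, function(o) min(o@blockStarts), integer(1))
  spanEnd <- vapply(orfs, function(o) max(o@blockEnds), integer(1))
  chrom <- vapply(orfs, function(o) o@chrom, character(1))
  strand <- vapply(orfs, function(o) o@strand, character(1))
  name <- vapply(orfs, function(o)
    paste(o@orfId, o@startCodon, o@orfClass, sep = "|"), character(1))
  blocks <- IRanges::IRangesList(lapply(seq_along(orfs), function(i) {
    o <- orfs[[i]]
    IRanges::IRanges(start = o@blockStarts - spanStart[i] + 1L,
                     end = o@blockEnds - spanStart[i])
  }))
  thick <- do.call(rbind, lapply(seq_along(orfs), function(i) {
    o <- orfs[[i]]
    # TIS codon genomic span (display metadata; clipped to the ORF span if
    # the codon crosses a junction)
    g <- if (o@strand == "+") c(o@tisGpos, o@tisGpos + 3L) else
      c(o@tisGpos - 2L, o@tisGpos + 1L)
    c(max(g[1L], spanStart[i]), min(g[2L], spanEnd[i]))
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = spanStart + 1L, end = spanEnd),
    strand = strand)
  gr$name <- name
  gr$score <- 0L
  gr$thick <- IRanges::IRanges(start = thick[, 1L] + 1L, end = thick[, 2L])
  if (!is.null(itemRgb)) gr$itemRgb <- itemRgb
  gr$blocks <- blocks
  gr
}

#' Write ORF records to BED12
#'
#' @param orfs List of [OrfRecord].
#' @param path Output file.
#' @param itemRgb Optional vector of colors (e.g. `"#000000"`) written to the
#'   itemRgb column.
#' @return `path`, invisibly.
#' @export
writeOrfBed <- function(orfs, path, itemRgb = NULL) {
  if (!length(orfs)) { writeLines(character(0), path); return(invisible(path)) }
  gr <- .orfToGRanges(orfs, itemRgb = itemRgb %||% rep("#000000", length(orfs)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read ORF records from BED12
#'
#' Inverse of [writeOrfBed()]; transcript association and class are recovered
#' from the name field, transcript-space anchors by re-projecting the blocks
#' through the supplied transcript models.
#'
#' @param path BED12 file in the [writeOrfBed()] dialect.
#' @param transcripts Named list of [TranscriptModel] (from
#'   [loadTranscripts()]).
#' @param genome Genome from [loadGenome()] (used to re-derive stop status).
#' @return List of [OrfRecord].
#' @export
readOrfBed <- function(path, transcripts, genome) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- vector("list", length(gr))
  seqCache <- new.env(parent = emptyenv())
  for (i in seq_along(gr)) {
    nm <- strsplit(gr$name[i], "|", fixed = TRUE)[[1L]]
    if (length(nm) < 3L) stop("BED name not in orf_id|codon|class dialect: ", gr$name[i])
    idParts <- strsplit(nm[1L], ":", fixed = TRUE)[[1L]]
    tid <- paste(idParts[seq_len(length(idParts) - 2L)], collapse = ":")
    tisGpos <- as.integer(idParts[length(idParts) - 1L])
    t <- transcripts[[tid]]
    if (is.null(t)) stop("BED references unknown transcript: ", tid)
    if (is.null(seqCache[[tid]]))
      assign(tid, splicedSequence(t, genome), envir = seqCache)
    out[[i]] <- buildOrf(list(gpos = tisGpos, codon = nm[2L]), t, genome,
                         splicedSeq = get(tid, envir = seqCache))
    if (out[[i]]@orfClass != nm[3L])
      warning("reclassified ", nm[1L], ": BED said ", nm[3L], ", computed ",
              out[[i]]@orfClass)
  }
  out
}
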