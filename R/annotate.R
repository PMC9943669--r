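# The annotation orchestrator: VCF + uORF BED + GTF + FASTA in; annotated
# VCF, TSV table and affected-uORF BED pairs out.

.TSV_COLUMNS <- c("chrom", "pos", "ref", "alt", "orf_id", "transcript_id",
                  "gene_id", "start_codon", "orf_class", "location",
                  "consequence", "impact", "new_stop_gpos", "read_through",
                  "junction_spanning")

.LENGTH_AFFECTING <- c("stop_gained", "stop_lost", "frameshift")

#' Annotate one variant against one uORF
#'
#' @param v One normalized variant (one-row data.frame).
#' @param orf An [OrfRecord].
#' @param t Its [TranscriptModel].
#' @param mf Its [MergedFeature] (precomputed).
#' @return One-row data.frame in the annotator's TSV column order.
#' @export
annotateVariantOrf <- function(v, orf, t, mf) {
  loc <- locateVariant(v, t)
  row <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                    id = v$id %||% NA_character_,
                    orig_index = v$orig_index %||% NA_integer_,
                    orf_id = orf@orfId, transcript_id = t@transcriptId,
                    gene_id = t@geneId, start_codon = orf@startCodon,
                    orf_class = orf@orfClass, location = loc,
                    consequence = NA_character_,
                    impact = "not_applicable",
                    new_stop_gpos = NA_integer_, read_through = FALSE,
                    junction_spanning = FALSE, stringsAsFactors = FALSE)
  if (loc == "deep_intronic") return(row)
  if (loc == "splice_site") {
    row$consequence <- "splice_site"
    edit <- tryCatch(applyVariantToFeature(mf, v), error = function(e) NULL)
    row$junction_spanning <- !is.null(edit) && edit$junctionSpanning
    return(row)
  }
  edit <- applyVariantToFeature(mf, v)
  row$junction_spanning <- edit$junctionSpanning
  cons <- uorfConsequence(mf, v, edit = edit)
  row$consequence <- cons
  if (cons %in% .LENGTH_AFFECTING) {
    scan <- scanNewStop(mf, v)
    row$read_through <- scan$readThrough
    row$impact <- classifyImpact(orf, mf, scan)
    if (!scan$readThrough) {
      origIdx <- editedToOriginalIdx(scan$edit, scan$newStopIdx)
      row$new_stop_gpos <- mf@gcoords[origIdx + 1L]
    }
  }
  row
}

#' Annotate variants located in uORFs
#'
#' The full annotator pipeline: read the inputs, normalize the variants,
#' overlap them with the uORFs, classify each (variant x uORF x transcript)
#' triple, and write the annotated VCF, the TSV results table, and paired
#' BED files of affected uORFs (original in black, resulting ORF in red;
#' separately for ATG- and non-ATG-started uORFs).
#'
#' @param vcf,orfBed,gtf,fasta Input file paths (uORF BED in the
#'   [writeOrfBed()] dialect).
#' @param outPrefix Output path prefix; files `<prefix>.vcf`,
#'   `<prefix>.tsv`, `<prefix>.atg_uorfs.bed`, `<prefix>.non_atg_uorfs.bed`
#'   are written. `NULL` skips file output.
#' @param excludeMainCds Restrict output to variants outside the main CDS.
#' @param maxIndelLen Indel length cutoff for [normalizeVariants()].
#' @return (invisibly) list with `table` (TSV data.frame), `errors`,
#'   `dropped`, `summary` (class counts), and the output paths.
#' @export
annotateUorfVariants <- function(vcf, orfBed, gtf, fasta, outPrefix = NULL,
                                 excludeMainCds = FALSE, maxIndelLen = 50L) {
  genome <- loadGenome(fasta)
  transcripts <- loadTranscripts(gtf)
  orfs <- readOrfBed(orfBed, transcripts, genome)
  .checkContigs(genome, transcripts, orfs)
  raw <- readVariants(vcf)
  norm <- normalizeVariants(raw$variants, genome, maxIndelLen = maxIndelLen)
  variants <- norm$variants
  pairs <- overlapVariants(variants, orfs, transcripts,
                           excludeMainCds = excludeMainCds)
  seqCache <- list(); mfCache <- list()
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    v <- variants[pairs$variant_row[k], ]
    o <- orfs[[pairs$orf_index[k]]]
    t <- transcripts[[o@transcriptId]]
    if (is.null(seqCache[[t@transcriptId]]))
      seqCache[[t@transcriptId]] <- splicedSequence(t, genome)
    if (is.null(mfCache[[o@orfId]]))
      mfCache[[o@orfId]] <- buildMergedFeature(
        o, t, genome, splicedSeq = seqCache[[t@transcriptId]])
    rows[[k]] <- annotateVariantOrf(v, o, t, mfCache[[o@orfId]])
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(
      data.frame(matrix(ncol = length(.TSV_COLUMNS) + 2L, nrow = 0)),
      c(.TSV_COLUMNS[1:4], "id", "orig_index", .TSV_COLUMNS[-(1:4)]))
  res <- list(table = tab, errors = norm$errors, dropped = raw$dropped,
              summary = summarizeClasses(tab))
  if (!is.null(outPrefix)) {
    res$paths <- .writeAnnotatorOutputs(tab, vcf, orfs, transcripts, genome,
                                        mfCache, outPrefix)
  }
  invisible(res)
}

.checkContigs <- function(genome, transcripts, orfs) {
  tc <- unique(vapply(transcripts, function(t) t@chrom, character(1)))
  oc <- unique(vapply(orfs, function(o) o@chrom, character(1)))
  bad <- setdiff(c(tc, oc), names(genome))
  if (length(bad))
    stop("contig name mismatch between inputs; missing from FASTA: ",
         paste(unique(bad), collapse = ", "))
}

# ---- outputs ---------------------------------------------------------------

.writeAnnotatorOutputs <- function(tab, vcfIn, orfs, transcripts, genome,
                                   mfCache, outPrefix) {
  paths <- list(vcf = paste0(outPrefix, ".vcf"),
                tsv = paste0(outPrefix, ".tsv"),
                atgBed = paste0(outPrefix, ".atg_uorfs.bed"),
                nonAtgBed = paste0(outPrefix, ".non_atg_uorfs.bed"))
  utils::write.table(tab[, .TSV_COLUMNS], paths$tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .writeAnnotatedVcf(tab, vcfIn, paths$vcf)
  .writeAffectedBeds(tab, orfs, transcripts, genome, mfCache,
                     paths$atgBed, paths$nonAtgBed)
  paths
}

# INFO tag UORF=orf_id|codon|orf_class|consequence|impact, one entry per
# annotation row, '&' joining fields-internal lists, ',' joining entries
.writeAnnotatedVcf <- function(tab, vcfIn, vcfOut) {
  vcf <- VariantAnnotation::readVcf(vcfIn, genome = "fixture")
  rr <- SummarizedExperiment::rowRanges(vcf)
  key <- paste(as.character(GenomicRanges::seqnames(rr)),
               GenomicRanges::start(rr))
  tags <- rep(NA_character_, length(rr))
  if (nrow(tab)) {
    # tie each annotation back to its input record (indel normalization may
    # have shifted pos); fall back to positional matching when the original
    # record index is unavailable
    recId <- if (all(!is.na(tab$orig_index))) tab$orig_index else
      match(paste(tab$chrom, tab$pos), key)
    ann <- stats::aggregate(
      tag ~ rec, data = data.frame(
        rec = recId,
        tag = paste(tab$orf_id, tab$start_codon, tab$orf_class,
                    tab$consequence, tab$impact, sep = "|"),
        stringsAsFactors = FALSE),
      FUN = function(x) paste(x, collapse = ","))
    tags[ann$rec] <- ann$tag
  }
  hdr <- VariantAnnotation::header(vcf)
  newInfo <- S4Vectors::DataFrame(
    Number = ".", Type = "String",
    Description = "uORF annotation: orf_id|start_codon|orf_class|consequence|impact",
    row.names = "UORF")
  VariantAnnotation::info(hdr) <-
    rbind(VariantAnnotation::info(hdr), newInfo)
  VariantAnnotation::header(vcf) <- hdr
  VariantAnnotation::info(vcf)$UORF <- tags
  VariantAnnotation::writeVcf(vcf, vcfOut)
  invisible(vcfOut)
}

# Paired records per length-affecting annotation: the original uORF (black)
# and the resulting ORF after the variant (red), split by start codon type.
.writeAffectedBeds <- function(tab, orfs, transcripts, genome, mfCache,
                               atgPath, nonAtgPath) {
  orfIds <- vapply(orfs, orfId, character(1))
  sel <- which(tab$consequence %in% .LENGTH_AFFECTING)
  recs <- list(); rgb <- character(0); isAtg <- logical(0)
  for (k in sel) {
    o <- orfs[[match(tab$orf_id[k], orfIds)]]
    t <- transcripts[[o@transcriptId]]
    mf <- mfCache[[o@orfId]]
    v <- tab[k, c("chrom", "pos", "ref", "alt")]
    scan <- scanNewStop(mf, v)
    endEdited <- if (scan$readThrough) nchar(scan$editedSeq) else
      scan$newStopIdx + 3L
    endOrig <- editedToOriginalIdx(scan$edit, endEdited - 1L) + 1L
    newEndT <- mf@tisTpos + endOrig
    blk <- transcriptIntervalToBlocks(t, mf@tisTpos, newEndT)
    resulting <- new("OrfRecord",
                     orfId = paste0(o@orfId, ":", tab$pos[k], tab$ref[k], ">",
                                    tab$alt[k]),
                     transcriptId = o@transcriptId, chrom = o@chrom,
                     strand = o@strand,
                     blockStarts = as.integer(blk$start),
                     blockEnds = as.integer(blk$end),
                     # display record: frame/stop invariants are asserted on
                     # the edited sequence, not on these projected blocks
                     startCodon = o@startCodon, stopFound = FALSE,
                     orfClass = o@orfClass, tisTpos = o@tisTpos,
                     stopTpos = NA_integer_, tisGpos = o@tisGpos)
    recs <- c(recs, list(o, resulting))
    rgb <- c(rgb, "#000000", "#FF0000")
    isAtg <- c(isAtg, rep(o@startCodon == "ATG", 2L))
  }
  writeBedSubset <- function(keep, path) {
    if (any(keep)) writeOrfBed(recs[keep], path, itemRgb = rgb[keep])
    else writeLines(character(0), path)
  }
  writeBedSubset(isAtg, atgPath)
  writeBedSubset(!isAtg, nonAtgPath)
  invisible(c(atgPath, nonAtgPath))
}

# ---- summaries -------------------------------------------------------------

#' Summarize annotation classes
#'
#' Counts and proportions per consequence x impact x start-codon type
#' (ATG/non-ATG), plus the three probable loss-of-function subgroups of
#' length-affecting variants: those leaving the reference CDS unaffected,
#' those producing an N-terminal CDS extension, and those creating an
#' out-of-frame overlap with the downstream CDS.
#'
#' @param tab Annotation data.frame from [annotateUorfVariants()].
#' @return List with `byClass` (counts + proportions) and `pLoF` data.frames.
#' @export
summarizeClasses <- function(tab) {
  if (!nrow(tab)) {
    empty <- data.frame(consequence = character(0), impact = character(0),
                        start_type = character(0), n = integer(0),
                        proportion = numeric(0))
    return(list(byClass = empty, pLoF = empty[, c("impact", "start_type", "n",
                                                  "proportion")]))
  }
  startType <- ifelse(tab$start_codon == "ATG", "ATG", "non-ATG")
  counted <- tab[!is.na(tab$consequence), , drop = FALSE]
  startType <- startType[!is.na(tab$consequence)]
  byClass <- as.data.frame(table(consequence = counted$consequence,
                                 impact = counted$impact,
                                 start_type = startType),
                           stringsAsFactors = FALSE)
  names(byClass)[names(byClass) == "Freq"] <- "n"
  byClass <- byClass[byClass$n > 0L, , drop = FALSE]
  byClass$proportion <- byClass$n / sum(byClass$n)
  rownames(byClass) <- NULL
  lof <- counted[counted$consequence %in% .LENGTH_AFFECTING, , drop = FALSE]
  lofType <- ifelse(lof$start_codon == "ATG", "ATG", "non-ATG")
  pLoF <- as.data.frame(table(impact = lof$impact, start_type = lofType),
                        stringsAsFactors = FALSE)
  names(pLoF)[names(pLoF) == "Freq"] <- "n"
  pLoF <- pLoF[pLoF$n > 0L, , drop = FALSE]
  pLoF$proportion <- if (nrow(pLoF)) pLoF$n / sum(pLoF$n) else numeric(0)
  rownames(pLoF) <- NULL
  list(byClass = byClass, pLoF = pLoF)
}

#' Compare two class summaries with a contingency test
#'
#' Fisher's exact test (with simulated p-values for large tables) on the
#' 2 x k table of class counts from two annotation runs.
#'
#' @param s1,s2 `byClass` data.frames from [summarizeClasses()].
#' @param by Column to tabulate (`"consequence"` or `"impact"`).
#' @return p-value in `[0, 1]`.
#' @export
compareSummaries <- function(s1, s2, by = "consequence") {
  lv <- sort(union(s1[[by]], s2[[by]]))
  c1 <- vapply(lv, function(l) sum(s1$n[s1[[by]] == l]), numeric(1))
  c2 <- vapply(lv, function(l) sum(s2$n[s2[[by]] == l]), numeric(1))
  m <- rbind(c1, c2)
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2L) return(1)
  stats::fisher.test(m, simulate.p.value = ncol(m) > 5L, B = 2000)$p.value
}
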