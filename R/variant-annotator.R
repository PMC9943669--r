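# Variant-level logic of the uORF annotator: VCF normalization, overlap,
# positional location, uORF-level consequence, merged-feature construction,
# first-stop scan and the four-way main-CDS impact classification.

#' Read variant records from a VCF file
#'
#' Multiallelic records are split into one record per ALT. Symbolic and
#' breakend ALTs are dropped with a reason.
#'
#' @param path VCF file (4.x, plain text or bgzipped).
#' @return List with `variants` (data.frame `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`, `orig_index`) and `dropped` (data.frame with `reason`).
#' @export
readVariants <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "fixture")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  ids <- names(rr) %||% rep(".", length(rr))
  rows <- list(); drops <- list()
  for (i in seq_along(rr)) {
    alts <- as.character(altL[[i]])
    for (a in alts) {
      if (!grepl("^[ACGTNacgtn]+$", a)) {
        drops[[length(drops) + 1L]] <- data.frame(
          chrom = as.character(GenomicRanges::seqnames(rr)[i]),
          pos = GenomicRanges::start(rr)[i], id = ids[i], ref = ref[i],
          alt = a, reason = "symbolic_alt", stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(rr)[i]),
        pos = GenomicRanges::start(rr)[i], id = ids[i], ref = toupper(ref[i]),
        alt = toupper(a), orig_index = i, stringsAsFactors = FALSE)
    }
  }
  list(variants = if (length(rows)) do.call(rbind, rows) else
         data.frame(chrom = character(0), pos = integer(0), id = character(0),
                    ref = character(0), alt = character(0),
                    orig_index = integer(0)),
       dropped = if (length(drops)) do.call(rbind, drops) else NULL)
}

#' Normalize variant records against the genome
#'
#' Trims redundant shared suffix/prefix bases (keeping the conventional
#' anchor base for indels), left-aligns indels within homopolymer or repeat
#' context, verifies REF against the genome (mismatching records become
#' per-record error entries and are skipped), and drops indels longer than
#' `maxIndelLen` with reason `large_indel`.
#'
#' @param variants data.frame from [readVariants()] (or with the same
#'   columns).
#' @param genome Genome from [loadGenome()].
#' @param maxIndelLen Maximum net inserted/deleted length (default 50).
#' @return List with `variants` (normalized data.frame) and `errors`
#'   (data.frame with a `reason` column; `NULL` when empty).
#' @export
normalizeVariants <- function(variants, genome, maxIndelLen = 50L) {
  out <- list(); errs <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    chrom <- v$chrom
    if (!chrom %in% names(genome)) {
      errs[[length(errs) + 1L]] <- cbind(v, reason = "unknown_contig")
      next
    }
    clen <- length(genome[[chrom]])
    gref <- contigSequence(genome, chrom, v$pos - 1L,
                           min(clen, v$pos - 1L + nchar(v$ref)))
    if (!identical(gref, v$ref)) {
      errs[[length(errs) + 1L]] <- cbind(v, reason = "ref_mismatch")
      next
    }
    ref <- v$ref; alt <- v$alt; pos <- v$pos
    # trim shared suffix (keep at least one base each)
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    # trim shared prefix (keep anchor when an allele would empty)
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
    }
    # left-align pure indels: an anchored allele (anchor + varying tail) can
    # shift one base left exactly when the tail's last base equals the
    # anchor, rotating the tail
    isDel <- nchar(ref) > 1L && nchar(alt) == 1L &&
      substr(ref, 1L, 1L) == alt
    isIns <- nchar(alt) > 1L && nchar(ref) == 1L &&
      substr(alt, 1L, 1L) == ref
    if (isDel || isIns) {
      repeat {
        if (pos <= 1L) break
        long <- if (isDel) ref else alt
        anchor <- substr(long, 1L, 1L)
        tail <- substr(long, 2L, nchar(long))
        if (substr(tail, nchar(tail), nchar(tail)) != anchor) break
        prev <- contigSequence(genome, chrom, pos - 2L, pos - 1L)
        long <- paste0(prev, anchor, substr(tail, 1L, nchar(tail) - 1L))
        pos <- pos - 1L
        if (isDel) { ref <- long; alt <- prev } else { alt <- long; ref <- prev }
      }
    }
    if (abs(nchar(ref) - nchar(alt)) > maxIndelLen) {
      errs[[length(errs) + 1L]] <- cbind(v, reason = "large_indel")
      next
    }
    v$ref <- ref; v$alt <- alt; v$pos <- pos
    out[[length(out) + 1L]] <- v
  }
  list(variants = if (length(out)) do.call(rbind, out) else variants[0, ],
       errors = if (length(errs)) do.call(rbind, errs) else NULL)
}

# 0-based half-open genomic interval of a variant's REF allele
.variantSpan <- function(v) c(v$pos - 1L, v$pos - 1L + nchar(v$ref))

#' Overlap variants with uORFs
#'
#' Emits one candidate triple per uORF whose genomic span (the interval from
#' the first to the last block, introns included -- intronic positions are
#' later separated into splice-site and deep-intronic by [locateVariant()])
#' intersects the variant. Variants hitting no uORF produce nothing: only
#' variants that fall within uORF boundaries are reported.
#'
#' @param variants Normalized data.frame from [normalizeVariants()].
#' @param orfs List of [OrfRecord].
#' @param transcripts Named list of [TranscriptModel].
#' @param excludeMainCds Drop variants whose span intersects the main-CDS
#'   genomic interval of the host transcript.
#' @return data.frame with `variant_row` and `orf_index` columns.
#' @export
overlapVariants <- function(variants, orfs, transcripts,
                            excludeMainCds = FALSE) {
  hits <- list()
  for (j in seq_along(orfs)) {
    o <- orfs[[j]]
    t <- transcripts[[o@transcriptId]]
    lo <- min(o@blockStarts); hi <- max(o@blockEnds)
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (v$chrom != o@chrom) next
      sp <- .variantSpan(v)
      if (!(sp[1L] < hi && sp[2L] > lo)) next
      if (excludeMainCds && !is.null(t) &&
          sp[1L] < t@cdsEndG && sp[2L] > t@cdsStartG) next
      hits[[length(hits) + 1L]] <- data.frame(variant_row = i, orf_index = j)
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(variant_row = integer(0), orf_index = integer(0))
}

#' Locate a variant relative to the exon structure of a uORF
#'
#' `exonic` when every affected base is exonic; `splice_site` when any
#' affected base lies within the `spliceWindow` intronic nt flanking an exon
#' of the uORF-containing transcript; `deep_intronic` otherwise (counted but
#' excluded from consequence analysis).
#'
#' @param v One normalized variant (one-row data.frame or list).
#' @param t The host [TranscriptModel].
#' @param spliceWindow Intronic window size (nt).
#' @return One of `"exonic"`, `"splice_site"`, `"deep_intronic"`.
#' @export
locateVariant <- function(v, t, spliceWindow = 2L) {
  sp <- .variantSpan(v)
  g <- sp[1L]:(sp[2L] - 1L)
  exonic <- !is.na(genomicToTranscript(t, g))
  if (all(exonic)) return("exonic")
  s <- t@exonStarts; e <- t@exonEnds
  nearEdge <- vapply(g[!exonic], function(p) {
    any(p >= e[-length(e)] & p < e[-length(e)] + spliceWindow) ||
      any(p < s[-1L] & p >= s[-1L] - spliceWindow)
  }, logical(1))
  if (any(nearEdge)) "splice_site" else "deep_intronic"
}

#' Build the merged feature of a uORF
#'
#' The spliced transcript substring from the uORF TIS through the end of the
#' main stop codon: for non-overlapping uORFs this equals the concatenation
#' of the uORF exonic sequence, the exonic gap to the main start codon, and
#' the main CDS; for uORFs already overlapping the CDS the substring counts
#' nothing twice.
#'
#' @param orf An [OrfRecord].
#' @param t Its [TranscriptModel].
#' @param genome Genome from [loadGenome()].
#' @param splicedSeq Optional precomputed spliced sequence.
#' @return A [MergedFeature].
#' @export
buildMergedFeature <- function(orf, t, genome, splicedSeq = NULL) {
  S <- if (is.null(splicedSeq)) splicedSequence(t, genome) else splicedSeq
  anchors <- cdsTranscriptAnchors(t)
  tisT <- orf@tisTpos
  if (tisT >= anchors[2L]) stop("TIS not upstream of the main stop codon")
  seqF <- substr(S, tisT + 1L, anchors[2L])
  idx <- tisT:(anchors[2L] - 1L)
  new("MergedFeature",
      sequence = seqF,
      gcoords = transcriptToGenomic(t, idx),
      cdsStartIdx = anchors[1L] - tisT,
      cdsEndIdx = anchors[2L] - tisT,
      uorfStopIdx = if (orf@stopFound) orf@stopTpos - tisT else NA_integer_,
      orfId = orf@orfId, transcriptId = t@transcriptId, chrom = t@chrom,
      strand = t@strand, tisTpos = tisT)
}

#' Apply a variant to a merged feature
#'
#' The REF bases are located through the per-base coordinate map and replaced
#' by ALT (reverse-complemented for minus-strand transcripts). Variants whose
#' REF spans a splice junction are applied to their exonic bases only and
#' flagged `junction_spanning`.
#'
#' @param mf A [MergedFeature].
#' @param v One normalized variant.
#' @return List: `sequence` (edited), `editStart` (0-based feature index),
#'   `nRefExonic`, `altLen`, `net` (length change), `junctionSpanning`.
#' @export
applyVariantToFeature <- function(mf, v) {
  ref <- v$ref; alt <- v$alt; pos <- v$pos
  # an indel anchor base lying outside the feature (e.g. the base upstream
  # of the uORF TIS) carries no edit: trim it while REF and ALT share it
  while (nchar(ref) > 1L && nchar(alt) >= 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
         is.na(match(pos - 1L, mf@gcoords))) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  n <- nchar(ref)
  g <- (pos - 1L):(pos - 2L + n)
  idx <- match(g, mf@gcoords) - 1L            # 0-based feature indices
  ex <- !is.na(idx)
  if (!any(ex)) stop("variant does not map into the merged feature")
  altF <- if (mf@strand == "+") alt else .revcompChr(alt)
  i1 <- min(idx[ex]); i2 <- max(idx[ex])
  seqn <- paste0(substr(mf@sequence, 1L, i1),
                 altF,
                 substr(mf@sequence, i2 + 2L, nchar(mf@sequence)))
  # effective edit as a half-open range of *original* feature indices that
  # are substituted or deleted (empty at the insertion point for pure
  # insertions): the VCF anchor base, which the edit preserves, is excluded
  # -- it sits 5' of the change on '+' but 3' of it on '-'
  anchored <- nchar(ref) != nchar(alt) &&
    substr(ref, 1L, 1L) == substr(alt, 1L, 1L) && nchar(alt) >= 1L
  if (!anchored) {
    effStart <- i1; effEnd <- i2 + 1L
  } else if (nchar(ref) > nchar(alt)) {        # deletion
    if (mf@strand == "+") { effStart <- i1 + 1L; effEnd <- i2 + 1L }
    else { effStart <- i1; effEnd <- i2 }
  } else {                                     # insertion
    effStart <- if (mf@strand == "+") i1 + 1L else i1
    effEnd <- effStart
  }
  list(sequence = seqn, editStart = i1, nRefExonic = i2 - i1 + 1L,
       altLen = nchar(altF), net = nchar(altF) - (i2 - i1 + 1L),
       effStart = effStart, effEnd = effEnd,
       junctionSpanning = any(!ex))
}

# first in-frame stop codon (frame 0) in a sequence; 0-based index or NA
.firstStopIdx <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(NA_integer_)
  starts <- seq.int(1L, n - 2L, by = 3L)
  cod <- substring(seq, starts, starts + 2L)
  w <- which(cod %in% .STOPS)
  if (length(w)) as.integer(starts[w[1L]] - 1L) else NA_integer_
}

#' Scan the edited merged feature for the first stop codon
#'
#' Codons are read from feature index 0 in the (possibly shifted) uORF frame
#' through the entire merged feature.
#'
#' @param mf A [MergedFeature].
#' @param v One normalized variant mapping into `mf`.
#' @return List: `newStopIdx` (0-based index in the *edited* sequence, `NA`
#'   when no stop precedes the feature end), `editedSeq`, `edit` (the
#'   [applyVariantToFeature()] result), `readThrough`.
#' @export
scanNewStop <- function(mf, v) {
  edit <- applyVariantToFeature(mf, v)
  idxNew <- .firstStopIdx(edit$sequence)
  list(newStopIdx = idxNew, editedSeq = edit$sequence, edit = edit,
       readThrough = is.na(idxNew))
}

#' uORF-level consequence of an exonic variant
#'
#' Length-preserving edits are classified codon-wise (synonymous, missense,
#' stop_gained, stop_lost); indels as frameshift (net length not divisible by
#' 3) or inframe_indel unless they create or destroy the uORF stop; any edit
#' changing the start codon is start_lost. Splice-site location
#' short-circuits to `splice_site` before this function is consulted.
#'
#' @param mf The uORF's [MergedFeature].
#' @param v One normalized exonic variant.
#' @param edit Optional precomputed [applyVariantToFeature()] result.
#' @return One of [uorfConsequences()] (never `"splice_site"` here).
#' @export
uorfConsequence <- function(mf, v, edit = NULL) {
  if (is.null(edit)) edit <- applyVariantToFeature(mf, v)
  i1 <- edit$editStart; nref <- edit$nRefExonic; net <- edit$net
  # start codon disruption: content comparison (covers substitutions,
  # deletions and insertions shifting bases into the codon)
  if (substr(edit$sequence, 1L, 3L) != substr(mf@sequence, 1L, 3L))
    return("start_lost")
  uEndOld <- if (!is.na(mf@uorfStopIdx)) mf@uorfStopIdx + 3L else
    nchar(mf@sequence)
  if (net %% 3L != 0L) return("frameshift")
  if (net == 0L) {
    # codon-wise comparison over the affected codon range
    c1 <- (i1 %/% 3L) * 3L
    c2 <- (((i1 + nref - 1L) %/% 3L) + 1L) * 3L
    c2 <- min(c2, (nchar(mf@sequence) %/% 3L) * 3L)
    if (c1 >= c2) return("synonymous")
    oldAA <- translateDna(substr(mf@sequence, c1 + 1L, c2))
    newAA <- translateDna(substr(edit$sequence, c1 + 1L, c2))
    codIdx <- seq_len(nchar(oldAA))
    oldStop <- substring(oldAA, codIdx, codIdx) == "*"
    newStop <- substring(newAA, codIdx, codIdx) == "*"
    if (any(oldStop & !newStop)) return("stop_lost")
    if (any(newStop & !oldStop)) return("stop_gained")
    if (oldAA == newAA) return("synonymous")
    return("missense")
  }
  # in-frame indel: did the uORF's first stop move?
  oldFirst <- .firstStopIdx(mf@sequence)
  newFirst <- .firstStopIdx(edit$sequence)
  expected <- if (!is.na(oldFirst) && edit$effStart < oldFirst + 3L)
    oldFirst + net else oldFirst
  if (is.na(oldFirst) && is.na(newFirst)) return("inframe_indel")
  if (is.na(oldFirst)) return("stop_gained")
  if (is.na(newFirst)) return("stop_lost")
  if (newFirst < expected) return("stop_gained")
  if (newFirst > expected) return("stop_lost")
  "inframe_indel"
}

#' Four-way main-CDS impact of a length-affecting variant
#'
#' Decision table on the edited merged feature: a new stop lying entirely
#' before the (shifted) main start leaves the CDS untouched
#' (`main_CDS_unaffected`) or removes a pre-existing overlap
#' (`overlap_removal`); an overlap that persists with an unchanged frame
#' relationship does not change the uORF/CDS geometry
#' (`main_CDS_unaffected`); otherwise, with no stop before the main start, a
#' reading frame congruent with the CDS yields a chimeric
#' `N-terminal_extension` and an incongruent frame a new
#' `out_of_frame_overlap` (including full read-through).
#'
#' @param orf The original [OrfRecord].
#' @param mf Its [MergedFeature].
#' @param scan Result of [scanNewStop()].
#' @return One of [mainCdsImpacts()] (never `"not_applicable"` here).
#' @export
classifyImpact <- function(orf, mf, scan) {
  edit <- scan$edit
  cdsIdx <- mf@cdsStartIdx
  # shift of the main-start index when the effective edit lies fully
  # upstream of it
  if (edit$effEnd <= cdsIdx)
    cdsIdx <- cdsIdx + edit$net
  originalOverlap <- orf@orfClass != "non_overlapping_uORF"
  stopBeforeCds <- !is.na(scan$newStopIdx) && scan$newStopIdx + 3L <= cdsIdx
  if (stopBeforeCds)
    return(if (originalOverlap) "overlap_removal" else "main_CDS_unaffected")
  origCong <- ((mf@cdsStartIdx %% 3L) + 3L) %% 3L
  newCong <- ((cdsIdx %% 3L) + 3L) %% 3L
  if (originalOverlap && newCong == origCong) return("main_CDS_unaffected")
  if (newCong == 0L) return("N-terminal_extension")
  "out_of_frame_overlap"
}

#' Map an index in the edited merged feature back to the original feature
#'
#' Positions inside the replaced segment map to the edit anchor.
#'
#' @param edit [applyVariantToFeature()] result.
#' @param idx 0-based index in the edited sequence.
#' @return 0-based index in the original feature sequence.
#' @export
editedToOriginalIdx <- function(edit, idx) {
  ifelse(idx < edit$editStart, idx,
         ifelse(idx >= edit$editStart + edit$altLen, idx - edit$net,
                edit$editStart))
}
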