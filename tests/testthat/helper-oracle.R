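# Independent brute-force oracle: applies a variant to the *genome*, rebuilds
# the transcript with shifted exon coordinates, re-extracts the spliced
# sequence with plain string ops, translates from the uORF TIS codon by
# codon, and derives the consequence and the four-way main-CDS impact from
# first-stop geometry. No package coordinate/feature code is used beyond
# plain slot access.

oracleRevcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]), collapse = "")
}

# 0-based index of the first stop codon read in frame 0, or NA
oracleFirstStop <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(NA_integer_)
  for (i in seq(1L, n - 2L, by = 3L)) {
    if (substr(seq, i, i + 2L) %in% c("TAA", "TAG", "TGA"))
      return(i - 1L)
  }
  NA_integer_
}

oracleAa <- function(seq) {
  gc <- Biostrings::GENETIC_CODE
  n <- (nchar(seq) %/% 3L) * 3L
  if (n == 0L) return("")
  st <- seq(1L, n - 2L, by = 3L)
  cod <- substring(seq, st, st + 2L)
  aa <- unname(gc[cod]); aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

oracleSpliced <- function(contigSeq, exonStarts, exonEnds, strand) {
  pieces <- mapply(function(s, e) substr(contigSeq, s + 1L, e),
                   exonStarts, exonEnds)
  s <- paste0(pieces, collapse = "")
  if (strand == "-") oracleRevcomp(s) else s
}

# annotate one exonic, single-exon-contained variant against one uORF
oracleAnnotate <- function(v, orf, t, genomeChr) {
  pos0 <- v$pos - 1L
  nref <- nchar(v$ref); nalt <- nchar(v$alt)
  net <- nalt - nref
  stopifnot(substr(genomeChr, pos0 + 1L, pos0 + nref) == v$ref)
  edited <- paste0(substr(genomeChr, 1L, pos0), v$alt,
                   substr(genomeChr, pos0 + nref + 1L, nchar(genomeChr)))
  es <- t@exonStarts; ee <- t@exonEnds
  host <- which(pos0 >= es & pos0 < ee)
  stopifnot(length(host) == 1L, pos0 + nref <= ee[host])
  ee[host] <- ee[host] + net
  after <- seq_along(es) > host
  es[after] <- es[after] + net
  ee[after] <- ee[after] + net
  Sorig <- oracleSpliced(genomeChr, t@exonStarts, t@exonEnds, t@strand)
  Snew <- oracleSpliced(edited, es, ee, t@strand)
  L <- nchar(Sorig)
  tmap <- unlist(mapply(function(s, e) s:(e - 1L), t@exonStarts, t@exonEnds,
                        SIMPLIFY = FALSE))
  g2t <- function(g) {
    k <- match(g, tmap)
    if (t@strand == "+") k - 1L else L - k
  }
  cdsStartT <- if (t@strand == "+") g2t(t@cdsStartG) else g2t(t@cdsEndG - 1L)
  cdsEndT <- if (t@strand == "+") g2t(t@cdsEndG - 1L) + 1L else
    g2t(t@cdsStartG) + 1L
  tis <- orf@tisTpos
  # effective edit in transcript space (VCF anchors excluded)
  anchored <- nref != nalt && substr(v$ref, 1L, 1L) == substr(v$alt, 1L, 1L)
  shiftsCds <- if (!anchored) {
    FALSE                                  # net == 0, no shift
  } else if (nref > nalt) {                # deletion of [pos0+1, pos0+nref)
    delT <- vapply((pos0 + 1L):(pos0 + nref - 1L), g2t, integer(1))
    max(delT) < cdsStartT
  } else {                                 # insertion after pos0
    insPoint <- if (t@strand == "+") g2t(pos0) + 1L else g2t(pos0)
    insPoint <= cdsStartT
  }
  cdsStartNew <- if (shiftsCds) cdsStartT + net else cdsStartT
  shiftsEnd <- if (!anchored) FALSE else if (nref > nalt) {
    delT <- vapply((pos0 + 1L):(pos0 + nref - 1L), g2t, integer(1))
    max(delT) < cdsEndT
  } else {
    insPoint <- if (t@strand == "+") g2t(pos0) + 1L else g2t(pos0)
    insPoint <= cdsEndT
  }
  cdsEndNew <- if (shiftsEnd) cdsEndT + net else cdsEndT
  capStop <- function(idx, bound) {
    if (is.na(idx) || idx + 3L > bound) NA_integer_ else idx
  }
  oldStop <- capStop(oracleFirstStop(substr(Sorig, tis + 1L, nchar(Sorig))),
                     cdsEndT - tis)
  newStop <- capStop(oracleFirstStop(substr(Snew, tis + 1L, nchar(Snew))),
                     cdsEndNew - tis)
  # transcript position of the first changed base, for the indel stop-shift
  # expectation
  editT <- if (!anchored) {
    if (t@strand == "+") g2t(pos0) else g2t(pos0 + nref - 1L)
  } else if (nref > nalt) {
    min(vapply((pos0 + 1L):(pos0 + nref - 1L), g2t, integer(1)))
  } else {
    if (t@strand == "+") g2t(pos0) + 1L else g2t(pos0)
  }
  editF <- editT - tis
  startOld <- substr(Sorig, tis + 1L, tis + 3L)
  startNew <- substr(Snew, tis + 1L, tis + 3L)
  consequence <- if (startNew != startOld) {
    "start_lost"
  } else if (net %% 3L != 0L) {
    "frameshift"
  } else if (net == 0L) {
    if (!identical(oldStop, newStop)) {
      if (!is.na(newStop) && (is.na(oldStop) || newStop < oldStop))
        "stop_gained" else "stop_lost"
    } else {
      scope <- if (is.na(oldStop)) ((cdsEndT - tis) %/% 3L) * 3L else
        oldStop + 3L
      aaOld <- oracleAa(substr(Sorig, tis + 1L, tis + scope))
      aaNew <- oracleAa(substr(Snew, tis + 1L, tis + scope))
      if (aaOld == aaNew) "synonymous" else "missense"
    }
  } else {
    expected <- if (!is.na(oldStop) && editF <= oldStop + 2L) oldStop + net
      else oldStop
    if (is.na(oldStop) && is.na(newStop)) "inframe_indel"
    else if (is.na(oldStop)) "stop_gained"
    else if (is.na(newStop)) "stop_lost"
    else if (newStop < expected) "stop_gained"
    else if (newStop > expected) "stop_lost"
    else "inframe_indel"
  }
  impact <- "not_applicable"; readThrough <- FALSE
  if (consequence %in% c("stop_gained", "stop_lost", "frameshift")) {
    readThrough <- is.na(newStop)
    cIdx <- cdsStartNew - tis
    origOverlap <- orf@orfClass != "non_overlapping_uORF"
    stopBefore <- !is.na(newStop) && newStop + 3L <= cIdx
    origCong <- ((cdsStartT - tis) %% 3L + 3L) %% 3L
    newCong <- (cIdx %% 3L + 3L) %% 3L
    impact <- if (stopBefore) {
      if (origOverlap) "overlap_removal" else "main_CDS_unaffected"
    } else if (origOverlap && newCong == origCong) "main_CDS_unaffected"
    else if (newCong == 0L) "N-terminal_extension"
    else "out_of_frame_overlap"
  }
  list(consequence = consequence, impact = impact, readThrough = readThrough)
}

# exhaustive SNVs plus 1..maxIndel-nt deletions and insertions over the
# exonic bases of a uORF, restricted to variants whose whole REF span
# (anchor included) lies inside a single exon
enumerateVariants <- function(orf, t, genomeChr, maxIndel = 2L) {
  inOneExon <- function(p0, n) {
    any(p0 >= t@exonStarts & p0 + n <= t@exonEnds)
  }
  out <- list()
  bases <- c("A", "C", "G", "T")
  ins <- c(bases, as.vector(outer(bases, bases, paste0)))
  ins <- ins[nchar(ins) <= maxIndel]
  for (b in seq_along(orf@blockStarts)) {
    for (g in orf@blockStarts[b]:(orf@blockEnds[b] - 1L)) {
      ref <- substr(genomeChr, g + 1L, g + 1L)
      for (a in setdiff(bases, ref))
        out[[length(out) + 1L]] <- data.frame(
          chrom = orf@chrom, pos = g + 1L, id = ".", ref = ref, alt = a,
          stringsAsFactors = FALSE)
      for (k in seq_len(maxIndel)) {       # delete [g, g+k), anchor g-1
        if (!inOneExon(g - 1L, k + 1L)) next
        anchor <- substr(genomeChr, g, g)
        out[[length(out) + 1L]] <- data.frame(
          chrom = orf@chrom, pos = g, id = ".",
          ref = paste0(anchor, substr(genomeChr, g + 1L, g + k)),
          alt = anchor, stringsAsFactors = FALSE)
      }
      if (inOneExon(g, 1L + 1L)) {         # insert after g (room for shift)
        for (s in ins)
          out[[length(out) + 1L]] <- data.frame(
            chrom = orf@chrom, pos = g + 1L, id = ".", ref = ref,
            alt = paste0(ref, s), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
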