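# Codon-independent Kozak context scoring.
#
# The score of a candidate start codon is the product over scored offsets of
# freq(offset, base) / max(freq(offset, .)): 1 exactly on the per-position
# consensus context, in (0, 1] always, and blind to the codon itself because
# offsets 0..2 are masked.

#' Load a Kozak position weight matrix from a TSV config
#'
#' The config is a tab-separated table with columns `offset`, `A`, `C`, `G`,
#' `T`, one row per window offset relative to the first base of the start
#' codon. Frequencies are pseudocounted (so that all entries are strictly
#' positive) and renormalized per offset.
#'
#' @param path TSV file path.
#' @param pseudocount Value added to every frequency before renormalization
#'   when any entry of that offset is zero.
#' @return A [KozakPWM].
#' @export
loadPwm <- function(path, pseudocount = 1e-3) {
  d <- utils::read.delim(path, check.names = FALSE)
  need <- c("offset", "A", "C", "G", "T")
  if (!all(need %in% names(d))) stop("PWM config must have columns ", paste(need, collapse = ", "))
  m <- as.matrix(d[, c("A", "C", "G", "T")])
  if (any(m < 0)) stop("negative frequencies in PWM config")
  zero <- rowSums(m <= 0) > 0
  m[zero, ] <- m[zero, ] + pseudocount
  m <- m / rowSums(m)
  rownames(m) <- NULL
  new("KozakPWM", offsets = as.integer(d$offset), freqs = m)
}

#' Path of the default Kozak PWM shipped with the package
#'
#' A vertebrate-consensus-shaped placeholder over offsets -6..+5 (codon at
#' 0..2 masked); replace with empirically derived frequencies for production
#' scans.
#'
#' @return File path.
#' @export
defaultPwmPath <- function() {
  system.file("extdata", "kozak_pwm_default.tsv", package = "uORFtools",
              mustWork = TRUE)
}

#' Score the Kozak context of a codon occurrence
#'
#' @param seq Transcript-orientation DNA string.
#' @param i 0-based index of the codon's first base within `seq`.
#' @param pwm A [KozakPWM].
#' @return Numeric score in (0, 1] with attribute `partial` set to `TRUE`
#'   when part of the context window falls outside `seq` (only the available
#'   offsets are then scored). Codon offsets 0..2 never contribute. An `N` at
#'   a scored offset contributes that offset's minimum frequency ratio.
#' @export
scoreContext <- function(seq, i, pwm) {
  offs <- scoredOffsets(pwm)
  rows <- match(offs, pwm@offsets)
  pos <- i + offs                      # 0-based positions in seq
  n <- nchar(seq)
  inside <- pos >= 0L & pos < n
  score <- 1
  for (k in seq_along(offs)) {
    if (!inside[k]) next
    base <- substr(seq, pos[k] + 1L, pos[k] + 1L)
    f <- pwm@freqs[rows[k], ]
    r <- if (base %in% names(f)) f[[base]] / max(f) else min(f) / max(f)
    score <- score * r
  }
  attr(score, "partial") <- any(!inside)
  score
}

#' Scan a transcript for candidate translation initiation sites
#'
#' Finds every occurrence of the ten allowed start codons (ATG plus
#' near-cognates) whose first base lies within the 5'UTR or the first
#' `cdsWindow` nt of the main CDS, and scores each context with the
#' codon-masked PWM. Context bases may extend beyond that region into any
#' available transcript sequence; candidates whose window is truncated by the
#' transcript 5' end are scored over the available offsets and flagged
#' `partial_context`.
#'
#' @param t A [TranscriptModel] with a 5'UTR of length >= 1.
#' @param genome Genome from [loadGenome()].
#' @param pwm A [KozakPWM].
#' @param cdsWindow Candidate territory downstream of the main start (nt).
#' @return data.frame: `transcript_id`, `tpos`, `gpos`, `codon`, `score`,
#'   `partial_context`.
#' @export
scanCandidates <- function(t, genome, pwm, cdsWindow = 100L) {
  S <- splicedSequence(t, genome)
  L <- nchar(S)
  utrLen <- cdsTranscriptAnchors(t)[1L]
  if (utrLen < 1L) stop("transcript has no 5'UTR: ", t@transcriptId)
  lim <- min(utrLen + cdsWindow, L - 2L)   # first base index bound (0-based, exclusive)
  if (lim <= 0L)
    return(data.frame(transcript_id = character(0), tpos = integer(0),
                      gpos = integer(0), codon = character(0),
                      score = numeric(0), partial_context = logical(0)))
  starts <- seq_len(lim) - 1L              # candidate 0-based first-base positions
  codons <- substring(S, starts + 1L, starts + 3L)
  hit <- codons %in% nearCognateCodons()
  tpos <- starts[hit]
  cods <- codons[hit]
  sc <- numeric(length(tpos)); part <- logical(length(tpos))
  for (k in seq_along(tpos)) {
    s <- scoreContext(S, tpos[k], pwm)
    sc[k] <- as.numeric(s); part[k] <- attr(s, "partial")
  }
  data.frame(transcript_id = rep(t@transcriptId, length(tpos)),
             tpos = tpos,
             gpos = if (length(tpos)) transcriptToGenomic(t, tpos) else integer(0),
             codon = cods, score = sc, partial_context = part,
             stringsAsFactors = FALSE)
}
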