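# Feature pipeline for the gradient-boosted TIS classifier: one-hot window
# encoding, signal capping/scaling, feature-row assembly, and gene-aware
# splitting.

#' Encoding specification for TIS windows
#'
#' Windows are centered on the first base of the candidate start codon:
#' `flank` nt on each side gives `2 * flank + 1` positions, one-hot encoded
#' over A, C, G, T (4 bits per position); `X` (padding/unknown, `N` treated
#' the same) is the all-zero block.
#'
#' @param flank Flank size in nt (default 50: 101-nt windows, 404-long
#'   one-hot vectors).
#' @param nExpression Number of per-gene expression features appended after
#'   the per-position signal block.
#' @return List with `flank`, `windowLen`, `oneHotLen`, `nExpression`,
#'   `totalLen` and an identifying `fingerprint` string.
#' @export
encodingSpec <- function(flank = 50L, nExpression = 0L) {
  windowLen <- 2L * flank + 1L
  spec <- list(flank = as.integer(flank), windowLen = windowLen,
               oneHotLen = 4L * windowLen, nExpression = as.integer(nExpression),
               totalLen = 4L * windowLen + windowLen + as.integer(nExpression))
  spec$fingerprint <- sprintf("onehot4x%d+signal%d+expr%d", windowLen,
                              windowLen, spec$nExpression)
  spec
}

#' Signal scaling specification
#'
#' Raw per-position read counts are capped at `cap` and linearly scaled to
#' `[0, outMax]`.
#'
#' @param cap Cap in reads (default 5000).
#' @param outMax Upper bound of the scaled range (default 10).
#' @return List with `cap` and `outMax`.
#' @export
signalScalingSpec <- function(cap = 5000, outMax = 10) {
  list(cap = cap, outMax = outMax)
}

#' One-hot encode fixed-length sequence windows
#'
#' @param seqs Character vector of windows, all of length `windowLen`;
#'   alphabet A, C, G, T, X (N treated as X).
#' @param windowLen Window length in nt.
#' @return Numeric matrix `length(seqs) x (4 * windowLen)`; each position
#'   contributes the block (A, C, G, T), with X/N the all-zero block.
#' @examples
#' oneHotWindow("ACGTX", windowLen = 5)
#' @export
oneHotWindow <- function(seqs, windowLen) {
  if (any(nchar(seqs) != windowLen))
    stop("all windows must have length ", windowLen)
  n <- length(seqs)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  bad <- !(chars %in% c("A", "C", "G", "T", "X", "N"))
  if (any(bad)) stop("windows contain characters outside {A,C,G,T,X,N}")
  out <- matrix(0, nrow = n, ncol = 4L * windowLen)
  bases <- c("A", "C", "G", "T")
  for (b in seq_along(bases)) {
    hit <- which(chars == bases[b], arr.ind = TRUE)
    if (nrow(hit))
      out[cbind(hit[, 1L], (hit[, 2L] - 1L) * 4L + b)] <- 1
  }
  out
}

#' Cap and scale raw signal counts
#'
#' `x -> min(x, cap) * outMax / cap`: monotone, bounded in `[0, outMax]`.
#'
#' @param x Numeric vector of non-negative read counts.
#' @param spec A [signalScalingSpec()].
#' @return Scaled numeric vector.
#' @examples
#' scaleSignal(c(0, 2500, 5000, 99999))
#' @export
scaleSignal <- function(x, spec = signalScalingSpec()) {
  if (any(x < 0)) stop("negative read counts")
  pmin(x, spec$cap) * spec$outMax / spec$cap
}

#' Assemble feature rows for candidate TISs
#'
#' For each candidate, a window of `2 * flank + 1` nt centered on the codon
#' first base is cut from the spliced transcript (padded with `X` beyond the
#' transcript ends), the per-position initiating-ribosome signal is sampled
#' from the genomic track through the coordinate map and cap/scaled, and the
#' gene's standardized expression features are appended. Transcripts whose
#' 5'UTR length falls outside `utrBounds` are excluded.
#'
#' @param candidates data.frame with `gene_id`, `transcript_id`, `chrom`,
#'   `gpos`, `strand`, `codon` and optionally `label`.
#' @param transcripts Named list of [TranscriptModel].
#' @param genome Genome from [loadGenome()].
#' @param track A [SignalTrack].
#' @param expression Optional numeric matrix gene x feature (z-scored per
#'   column by the caller or [standardizeExpression()]).
#' @param spec An [encodingSpec()]; its `nExpression` must match
#'   `ncol(expression)`.
#' @param scaling A [signalScalingSpec()].
#' @param utrBounds Admissible 5'UTR length range (default `c(30, 3000)`).
#' @return List: `features` (numeric matrix n x `spec$totalLen`), `meta`
#'   (data.frame of retained candidates), `excluded` (count filtered out by
#'   the UTR bounds).
#' @export
extractWindows <- function(candidates, transcripts, genome, track,
                           expression = NULL, spec = encodingSpec(),
                           scaling = signalScalingSpec(),
                           utrBounds = c(30L, 3000L)) {
  nExpr <- if (is.null(expression)) 0L else ncol(expression)
  if (nExpr != spec$nExpression)
    stop("encoding spec declares ", spec$nExpression,
         " expression features but ", nExpr, " supplied")
  keepT <- vapply(transcripts, function(t) {
    u <- cdsTranscriptAnchors(t)[1L]
    u >= utrBounds[1L] && u <= utrBounds[2L]
  }, logical(1))
  ok <- candidates$transcript_id %in% names(transcripts)[keepT]
  excluded <- sum(!ok)
  cand <- candidates[ok, , drop = FALSE]
  featList <- vector("list", 0L)
  metaList <- vector("list", 0L)
  for (tid in unique(cand$transcript_id)) {
    t <- transcripts[[tid]]
    d <- cand[cand$transcript_id == tid, , drop = FALSE]
    S <- splicedSequence(t, genome)
    L <- nchar(S)
    tpos <- genomicToTranscript(t, d$gpos)
    if (anyNA(tpos)) stop("unmappable candidate on ", tid)
    win <- vapply(tpos, function(p) {
      lo <- p - spec$flank; hi <- p + spec$flank
      pre <- strrep("X", max(0L, -lo))
      post <- strrep("X", max(0L, hi - (L - 1L)))
      paste0(pre, substr(S, max(0L, lo) + 1L, min(L - 1L, hi) + 1L), post)
    }, character(1))
    oh <- oneHotWindow(win, spec$windowLen)
    # batch the signal lookup: one query over all window positions of this
    # transcript's candidates
    rngMat <- outer(tpos, (-spec$flank):(spec$flank), `+`)
    inside <- rngMat >= 0L & rngMat < L
    gAll <- rep(NA_integer_, length(rngMat))
    gAll[inside] <- transcriptToGenomic(t, rngMat[inside])
    uniqG <- unique(gAll[!is.na(gAll)])
    cnt <- stats::setNames(signalAt(track, t@chrom, uniqG, t@strand),
                           uniqG)
    raw <- numeric(length(rngMat))
    raw[inside] <- cnt[as.character(gAll[inside])]
    sig <- matrix(scaleSignal(raw, scaling), nrow = nrow(rngMat))
    ex <- if (nExpr) {
      row <- expression[d$gene_id[1L], , drop = TRUE]
      matrix(rep(as.numeric(row), nrow(d)), nrow = nrow(d), byrow = TRUE)
    } else matrix(0, nrow(d), 0L)
    featList[[length(featList) + 1L]] <- cbind(oh, sig, ex)
    metaList[[length(metaList) + 1L]] <- d
  }
  features <- if (length(featList)) do.call(rbind, featList) else
    matrix(0, 0L, spec$totalLen)
  stopifnot(ncol(features) == spec$totalLen)
  list(features = features,
       meta = if (length(metaList)) do.call(rbind, metaList) else cand,
       excluded = excluded)
}

#' Z-score an expression matrix per feature column
#'
#' @param m Numeric matrix gene x feature.
#' @return Standardized matrix (columns with zero variance become 0).
#' @export
standardizeExpression <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(m, 2L, mu), 2L, sdv, "/")
}

#' Gene-aware train/validation/test split
#'
#' Genes are clustered by genomic span overlap so that overlapping genes
#' always co-assign, clusters are shuffled with the given seed, and assigned
#' to splits at the stated fractions of genes (deviation at most one
#' cluster).
#'
#' @param meta data.frame with `gene_id`, `chrom`, `gpos` per row.
#' @param fractions Numeric length-3 vector summing to 1 (train, val, test).
#' @param seed Integer seed for the shuffle.
#' @param span Half-width (nt) around each candidate used as the gene's
#'   genomic footprint when clustering.
#' @return List of integer row-index vectors `train`, `val`, `test`.
#' @export
splitByGene <- function(meta, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                        span = 0L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  g <- stats::aggregate(gpos ~ gene_id + chrom, data = meta,
                        FUN = function(x) c(min(x), max(x)))
  genes <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                      start = g$gpos[, 1L] - span, end = g$gpos[, 2L] + span,
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), ]
  cluster <- integer(nrow(genes)); cid <- 0L; curEnd <- -Inf; curChrom <- ""
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != curChrom || genes$start[i] > curEnd) {
      cid <- cid + 1L; curChrom <- genes$chrom[i]; curEnd <- genes$end[i]
    } else curEnd <- max(curEnd, genes$end[i])
    cluster[i] <- cid
  }
  genes$cluster <- cluster
  clusters <- split(genes$gene_id, genes$cluster)
  ord <- .withSeed(seed, sample.int(length(clusters)))
  sizes <- lengths(clusters)[ord]
  cum <- cumsum(sizes) / sum(sizes)
  assign <- ifelse(cum <= fractions[1L], "train",
                   ifelse(cum <= fractions[1L] + fractions[2L], "val", "test"))
  # guarantee non-empty val/test when enough clusters exist
  if (!any(assign == "val") && length(assign) >= 3L)
    assign[which(assign == "train")[sum(assign == "train")]] <- "val"
  if (!any(assign == "test") && length(assign) >= 3L)
    assign[length(assign)] <- "test"
  geneSplit <- stats::setNames(rep(NA_character_, nrow(genes)), NULL)
  for (k in seq_along(ord))
    geneSplit[genes$cluster == as.integer(names(clusters)[ord[k]])] <- assign[k]
  names(geneSplit) <- genes$gene_id
  rowSplit <- unname(geneSplit[meta$gene_id])
  list(train = which(rowSplit == "train"),
       val = which(rowSplit == "val"),
       test = which(rowSplit == "test"))
}

# evaluate expr with a local RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
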