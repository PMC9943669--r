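# Planted-rule dataset for the TIS classifier's parameter-recovery check:
# a candidate is rule-positive iff its capped/scaled initiating-ribosome
# signal at the codon first base reaches 8 AND the fixed context 6-mer
# GCCACC immediately precedes the codon; labels are then flipped at a small
# noise rate.

#' Generate a planted-rule machine-learning dataset
#'
#' One single-exon transcript per gene (strands alternating), `perGene`
#' candidate start codons spaced along each 5'UTR. Rule-positives receive a
#' signal peak of 4000--5000 reads (scaled 8--10) at the codon first base
#' and the GCCACC context; negatives lack the peak, the motif, or both.
#' Labels are flipped independently at `noise`.
#'
#' @param nGenes Number of genes/transcripts (default 1000).
#' @param perGene Candidates per transcript (default 20).
#' @param rulePositive Probability a candidate is rule-positive (default
#'   0.4).
#' @param noise Label flip rate (default 0.05).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param dir Optional output directory for candidate TSV, bedGraph signal
#'   and expression TSV.
#' @return List: `genome`, `transcripts`, `candidates` (with `label` and the
#'   noiseless `rule` column), `track`, `expression`, `paths` (when written).
#' @export
makeMlDataset <- function(nGenes = 1000L, perGene = 20L, rulePositive = 0.4,
                          noise = 0.05, seed = 1L, dir = NULL) {
  .withSeed(seed, .makeMlImpl(nGenes, perGene, rulePositive, noise, dir))
}

.makeMlImpl <- function(nGenes, perGene, rulePositive, noise, dir) {
  utrLen <- 500L
  cds <- paste0("ATG", strrep("GCA", 8L), "TAA")
  motif <- "GCCACC"
  contigs <- character(nGenes)
  txs <- vector("list", nGenes)
  candList <- vector("list", nGenes)
  sigList <- vector("list", nGenes)
  for (i in seq_len(nGenes)) {
    gid <- sprintf("GENE%04d", i)
    tid <- sprintf("TX%04d", i)
    chrom <- sprintf("ctg%04d", i)
    strand <- if (i %% 2L == 0L) "-" else "+"
    utr <- .randomDna(utrLen)
    tpos <- 60L + 22L * (seq_len(perGene) - 1L)
    rule <- stats::runif(perGene) < rulePositive
    hasMotif <- rule | stats::runif(perGene) < 0.3
    hasPeak <- rule | (!hasMotif & stats::runif(perGene) < 0.5)
    codon <- sample(nearCognateCodons(), perGene, replace = TRUE)
    for (k in seq_len(perGene)) {
      p <- tpos[k]
      substr(utr, p + 1L, p + 3L) <- codon[k]
      ctx <- if (hasMotif[k]) motif else {
        x <- .randomDna(6L)
        while (x == motif) x <- .randomDna(6L)
        x
      }
      substr(utr, p - 5L, p) <- ctx
    }
    d <- .txDesign(tid, gid, utr, cds, .randomDna(20L))
    pl <- .placeTx(d, strand, 0L)
    contigs[i] <- pl$segment
    txs[[i]] <- TranscriptModel(tid, gid, chrom, strand, pl$exonStarts,
                                pl$exonEnds,
                                min(pl$map[(utrLen + 1L):(utrLen + nchar(cds))]),
                                max(pl$map[(utrLen + 1L):(utrLen + nchar(cds))]) + 1L)
    raw <- ifelse(hasPeak, stats::runif(perGene, 4000, 5000),
                  stats::runif(perGene, 0, 3000))
    gpos <- pl$map[tpos + 1L]
    lab <- as.integer(rule)
    flip <- stats::runif(perGene) < noise
    lab[flip] <- 1L - lab[flip]
    candList[[i]] <- data.frame(
      gene_id = gid, transcript_id = tid, chrom = chrom, gpos = gpos,
      strand = strand, codon = codon, label = lab, rule = rule,
      stringsAsFactors = FALSE)
    sigList[[i]] <- data.frame(chrom = chrom, pos = gpos, count = round(raw),
                               stringsAsFactors = FALSE)
  }
  names(contigs) <- sprintf("ctg%04d", seq_len(nGenes))
  names(txs) <- vapply(txs, transcriptId, character(1))
  candidates <- do.call(rbind, candList)
  signal <- do.call(rbind, sigList)
  genome <- Biostrings::DNAStringSet(contigs)
  expression <- matrix(stats::rnorm(nGenes * 8L), nrow = nGenes,
                       dimnames = list(sprintf("GENE%04d", seq_len(nGenes)),
                                       paste0("cell", 1:8)))
  res <- list(genome = genome, transcripts = txs, candidates = candidates,
              track = SignalTrack(signal), expression = expression,
              noise = noise)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(candidates = file.path(dir, "candidates.tsv"),
                  bedgraph = file.path(dir, "ml_signal.bedgraph"),
                  expression = file.path(dir, "ml_expression.tsv"),
                  fasta = file.path(dir, "ml_genome.fa"))
    utils::write.table(candidates, paths$candidates, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    with(signal[order(signal$chrom, signal$pos), ],
         writeLines(sprintf("%s\t%d\t%d\t%g", chrom, pos, pos + 1L, count),
                    paths$bedgraph))
    utils::write.table(cbind(gene_id = rownames(expression),
                             as.data.frame(expression)),
                       paths$expression, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    Biostrings::writeXStringSet(genome, paths$fasta)
    res$paths <- paths
  }
  res
}
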