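#' @include AllClasses.R
NULL

## Plain-vector view of a block set (exons or ORF blocks): genomic
## ascending starts/ends plus cumulative spliced widths. All heavy loops
## run on these indexes rather than on S4 objects.
.blockIndex <- function(blocks) {
  s <- start(blocks)
  e <- end(blocks)
  ord <- order(s)
  s <- s[ord]; e <- e[ord]
  list(chrom = as.character(seqnames(blocks))[1],
       strand = as.character(strand(blocks))[1],
       starts = s, ends = e,
       cum = c(0L, cumsum(e - s + 1L)),
       L = sum(e - s + 1L))
}

## Decompose a whole GRangesList into plain block indexes in one pass
## (elementwise [[ extraction on GRangesList is far too slow in loops).
.grlIndex <- function(grl) {
  u <- unlist(grl, use.names = FALSE)
  n <- lengths(grl)
  f <- rep.int(seq_along(grl), n)
  sSplit <- split(start(u), f)
  eSplit <- split(end(u), f)
  chromAll <- as.character(seqnames(u))
  strandAll <- as.character(strand(u))
  firstIdx <- cumsum(c(1L, n[-length(n)]))
  out <- vector("list", length(grl))
  for (k in seq_along(grl)) {
    if (n[k] == 0L) next
    key <- as.character(k)
    s <- sSplit[[key]]
    e <- eSplit[[key]]
    ord <- order(s)
    s <- s[ord]; e <- e[ord]
    out[[k]] <- list(chrom = chromAll[firstIdx[k]],
                     strand = strandAll[firstIdx[k]],
                     starts = s, ends = e,
                     cum = c(0L, cumsum(e - s + 1L)),
                     L = sum(e - s + 1L))
  }
  names(out) <- names(grl)
  out
}

.txIndex <- function(tx) .grlIndex(tx@exons)

## genomic position -> 1-based spliced offset (NA when non-exonic)
.g2t <- function(ix, pos) {
  minus <- ix$strand == "-"
  n <- length(ix$starts)
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(n)) {
    k <- if (minus) n - i + 1L else i
    hit <- !is.na(pos) & pos >= ix$starts[k] & pos <= ix$ends[k]
    if (!any(hit)) next
    within <- if (minus) ix$ends[k] - pos[hit] else pos[hit] - ix$starts[k]
    cumBefore <- if (minus) ix$L - ix$cum[k + 1L] else ix$cum[k]
    out[hit] <- cumBefore + within + 1L
  }
  out
}

## 1-based spliced offset -> genomic position (NA when out of range)
.t2g <- function(ix, offset) {
  out <- rep(NA_integer_, length(offset))
  ok <- !is.na(offset) & offset >= 1L & offset <= ix$L
  if (!any(ok)) return(out)
  off0 <- offset[ok] - 1L
  if (ix$strand == "-") off0 <- ix$L - 1L - off0
  idx <- findInterval(off0, ix$cum[-length(ix$cum)])
  out[ok] <- ix$starts[idx] + (off0 - ix$cum[idx])
  out
}

## All genomic positions of a block index, 5'->3' transcript order.
.splicedPos <- function(ix) {
  p <- unlist(mapply(seq.int, ix$starts, ix$ends, SIMPLIFY = FALSE),
              use.names = FALSE)
  if (ix$strand == "-") rev(p) else p
}

## Blocks in translation (5'->3') order: ascending genomic start on +,
## descending on -.
translationOrder <- function(blocks) {
  blocks <- sort(blocks)
  if (as.character(strand(blocks)[1]) == "-") rev(blocks) else blocks
}

## All genomic positions of a block set, in 5'->3' transcript order.
splicedPositions <- function(blocks) {
  .splicedPos(.blockIndex(blocks))
}

#' Map genomic positions onto a spliced transcript
#'
#' Converts genomic positions to 1-based offsets along the spliced
#' transcript, counted 5' to 3' (so on a minus-strand transcript, offset 1
#' is the 3'-most genomic base of the first exon in transcription order).
#' Intronic or out-of-range positions map to `NA`.
#'
#' The mapping is computed from cumulative exon widths, not by
#' enumeration, so it is O(number of exons) per position.
#'
#' @param tx A [TranscriptSet].
#' @param id Transcript id.
#' @param pos Integer vector of genomic positions (1-based).
#' @return Integer vector of spliced offsets, `NA` where non-exonic.
#' @seealso [transcriptToGenome()], [frameOf()]
#' @examples
#' tx <- toyTranscriptSet()
#' genomeToTranscript(tx, "TX1", c(201, 150))
#' @export
genomeToTranscript <- function(tx, id, pos) {
  ex <- exonsOf(tx, id)
  if (is.null(ex)) stop("unknown transcript: ", id)
  .g2t(.blockIndex(ex), pos)
}

#' Map spliced-transcript offsets back to genomic positions
#'
#' Inverse of [genomeToTranscript()]; offsets outside `[1, spliced length]`
#' map to `NA`.
#'
#' @inheritParams genomeToTranscript
#' @param offset Integer vector of 1-based spliced offsets.
#' @return Integer vector of genomic positions.
#' @export
transcriptToGenome <- function(tx, id, offset) {
  ex <- exonsOf(tx, id)
  if (is.null(ex)) stop("unknown transcript: ", id)
  .t2g(.blockIndex(ex), offset)
}

#' Spliced length of a transcript
#' @inheritParams genomeToTranscript
#' @return Integer spliced length in nt.
#' @export
transcriptLength <- function(tx, id) sum(width(exonsOf(tx, id)))

#' Enumerate the codons of an ORF
#'
#' Tiles the ORF's spliced sequence into consecutive codons and returns,
#' for each codon, its three genomic positions in translation order.
#' Codons may span splice junctions, in which case their positions come
#' from two blocks.
#'
#' @param blocks A [GRanges] of ORF blocks (one chromosome/strand, total
#'   width divisible by 3), or an [OrfSet] together with `id`.
#' @param id ORF id when `blocks` is an `OrfSet`.
#' @return Integer matrix with `n_codons` rows and 3 columns; row i holds
#'   the genomic positions of codon i in translation order.
#' @examples
#' orfCodons(GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 19), "+"))
#' @export
orfCodons <- function(blocks, id = NULL) {
  if (is(blocks, "OrfSet")) blocks <- orfBlocks(blocks, id)
  p <- splicedPositions(blocks)
  stopifnot(length(p) %% 3L == 0L)
  matrix(p, ncol = 3L, byrow = TRUE)
}

#' Reading-frame phase of genomic positions relative to an ORF
#'
#' Frame 0 marks the first base of each codon. The phase is defined from
#' the ORF's start codon and extended beyond the ORF in both directions
#' along the host transcript, so in-frame positions can be counted in the
#' flanking windows around the stop codon.
#'
#' @param blocks ORF blocks ([GRanges]) assigned to transcript `id`.
#' @param tx A [TranscriptSet].
#' @param id Host transcript id.
#' @param pos Genomic positions.
#' @return Integer vector in `{0, 1, 2}`, `NA` for non-exonic positions.
#' @export
frameOf <- function(blocks, tx, id, pos) {
  .frameOf(.blockIndex(blocks), .blockIndex(exonsOf(tx, id)), pos)
}

.frameOf <- function(orfIx, txIx, pos) {
  s0 <- .g2t(txIx, .splicedPos(orfIx)[1])
  if (is.na(s0)) stop("ORF start is not exonic on the host transcript")
  (.g2t(txIx, pos) - s0) %% 3L
}

#' Transcript flanking windows around an ORF's stop codon
#'
#' Returns the transcript intervals of up to `w` nt immediately 5' and 3'
#' of the stop codon (the ORF's last 3 nt). The stop codon itself belongs
#' to neither window. Windows are defined on the transcript, so the
#' "before" window may extend 5' of a very short ORF's start codon, and
#' both truncate at the transcript ends.
#'
#' @inheritParams frameOf
#' @param w Window size in nt (default 15).
#' @return A list with elements `before` and `after`, each a list with
#'   integer `start`, `end` (1-based spliced offsets, inclusive; `end <
#'   start` denotes an empty window) and `size` (realized width).
#' @export
stopFlankWindows <- function(blocks, tx, id, w = 15L) {
  .stopFlanks(.blockIndex(blocks), .blockIndex(exonsOf(tx, id)), w)
}

.stopFlanks <- function(orfIx, txIx, w = 15L) {
  p <- .splicedPos(orfIx)
  L <- txIx$L
  stopFirst <- .g2t(txIx, p[length(p) - 2L])
  if (is.na(stopFirst)) stop("stop codon not exonic on the host transcript")
  bStart <- max(1L, stopFirst - w)
  bEnd <- stopFirst - 1L
  aStart <- stopFirst + 3L
  aEnd <- min(L, stopFirst + 2L + w)
  list(before = list(start = bStart, end = bEnd,
                     size = max(0L, bEnd - bStart + 1L)),
       after = list(start = aStart, end = aEnd,
                    size = max(0L, aEnd - aStart + 1L)))
}

## Convert an offset interval on a transcript into genomic blocks
## (GRanges sorted by start). Used by the simulator to plant ORFs.
offsetsToBlocks <- function(tx, id, from, to) {
  g <- transcriptToGenome(tx, id, from:to)
  stopifnot(!anyNA(g))
  g <- sort(g)
  brk <- c(0L, which(diff(g) != 1L), length(g))
  ex <- exonsOf(tx, id)
  GRanges(as.character(seqnames(ex))[1],
          IRanges(g[brk[-length(brk)] + 1L], g[brk[-1]]),
          strand = as.character(strand(ex))[1])
}
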