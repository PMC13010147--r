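#' @include AllClasses.R coordinates.R
NULL

emptyCounts <- function() {
  g <- GRanges()
  g$score <- integer(0)
  g
}

expandBedgraph <- function(gr, strandChar, label) {
  if (length(gr) == 0L)
    return(emptyCounts())
  sc <- gr$score
  if (any(sc < 0))
    stop("negative P-site value at ", label, " ",
         as.character(seqnames(gr))[which(sc < 0)[1]], ":",
         start(gr)[which(sc < 0)[1]])
  rounded <- round(sc)
  off <- abs(sc - rounded) > 1e-6
  if (any(off))
    stop("non-integer P-site value ", sc[which(off)[1]], " at ", label, " ",
         as.character(seqnames(gr))[which(off)[1]], ":",
         start(gr)[which(off)[1]])
  gr <- gr[rounded > 0]
  if (length(gr) == 0L) return(emptyCounts())
  rounded <- round(gr$score)
  pos <- unlist(mapply(seq, start(gr), end(gr), SIMPLIFY = FALSE),
                use.names = FALSE)
  chrom <- rep(as.character(seqnames(gr)), width(gr))
  out <- GRanges(chrom, IRanges(pos, width = 1L), strand = strandChar,
                 score = rep(as.integer(rounded), width(gr)))
  key <- paste(chrom, pos)
  if (anyDuplicated(key))
    stop("overlapping spans in ", label, " at ",
         key[which(duplicated(key))[1]])
  out
}

#' Read a strand-specific bedGraph pair into a PsiteTrack
#'
#' Each file holds 0-based half-open spans of per-base P-site counts for
#' one strand; spans are expanded to single-base positions. Values must
#' be non-negative integers (tolerance 1e-6); overlapping spans within
#' one strand are rejected as ambiguous.
#'
#' @param plusPath,minusPath bedGraph files for the + and - strand.
#' @param datasetId Label for the resulting track.
#' @return A [PsiteTrack].
#' @seealso [poolTracks()], [projectTrack()], [writeBedgraphPair()]
#' @export
readBedgraphPair <- function(plusPath, minusPath, datasetId) {
  rd <- function(p) {
    lines <- readLines(p)
    if (!any(nzchar(lines) & !grepl("^(#|track|browser)", lines)))
      return(emptyCounts())
    rtracklayer::import(p, format = "bedGraph")
  }
  cts <- c(expandBedgraph(rd(plusPath), "+", basename(plusPath)),
           expandBedgraph(rd(minusPath), "-", basename(minusPath)))
  new("PsiteTrack", datasetId = datasetId, counts = sort(cts))
}

#' Write a PsiteTrack as a bedGraph pair
#'
#' @param track A [PsiteTrack].
#' @param plusPath,minusPath Output bedGraph paths per strand.
#' @return The two paths, invisibly.
#' @export
writeBedgraphPair <- function(track, plusPath, minusPath) {
  wr <- function(strandChar, p) {
    gr <- track@counts[as.character(strand(track@counts)) == strandChar]
    strand(gr) <- "*"
    rtracklayer::export(gr, p, format = "bedGraph")
  }
  wr("+", plusPath)
  wr("-", minusPath)
  invisible(c(plusPath, minusPath))
}

#' Construct a PsiteTrack from positions and counts
#'
#' @param datasetId Track label.
#' @param chrom,pos,strand,count Parallel vectors describing single-base
#'   counts; duplicate (chrom, strand, pos) entries are summed.
#' @return A [PsiteTrack].
#' @export
psiteTrack <- function(datasetId, chrom = character(0), pos = integer(0),
                       strand = character(0), count = integer(0)) {
  if (length(pos) == 0L)
    return(new("PsiteTrack", datasetId = datasetId, counts = GRanges()))
  key <- paste(chrom, strand, pos)
  agg <- rowsum(as.numeric(count), key)
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  gr <- GRanges(vapply(parts, `[`, "", 1L),
                IRanges(as.integer(vapply(parts, `[`, "", 3L)), width = 1L),
                strand = vapply(parts, `[`, "", 2L),
                score = as.integer(agg[, 1]))
  gr <- gr[gr$score > 0]
  new("PsiteTrack", datasetId = datasetId, counts = sort(gr))
}

#' Pool P-site tracks by positionwise summation
#'
#' @param tracks A list of [PsiteTrack] objects (at least one).
#' @param datasetId Label for the pooled track.
#' @return A [PsiteTrack] whose count at every position is the sum of the
#'   input counts there.
#' @export
poolTracks <- function(tracks, datasetId = "pooled") {
  if (is(tracks, "PsiteTrack")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1L)
  all <- do.call(c, lapply(tracks, function(t) t@counts))
  if (length(all) == 0L)
    return(new("PsiteTrack", datasetId = datasetId, counts = GRanges()))
  psiteTrack(datasetId,
             chrom = as.character(seqnames(all)), pos = start(all),
             strand = as.character(strand(all)), count = all$score)
}

## Plain lookup structure: per (chrom, strand), sorted positions and
## their counts; queried by binary search (findInterval).
.trackIndex <- function(track) {
  cts <- track@counts
  if (length(cts) == 0L) return(list())
  key <- paste0(as.character(seqnames(cts)), "|", as.character(strand(cts)))
  pos <- start(cts)
  sc <- as.numeric(cts$score)
  out <- lapply(split(seq_along(key), key), function(i) {
    o <- order(pos[i])
    list(pos = pos[i][o], score = sc[i][o])
  })
  out
}

.countsAtIdx <- function(tIdx, chrom, strandChar, pos) {
  sl <- tIdx[[paste0(chrom, "|", strandChar)]]
  if (is.null(sl)) return(numeric(length(pos)))
  i <- findInterval(pos, sl$pos)
  out <- numeric(length(pos))
  hit <- i > 0L & sl$pos[pmax(i, 1L)] == pos
  out[hit] <- sl$score[i[hit]]
  out
}

## Counts at explicit genomic single-base positions on one strand.
countsAt <- function(track, chrom, strandChar, pos) {
  .countsAtIdx(.trackIndex(track), chrom, strandChar, pos)
}

#' Project a P-site track onto a transcript interval
#'
#' Returns per-nucleotide counts along a spliced-transcript interval,
#' 5' to 3'. Only counts on the transcript's own strand are visible
#' (Ribo-seq is stranded).
#'
#' @param track A [PsiteTrack].
#' @param tx A [TranscriptSet].
#' @param id Transcript id.
#' @param from,to 1-based spliced offsets (inclusive); default the whole
#'   transcript.
#' @return Numeric vector of length `to - from + 1` (empty when
#'   `to < from`).
#' @export
projectTrack <- function(track, tx, id, from = 1L,
                         to = transcriptLength(tx, id)) {
  if (to < from) return(numeric(0))
  ex <- exonsOf(tx, id)
  g <- transcriptToGenome(tx, id, from:to)
  stopifnot(!anyNA(g))
  countsAt(track, as.character(seqnames(ex))[1],
           as.character(strand(ex))[1], g)
}
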