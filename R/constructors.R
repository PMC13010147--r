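#' @include AllClasses.R
NULL

#' Construct a TranscriptSet programmatically
#'
#' @param exons Named list of [GRanges] (one per transcript).
#' @param cds Named list of [GRanges]; transcripts absent from the list
#'   get an empty CDS.
#' @param txData A data.frame/[S4Vectors::DataFrame] with columns
#'   `transcript_id`, `gene_id`, `gene_biotype`, `transcript_biotype`
#'   and optionally `mane_select`, `appris_rank`, `tsl`, `readthrough`
#'   (defaulted to untagged when missing).
#' @return A validated [TranscriptSet].
#' @export
TranscriptSet <- function(exons, cds = list(), txData) {
  txData <- as(txData, "DataFrame")
  ids <- txData$transcript_id
  if (is.null(txData$mane_select)) txData$mane_select <- FALSE
  if (is.null(txData$appris_rank)) txData$appris_rank <- NA_integer_
  if (is.null(txData$tsl)) txData$tsl <- NA_integer_
  if (is.null(txData$readthrough)) txData$readthrough <- FALSE
  exl <- GRangesList(lapply(ids, function(i) sort(exons[[i]])))
  names(exl) <- ids
  cdl <- GRangesList(lapply(ids, function(i) {
    g <- cds[[i]]
    if (is.null(g)) GRanges() else sort(g)
  }))
  names(cdl) <- ids
  obj <- new("TranscriptSet", exons = exl, cds = cdl, txData = txData)
  validObject(obj)
  obj
}

#' Construct an OrfSet programmatically
#'
#' @param blocks Named list of [GRanges] (one element per ORF, blocks of
#'   the spliced ORF including the stop codon).
#' @param startCodon,legacyName,hostTranscript,orfType Optional per-ORF
#'   character vectors (recycled `NA` when missing).
#' @param sourceDatasets Optional list of character vectors of study
#'   labels per ORF.
#' @return A validated [OrfSet].
#' @export
OrfSet <- function(blocks, startCodon = NULL, sourceDatasets = NULL,
                   legacyName = NULL, hostTranscript = NULL,
                   orfType = NULL) {
  ids <- names(blocks)
  if (is.null(ids)) stop("blocks must be a named list")
  n <- length(ids)
  fill <- function(x) if (is.null(x)) rep(NA_character_, n) else x
  bl <- GRangesList(lapply(blocks, sort))
  names(bl) <- ids
  if (is.null(sourceDatasets))
    sourceDatasets <- replicate(n, character(0), simplify = FALSE)
  od <- DataFrame(orf_id = ids,
                  start_codon = fill(startCodon),
                  n_codons = as.integer(sum(width(bl)) / 3L),
                  source_datasets = IRanges::CharacterList(sourceDatasets),
                  legacy_name = fill(legacyName),
                  host_transcript = fill(hostTranscript),
                  orf_type = fill(orfType))
  obj <- new("OrfSet", blocks = bl, orfData = od)
  validObject(obj)
  obj
}

#' A small two-exon example transcript set
#'
#' One plus-strand two-exon coding transcript, used in documentation
#' examples.
#'
#' @return A [TranscriptSet] with a single transcript `TX1`.
#' @export
toyTranscriptSet <- function() {
  TranscriptSet(
    exons = list(TX1 = GRanges("chr1", IRanges(c(1, 201), c(100, 300)),
                               strand = "+")),
    cds = list(TX1 = GRanges("chr1", IRanges(c(31, 201), c(100, 260)),
                             strand = "+")),
    txData = data.frame(transcript_id = "TX1", gene_id = "G1",
                        gene_biotype = "protein_coding",
                        transcript_biotype = "protein_coding"))
}
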