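#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- Rle
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#' @importFrom BiocGenerics sort
NULL

#' Transcript models parsed from a GTF annotation
#'
#' A `TranscriptSet` holds one spliced transcript model per transcript:
#' its exons, its (possibly empty) CDS blocks, and the per-transcript
#' metadata used for host-transcript assignment (biotypes, MANE Select,
#' APPRIS rank, transcript support level, readthrough flag).
#'
#' All coordinates are 1-based closed, the native GRanges convention;
#' conversion from the GTF dialect happens in [readAnnotation()].
#'
#' @slot exons A [GRangesList] named by transcript id; each element sorted
#'   by genomic start, non-overlapping, on a single chromosome and strand.
#' @slot cds A [GRangesList] parallel to `exons`; elements may be empty.
#' @slot txData A [S4Vectors::DataFrame] with one row per transcript:
#'   `transcript_id`, `gene_id`, `gene_biotype` (one of `protein_coding`,
#'   `lncRNA`, `pseudogene`, `other`), `transcript_biotype`, `mane_select`
#'   (logical), `appris_rank` (integer, `NA` = untagged), `tsl` (integer
#'   1-5, `NA` = untagged), `readthrough` (logical).
#'
#' @seealso [readAnnotation()], [writeAnnotation()]
#' @export
setClass("TranscriptSet",
  representation(exons = "CompressedGRangesList",
                 cds = "CompressedGRangesList",
                 txData = "DataFrame"))

setValidity("TranscriptSet", function(object) {
  ids <- object@txData$transcript_id
  if (is.null(ids)) return("txData must have a transcript_id column")
  if (anyDuplicated(ids)) return("duplicated transcript ids")
  if (!identical(names(object@exons), ids) ||
      !identical(names(object@cds), ids))
    return("exons/cds names must match txData$transcript_id")
  for (i in seq_along(ids)) {
    ex <- object@exons[[i]]
    if (length(ex) == 0L) return(paste0("transcript ", ids[i], " has no exons"))
    if (length(unique(as.character(seqnames(ex)))) != 1L ||
        length(unique(as.character(strand(ex)))) != 1L)
      return(paste0("transcript ", ids[i], " mixes chromosomes or strands"))
    st <- start(ex)
    if (is.unsorted(st, strictly = TRUE) ||
        any(start(ex)[-1] <= end(ex)[-length(ex)]))
      return(paste0("transcript ", ids[i],
                    " exons must be sorted and non-overlapping"))
    cd <- object@cds[[i]]
    if (length(cd) > 0L) {
      hit <- IRanges::findOverlaps(IRanges(start(cd), end(cd)),
                                   IRanges(st, end(ex)), type = "within")
      if (length(unique(S4Vectors::queryHits(hit))) != length(cd))
        return(paste0("CDS block outside exons in transcript ", ids[i]))
      if (!all(as.character(seqnames(cd)) == as.character(seqnames(ex)[1])) ||
          !all(as.character(strand(cd)) == as.character(strand(ex)[1])))
        return(paste0("CDS chromosome/strand mismatch in transcript ", ids[i]))
    }
  }
  TRUE
})

#' Candidate ORFs as ordered genomic blocks
#'
#' An `OrfSet` stores spliced candidate ORFs: for each ORF the genomic
#' blocks (stop codon included as the last 3 nt, the published catalog BED
#' convention), and per-ORF metadata.
#'
#' @slot blocks A [GRangesList] named by ORF id; blocks sorted by genomic
#'   start, one chromosome and strand per ORF, total width divisible by 3
#'   and at least 6 nt (a minimal start-stop ORF).
#' @slot orfData A [S4Vectors::DataFrame] with one row per ORF:
#'   `orf_id`, `start_codon`, `n_codons` (stop included),
#'   `source_datasets` (a [IRanges::CharacterList]), `legacy_name`,
#'   `host_transcript`, `orf_type` (filled by the catalog pipeline).
#'
#' @seealso [readOrfs()], [collapseIdentical()], [buildCatalog()]
#' @export
setClass("OrfSet",
  representation(blocks = "CompressedGRangesList", orfData = "DataFrame"))

setValidity("OrfSet", function(object) {
  ids <- object@orfData$orf_id
  if (is.null(ids)) return("orfData must have an orf_id column")
  if (anyDuplicated(ids)) return("duplicated ORF ids")
  if (!identical(names(object@blocks), ids))
    return("blocks names must match orfData$orf_id")
  w <- sum(width(object@blocks))
  bad <- w %% 3L != 0L | w < 6L
  if (any(bad))
    return(paste0("ORF length not a multiple of 3 (or < 2 codons): ",
                  paste(ids[bad], collapse = ", ")))
  if (!all(object@orfData$n_codons * 3L == w))
    return("n_codons inconsistent with block lengths")
  TRUE
})

#' Strand-specific per-base P-site counts
#'
#' Sparse single-nucleotide counts over a genome. Each position is the
#' inferred ribosomal P-site of one or more footprints; offset inference
#' happens upstream and is not modelled here.
#'
#' @slot datasetId Label of the (possibly pooled) dataset.
#' @slot counts A width-1 [GRanges] with strand `+`/`-` and an integer
#'   `score` column of positive counts; positions unique per strand.
#'
#' @seealso [readBedgraphPair()], [poolTracks()], [projectTrack()]
#' @export
setClass("PsiteTrack",
  representation(datasetId = "character", counts = "GRanges"))

setValidity("PsiteTrack", function(object) {
  cts <- object@counts
  if (length(cts) == 0L) return(TRUE)
  if (any(width(cts) != 1L)) return("counts must be width-1 positions")
  if (is.null(cts$score) || any(cts$score < 0))
    return("counts need a non-negative score column")
  if (any(as.character(strand(cts)) == "*"))
    return("counts must be stranded")
  key <- paste(seqnames(cts), strand(cts), start(cts))
  if (anyDuplicated(key)) return("duplicated positions on one strand")
  TRUE
})

#' Calibrated pass thresholds for one dataset
#'
#' Per-metric pass thresholds derived from the score distribution of
#' annotated coding sequences, together with the underlying normal-fit
#' parameters (`NA` for the shipped named defaults, whose fits were not
#' republished).
#'
#' @slot datasetId Dataset label the thresholds apply to.
#' @slot fits Numeric matrix, rows `mu`/`sd`, columns `pif`, `uniformity`,
#'   `dropoff`.
#' @slot thresholds Named numeric vector (`pif`, `uniformity`, `dropoff`),
#'   each in `[0, 1]`.
#'
#' @seealso [deriveThresholds()], [defaultThresholds()], [passesThresholds()]
#' @export
setClass("ThresholdSet",
  representation(datasetId = "character", fits = "matrix",
                 thresholds = "numeric"))

setValidity("ThresholdSet", function(object) {
  need <- c("pif", "uniformity", "dropoff")
  if (!identical(names(object@thresholds), need))
    return("thresholds must be named pif, uniformity, dropoff")
  if (any(object@thresholds < 0 | object@thresholds > 1))
    return("thresholds must lie in [0, 1]")
  if (!identical(colnames(object@fits), need) ||
      !identical(rownames(object@fits), c("mu", "sd")))
    return("fits must be a mu/sd x pif/uniformity/dropoff matrix")
  sds <- object@fits["sd", ]
  if (any(!is.na(sds) & sds < 0)) return("fitted sd must be >= 0")
  TRUE
})

#' Stage bookkeeping for a catalog build
#'
#' Conserved accounting of every input ORF through the pipeline stages,
#' plus per-type and per-length-bin summaries of the Comprehensive and
#' Primary sets.
#'
#' @slot counts Named integer vector: `compiled`, `duplicate`, `unmapped`,
#'   `excluded_same_frame_cds`, `excluded_pseudogene`, `unique_sequences`,
#'   `comprehensive`, `primary`. Conservation
#'   `compiled = duplicate + unmapped + excluded + comprehensive` is a
#'   validity requirement.
#' @slot perType data.frame of comprehensive/primary counts per ORF type.
#' @slot perLengthBin data.frame of comprehensive/primary counts per
#'   20-nt length bin (to 500 nt, then open-ended).
#'
#' @seealso [buildCatalog()], [stageCounts()]
#' @export
setClass("CatalogReport",
  representation(counts = "integer", perType = "data.frame",
                 perLengthBin = "data.frame"))

setValidity("CatalogReport", function(object) {
  cnt <- object@counts
  need <- c("compiled", "duplicate", "unmapped", "excluded_same_frame_cds",
            "excluded_pseudogene", "unique_sequences", "comprehensive",
            "primary")
  if (!all(need %in% names(cnt)))
    return(paste("counts must contain:", paste(need, collapse = ", ")))
  if (cnt["compiled"] != cnt["duplicate"] + cnt["unmapped"] +
        cnt["excluded_same_frame_cds"] + cnt["excluded_pseudogene"] +
        cnt["comprehensive"])
    return("stage counts are not conserved")
  if (cnt["unique_sequences"] != cnt["compiled"] - cnt["duplicate"] -
        cnt["unmapped"])
    return("unique_sequences inconsistent with compiled/duplicate/unmapped")
  if (cnt["primary"] > cnt["comprehensive"])
    return("primary cannot exceed comprehensive")
  TRUE
})
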