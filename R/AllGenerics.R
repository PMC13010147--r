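#' @include AllClasses.R
NULL

#' @rdname TranscriptSet-class
#' @param object,x A `TranscriptSet`.
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("txData", function(x) standardGeneric("txData"))

#' @rdname TranscriptSet-class
#' @param id A transcript (or ORF) identifier.
#' @export
setGeneric("exonsOf", function(x, id) standardGeneric("exonsOf"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("cdsOf", function(x, id) standardGeneric("cdsOf"))

#' @rdname OrfSet-class
#' @export
setGeneric("orfIds", function(x) standardGeneric("orfIds"))

#' @rdname OrfSet-class
#' @export
setGeneric("orfData", function(x) standardGeneric("orfData"))

#' @rdname OrfSet-class
#' @export
setGeneric("orfBlocks", function(x, id) standardGeneric("orfBlocks"))

#' @rdname PsiteTrack-class
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname PsiteTrack-class
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname ThresholdSet-class
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname CatalogReport-class
#' @export
setGeneric("stageCounts", function(x, ...) standardGeneric("stageCounts"))

setMethod("transcriptIds", "TranscriptSet", function(x) x@txData$transcript_id)
setMethod("txData", "TranscriptSet", function(x) x@txData)
setMethod("exonsOf", "TranscriptSet", function(x, id) x@exons[[id]])
setMethod("cdsOf", "TranscriptSet", function(x, id) x@cds[[id]])

setMethod("orfIds", "OrfSet", function(x) x@orfData$orf_id)
setMethod("orfData", "OrfSet", function(x) x@orfData)
setMethod("orfBlocks", "OrfSet", function(x, id) {
  if (missing(id)) x@blocks else x@blocks[[id]]
})

setMethod("datasetId", "PsiteTrack", function(x) x@datasetId)
setMethod("librarySize", "PsiteTrack", function(x) {
  if (length(x@counts) == 0L) 0 else sum(as.numeric(x@counts$score))
})

setMethod("thresholds", "ThresholdSet", function(x) x@thresholds)

#' @rdname CatalogReport-class
#' @param x A `CatalogReport`.
#' @param ... Unused.
#' @export
setMethod("stageCounts", "CatalogReport", function(x, ...) x@counts)

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", nrow(object@txData), "transcripts (",
      length(unique(object@txData$gene_id)), "genes )\n")
  tab <- table(object@txData$gene_biotype)
  cat("  gene biotypes:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "OrfSet", function(object) {
  cat("OrfSet with", nrow(object@orfData), "ORFs;",
      "codons (incl. stop):", paste(range(object@orfData$n_codons),
                                    collapse = "-"), "\n")
  if (!all(is.na(object@orfData$orf_type))) {
    tab <- table(object@orfData$orf_type, useNA = "no")
    cat("  types:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "PsiteTrack", function(object) {
  cat("PsiteTrack", sQuote(object@datasetId), "with",
      length(object@counts), "positions,",
      format(librarySize(object), big.mark = ","), "P-sites\n")
})

setMethod("show", "ThresholdSet", function(object) {
  cat("ThresholdSet", sQuote(object@datasetId), "\n")
  print(round(object@thresholds, 4))
})

setMethod("show", "CatalogReport", function(object) {
  cat("CatalogReport\n")
  for (nm in names(object@counts))
    cat(sprintf("  %-24s %d\n", nm, object@counts[[nm]]))
})
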