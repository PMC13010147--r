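#' @include AllClasses.R coordinates.R psite-tracks.R
NULL

#' P-sites-in-frame score
#'
#' PIF is the proportion of an ORF body's P-sites that fall on the
#' translating frame (frame 0, the first base of each codon).
#'
#' @param bodyValues Per-nucleotide P-site counts over the ORF body laid
#'   out codon-wise, so position `i` has frame `(i - 1) %% 3`.
#' @return A fraction in `[0, 1]`, or `NA` when the body has no counts.
#' @seealso [computeUniformity()], [computeDropoff()], [scoreOrf()]
#' @examples
#' computePif(c(5, 1, 0, 2, 1, 1))  # 7/10
#' @export
computePif <- function(bodyValues) {
  tot <- sum(bodyValues)
  if (tot == 0) return(NA_real_)
  frame <- (seq_along(bodyValues) - 1L) %% 3L
  sum(bodyValues[frame == 0L]) / tot
}

#' Uniformity score
#'
#' The fraction of codons showing translation: a codon passes when
#' strictly more than one third of its own P-sites are in frame 0.
#' Codons with zero counts fail (no evidence), so Uniformity rewards
#' periodic signal throughout the ORF's length.
#'
#' @inheritParams computePif
#' @return A fraction in `[0, 1]`, or `NA` when the whole body has no
#'   counts.
#' @export
computeUniformity <- function(bodyValues) {
  if (sum(bodyValues) == 0) return(NA_real_)
  m <- matrix(bodyValues, ncol = 3L, byrow = TRUE)
  tot <- rowSums(m)
  pass <- tot > 0 & m[, 1] / pmax(tot, 1) > 1 / 3
  sum(pass) / nrow(m)
}

#' Drop-off score
#'
#' The sharpness of termination at the stop codon: with B the in-frame
#' P-sites in the window immediately 5' of the stop codon and A the
#' in-frame P-sites in the window immediately 3' of it, Drop-off is
#' `B / (B + A)`. Only positions in the ORF's translating frame count;
#' the stop codon itself belongs to neither window.
#'
#' @param beforeValues,afterValues Per-nucleotide counts over the two
#'   flanking windows (transcript order, 5' to 3').
#' @param beforeFrames,afterFrames Parallel integer frames (0/1/2) of the
#'   window positions relative to the ORF's phase (see [frameOf()]).
#' @return A fraction in `[0, 1]`, or `NA` when `B + A = 0`.
#' @export
computeDropoff <- function(beforeValues, afterValues, beforeFrames,
                           afterFrames) {
  B <- sum(beforeValues[beforeFrames == 0L])
  A <- sum(afterValues[afterFrames == 0L])
  if (B + A == 0) return(NA_real_)
  B / (B + A)
}

#' P-sites per million (PPM)
#'
#' Length-normalized P-site densities scaled so the densities over the
#' whole evaluated universe sum to one million. PPM depends on the
#' universe composition, which the caller controls (the catalog pipeline
#' passes ncORFs plus annotated CDS bodies).
#'
#' @param universe A data.frame with columns `orf_id`, `n_psites`, and
#'   `length` (body length in nt, > 0).
#' @return Named numeric vector of PPM values (all zero when the whole
#'   universe has zero counts).
#' @export
computePpm <- function(universe) {
  if (nrow(universe) == 0L) stop("empty PPM universe")
  stopifnot(all(universe$length > 0))
  dens <- universe$n_psites / universe$length
  tot <- sum(dens)
  ppm <- if (tot == 0) rep(0, nrow(universe)) else 1e6 * dens / tot
  stats::setNames(ppm, universe$orf_id)
}

#' Score one ORF against a P-site track
#'
#' Computes the three translation-signature metrics for an ORF on its
#' host transcript: PIF and Uniformity over the ORF body (sense codons;
#' the stop codon is excluded by default so that terminating-ribosome
#' pileups do not inflate the in-frame totals), and Drop-off over the
#' two `window`-nt transcript flanks of the stop codon.
#'
#' @param orfs An [OrfSet].
#' @param id ORF id.
#' @param tx A [TranscriptSet] containing the ORF's host transcript.
#' @param track A [PsiteTrack].
#' @param host Host transcript id; defaults to the recorded
#'   `host_transcript`.
#' @param window Flank window size in nt (default 15).
#' @param includeStop Include the stop codon in the PIF/Uniformity body
#'   (default `FALSE`).
#' @return A one-row data.frame with `orf_id`, `dataset_id`, `pif`,
#'   `uniformity`, `dropoff`, `n_psites` (body total, all frames).
#' @export
scoreOrf <- function(orfs, id, tx, track, host = NULL, window = 15L,
                     includeStop = FALSE) {
  blocks <- orfBlocks(orfs, id)
  if (is.null(host)) {
    host <- orfData(orfs)$host_transcript[match(id, orfIds(orfs))]
    if (is.na(host)) stop("ORF ", id, " has no assigned host transcript")
  }
  .scoreOrfIdx(id, .blockIndex(blocks), .blockIndex(exonsOf(tx, host)),
               .trackIndex(track), datasetId(track), window, includeStop)
}

.scoreOrfIdx <- function(id, orfIx, hostIx, tIdx, dsId, window = 15L,
                         includeStop = FALSE) {
  p <- .splicedPos(orfIx)
  nBody3 <- if (includeStop) length(p) else length(p) - 3L
  bodyPos <- p[seq_len(nBody3)]
  bodyVals <- .countsAtIdx(tIdx, orfIx$chrom, orfIx$strand, bodyPos)

  fw <- .stopFlanks(orfIx, hostIx, w = window)
  winVals <- function(wdw) {
    if (wdw$size == 0L) return(list(v = numeric(0), f = integer(0)))
    g <- .t2g(hostIx, wdw$start:wdw$end)
    list(v = .countsAtIdx(tIdx, orfIx$chrom, orfIx$strand, g),
         f = .frameOf(orfIx, hostIx, g))
  }
  bef <- winVals(fw$before)
  aft <- winVals(fw$after)

  data.frame(orf_id = id, dataset_id = dsId,
             pif = computePif(bodyVals),
             uniformity = computeUniformity(bodyVals),
             dropoff = computeDropoff(bef$v, aft$v, bef$f, aft$f),
             n_psites = sum(bodyVals),
             stringsAsFactors = FALSE)
}

#' Score every ORF of a set against one or more tracks
#'
#' @inheritParams scoreOrf
#' @param tracks A [PsiteTrack] or list of them.
#' @return A data.frame of signature scores, one row per (ORF, dataset),
#'   with a `ppm` column computed over the universe of the scored ORFs
#'   plus any `cdsUniverse` rows supplied.
#' @param cdsUniverse Optional data.frame (`orf_id`, `n_psites`,
#'   `length`) of annotated CDS bodies to include in the PPM universe,
#'   per dataset (a list named by dataset id, or a single data.frame
#'   reused for all).
#' @export
scoreOrfs <- function(orfs, tx, tracks, window = 15L, includeStop = FALSE,
                      cdsUniverse = NULL) {
  if (is(tracks, "PsiteTrack")) tracks <- list(tracks)
  ids <- orfIds(orfs)
  hosts <- orfData(orfs)$host_transcript
  if (anyNA(hosts))
    stop("unassigned host transcript for: ",
         paste(ids[is.na(hosts)], collapse = ", "))
  orfIdx <- .grlIndex(orfs@blocks)
  hostIdx <- lapply(unique(hosts), function(h) .blockIndex(tx@exons[[h]]))
  names(hostIdx) <- unique(hosts)
  out <- lapply(tracks, function(trk) {
    tIdx <- .trackIndex(trk)
    dsId <- datasetId(trk)
    rows <- do.call(rbind, lapply(seq_along(ids), function(k)
      .scoreOrfIdx(ids[k], orfIdx[[k]], hostIdx[[hosts[k]]], tIdx, dsId,
                   window = window, includeStop = includeStop)))
    bodyLen <- (orfData(orfs)$n_codons - if (includeStop) 0L else 1L) * 3L
    uni <- data.frame(orf_id = rows$orf_id, n_psites = rows$n_psites,
                      length = bodyLen)
    if (!is.null(cdsUniverse)) {
      extra <- if (is.data.frame(cdsUniverse)) cdsUniverse
               else cdsUniverse[[datasetId(trk)]]
      uni <- rbind(uni, extra[, c("orf_id", "n_psites", "length")])
    }
    ppm <- computePpm(uni)
    rows$ppm <- ppm[rows$orf_id]
    rows
  })
  do.call(rbind, out)
}

#' Read-length periodicity QC
#'
#' For each read-length-specific track, aggregates P-sites over the
#' bodies of all annotated CDSs (in CDS phase) and reports the in-frame
#' fraction; a read length is selected when its fraction exceeds
#' `minFraction`.
#'
#' @param tracks Named list of [PsiteTrack]s, one per read length.
#' @param tx A [TranscriptSet]; transcripts with CDS are used.
#' @param minFraction Selection threshold (default 0.60).
#' @return A data.frame with `dataset_id`, `in_frame_fraction` (`NA` when
#'   a length has no CDS coverage) and `selected`.
#' @export
periodicityQc <- function(tracks, tx, minFraction = 0.60) {
  stopifnot(length(tracks) >= 1L)
  txd <- txData(tx)
  withCds <- txd$transcript_id[lengths(tx@cds) > 0]
  if (length(withCds) == 0L) stop("no transcripts with CDS")
  cdsIdx <- lapply(withCds, function(id) .blockIndex(cdsOf(tx, id)))
  res <- lapply(tracks, function(trk) {
    tIdx <- .trackIndex(trk)
    inFrame <- 0
    total <- 0
    for (ix in cdsIdx) {
      p <- .splicedPos(ix)
      vals <- .countsAtIdx(tIdx, ix$chrom, ix$strand, p)
      frame <- (seq_along(p) - 1L) %% 3L
      inFrame <- inFrame + sum(vals[frame == 0L])
      total <- total + sum(vals)
    }
    frac <- if (total == 0) NA_real_ else inFrame / total
    data.frame(dataset_id = datasetId(trk), in_frame_fraction = frac,
               selected = !is.na(frac) && frac > minFraction)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Dump a per-ORF P-site profile
#'
#' Writes (or returns) the per-nucleotide profile of an ORF body plus
#' stop-codon flanks: transcript offset, frame relative to the ORF, and
#' P-site count -- the raw material for single-ORF profile plots.
#'
#' @inheritParams scoreOrf
#' @param path Optional TSV path; when `NULL` the data.frame is returned.
#' @return The profile data.frame (invisibly when written to `path`).
#' @export
psiteProfile <- function(orfs, id, tx, track, host = NULL, window = 15L,
                         path = NULL) {
  blocks <- orfBlocks(orfs, id)
  if (is.null(host)) {
    host <- orfData(orfs)$host_transcript[match(id, orfIds(orfs))]
  }
  p <- splicedPositions(blocks)
  off <- genomeToTranscript(tx, host, p)
  fw <- stopFlankWindows(blocks, tx, host, w = window)
  allOff <- sort(unique(c(off,
                          if (fw$before$size) fw$before$start:fw$before$end,
                          if (fw$after$size) fw$after$start:fw$after$end)))
  g <- transcriptToGenome(tx, host, allOff)
  prof <- data.frame(
    transcript_offset = allOff,
    frame = frameOf(blocks, tx, host, g),
    count = countsAt(track, as.character(seqnames(blocks))[1],
                     as.character(strand(blocks))[1], g))
  if (is.null(path)) return(prof)
  write.table(prof, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prof)
}
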