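#' @include AllClasses.R coordinates.R signatures.R calibration.R
#' @importFrom igraph graph_from_data_frame components make_empty_graph
#' @importFrom stats chisq.test
NULL

orfIdentityKey <- function(blocks) {
  ix <- if (is.list(blocks) && !is.null(blocks$starts)) blocks
        else .blockIndex(blocks)
  paste0(ix$chrom, ":", ix$strand, ":",
         paste(ix$starts, ix$ends, sep = "-", collapse = ","))
}

subsetOrfSet <- function(orfs, keep) {
  new("OrfSet", blocks = orfs@blocks[keep],
      orfData = orfs@orfData[match(keep, orfIds(orfs)), , drop = FALSE])
}

#' Collapse identical ORFs
#'
#' Two records are identical when they share chromosome, strand and the
#' exact block list. Survivors carry the union of the duplicates' source
#' datasets and all their legacy names (first non-missing kept as the
#' primary legacy name).
#'
#' @param orfs An [OrfSet].
#' @return A list with `orfs` (the deduplicated [OrfSet], first
#'   occurrence kept) and `duplicates` (count of removed records).
#' @export
collapseIdentical <- function(orfs) {
  ids <- orfIds(orfs)
  keys <- vapply(.grlIndex(orfs@blocks), orfIdentityKey, "")
  first <- !duplicated(keys)
  od <- orfData(orfs)
  keepIdx <- which(first)
  for (k in keepIdx) {
    grp <- which(keys == keys[k])
    if (length(grp) > 1L) {
      od$source_datasets[[k]] <-
        sort(unique(unlist(od$source_datasets[grp])))
      leg <- od$legacy_name[grp]
      leg <- leg[!is.na(leg)]
      if (length(leg)) od$legacy_name[k] <- leg[1]
    }
  }
  out <- new("OrfSet", blocks = orfs@blocks[keepIdx],
             orfData = od[keepIdx, , drop = FALSE])
  list(orfs = out, duplicates = sum(!first))
}

## Transcripts whose spliced structure contains the ORF as a contiguous
## sub-path (junction-exact compatibility).
compatibleTranscripts <- function(blocks, tx, txIdx = .txIndex(tx)) {
  .compatibleIdx(.blockIndex(blocks), txIdx)
}

.compatibleIdx <- function(orfIx, txIdx) {
  p <- .splicedPos(orfIx)
  ok <- character(0)
  for (id in names(txIdx)) {
    ix <- txIdx[[id]]
    if (ix$chrom != orfIx$chrom || ix$strand != orfIx$strand) next
    if (p[1] < ix$starts[1] || p[1] > ix$ends[length(ix$ends)]) next
    off <- .g2t(ix, p)
    if (anyNA(off)) next
    if (all(diff(off) == 1L)) ok <- c(ok, id)
  }
  ok
}

## Genomic position/phase keys of every CDS base of coding or NMD
## transcripts (phase = codon offset in translation order).
cdsPhaseKeys <- function(tx) {
  txd <- txData(tx)
  sel <- txd$transcript_biotype %in% c("protein_coding",
                                       "nonsense_mediated_decay") &
    lengths(tx@cds) > 0
  cdsIdx <- .grlIndex(tx@cds)
  keys <- lapply(which(sel), function(k) {
    ix <- cdsIdx[[k]]
    p <- .splicedPos(ix)
    paste(ix$chrom, ix$strand, p, (seq_along(p) - 1L) %% 3L)
  })
  unique(unlist(keys))
}

pseudogenePositions <- function(tx) {
  txd <- txData(tx)
  sel <- txd$gene_biotype == "pseudogene"
  exIdx <- .grlIndex(tx@exons)
  keys <- lapply(which(sel), function(k) {
    ix <- exIdx[[k]]
    paste(ix$chrom, ix$strand, .splicedPos(ix))
  })
  unique(unlist(keys))
}

#' Map ORFs to transcripts and apply the catalog exclusions
#'
#' An ORF is *unmapped* when no transcript's exon structure contains its
#' blocks contiguously in spliced space (junction-exact), or when its
#' only compatible transcripts belong to genes of unknown ("other")
#' biotype. Mapped ORFs are then *excluded* when any of their genomic
#' positions coincides, same strand and same codon phase, with a CDS
#' base of a protein-coding or nonsense-mediated-decay transcript
#' (`same_frame_cds`), or when they overlap a pseudogene gene's exons on
#' the same strand in any frame (`pseudogene`).
#'
#' @param orfs An [OrfSet].
#' @param tx A [TranscriptSet].
#' @return A list: `orfs` (kept [OrfSet]), `compatible` (list of
#'   compatible transcript ids per kept ORF), and `excluded` (data.frame
#'   `orf_id`, `reason` with reasons `unmapped`, `same_frame_cds`,
#'   `pseudogene`).
#' @export
mapAndExclude <- function(orfs, tx) {
  ids <- orfIds(orfs)
  cdsKeys <- cdsPhaseKeys(tx)
  psgPos <- pseudogenePositions(tx)
  txd <- txData(tx)
  hostable <- txd$transcript_id[txd$gene_biotype %in%
                                  c("protein_coding", "lncRNA")]
  txIdx <- .txIndex(tx)
  orfIdx <- .grlIndex(orfs@blocks)
  keep <- character(0)
  compat <- list()
  exc <- data.frame(orf_id = character(0), reason = character(0))
  for (id in ids) {
    orfIx <- orfIdx[[id]]
    cand <- .compatibleIdx(orfIx, txIdx)
    if (length(intersect(cand, hostable)) == 0L) {
      exc <- rbind(exc, data.frame(orf_id = id, reason = "unmapped"))
      next
    }
    p <- .splicedPos(orfIx)
    phaseKeys <- paste(orfIx$chrom, orfIx$strand, p,
                       (seq_along(p) - 1L) %% 3L)
    if (any(phaseKeys %in% cdsKeys)) {
      exc <- rbind(exc, data.frame(orf_id = id, reason = "same_frame_cds"))
      next
    }
    if (any(paste(orfIx$chrom, orfIx$strand, p) %in% psgPos)) {
      exc <- rbind(exc, data.frame(orf_id = id, reason = "pseudogene"))
      next
    }
    keep <- c(keep, id)
    compat[[id]] <- intersect(cand, hostable)
  }
  list(orfs = subsetOrfSet(orfs, keep), compatible = compat,
       excluded = exc)
}

#' Choose the host transcript among compatible candidates
#'
#' Priority: readthrough transcripts are demoted below all others; then
#' MANE Select wins; then best (lowest) APPRIS rank (untagged ranks
#' worst); then best (lowest) transcript support level; then
#' protein-coding transcript biotype over non-coding; ties broken
#' deterministically by transcript id.
#'
#' @param tx A [TranscriptSet].
#' @param candidates Non-empty character vector of compatible transcript
#'   ids.
#' @return The chosen transcript id.
#' @export
assignHostTranscript <- function(tx, candidates) {
  if (length(candidates) == 0L) stop("empty candidate transcript set")
  txd <- txData(tx)
  i <- match(candidates, txd$transcript_id)
  if (anyNA(i)) stop("unknown transcript(s): ",
                     paste(candidates[is.na(i)], collapse = ", "))
  appris <- txd$appris_rank[i]
  appris[is.na(appris)] <- max(APPRIS_RANKS) + 1L
  tsl <- txd$tsl[i]
  tsl[is.na(tsl)] <- 6L
  ord <- order(txd$readthrough[i],                 # FALSE first
               !txd$mane_select[i],                # MANE first
               appris, tsl,
               txd$transcript_biotype[i] != "protein_coding",
               candidates)
  candidates[ord[1]]
}

#' Classify an ORF into one of the seven ncORF types
#'
#' Decision order: lncRNA host gene gives `lncRNA-ORF`; a non-coding
#' transcript of a protein-coding gene gives `PT-ORF`; otherwise the
#' ORF's position relative to the host CDS in spliced coordinates gives
#' `uORF` (entirely 5'), `uoORF` (starts 5', overlaps the CDS), `intORF`
#' (within the CDS), `dORF` (entirely 3'), or `doORF` (overlaps the CDS
#' and extends 3' of it). An ORF spanning 5' UTR, CDS and 3' UTR at once
#' is not representable and raises an error.
#'
#' @param orfs An [OrfSet]; or pass `blocks` directly.
#' @param id ORF id.
#' @param tx A [TranscriptSet].
#' @param host Host transcript id.
#' @return One of `"uORF"`, `"uoORF"`, `"intORF"`, `"dORF"`, `"doORF"`,
#'   `"lncRNA-ORF"`, `"PT-ORF"`.
#' @export
classifyOrfType <- function(orfs, id, tx, host) {
  blocks <- if (is(orfs, "OrfSet")) orfBlocks(orfs, id) else orfs
  txd <- txData(tx)
  i <- match(host, txd$transcript_id)
  if (is.na(i)) stop("unknown host transcript: ", host)
  cd <- cdsOf(tx, host)
  .classifyIdx(.blockIndex(blocks), .blockIndex(exonsOf(tx, host)),
               if (length(cd)) .blockIndex(cd) else NULL,
               txd$gene_biotype[i], txd$transcript_biotype[i], id, host)
}

.classifyIdx <- function(orfIx, hostIx, cdsIx, geneBiotype, txBiotype,
                         id, host) {
  if (geneBiotype == "lncRNA") return("lncRNA-ORF")
  if (geneBiotype != "protein_coding")
    stop("transcript ", host, " of gene biotype ", geneBiotype,
         " cannot host an ncORF")
  if (txBiotype != "protein_coding" || is.null(cdsIx)) return("PT-ORF")

  cdsOff <- range(.g2t(hostIx, .splicedPos(cdsIx)))
  orfOff <- range(.g2t(hostIx, .splicedPos(orfIx)))
  oS <- orfOff[1]; oE <- orfOff[2]
  cS <- cdsOff[1]; cE <- cdsOff[2]
  if (oE < cS) return("uORF")
  if (oS > cE) return("dORF")
  if (oS >= cS && oE <= cE) return("intORF")
  if (oS < cS && oE > cE)
    stop("ORF ", if (is.character(id)) id else "", " spans the 5' UTR, ",
         "CDS and 3' UTR of ", host, "; not representable")
  if (oS < cS) "uoORF" else "doORF"
}

#' Cluster ORFs into isoform groups by shared codons
#'
#' Two ORFs are isoforms when they share at least one genomic codon
#' (identical 3 genomic positions, same strand, same intra-codon order);
#' clusters are the connected components of that relation. For each
#' related pair the cluster records whether the pair shares its start
#' codon, its stop codon, and whether the shared codons cover at least
#' 90% of the shorter ORF.
#'
#' @param orfs An [OrfSet].
#' @param overlapFraction Fraction of the shorter ORF's codons that must
#'   be shared for the `overlap_ge` flag (default 0.9).
#' @return A list with `membership` (named integer cluster id per ORF)
#'   and `pairs` (data.frame `orf1`, `orf2`, `shared_codons`,
#'   `shared_start`, `shared_stop`, `overlap_ge`).
#' @export
clusterIsoforms <- function(orfs, overlapFraction = 0.9) {
  ids <- orfIds(orfs)
  codKeys <- lapply(.grlIndex(orfs@blocks), function(ix) {
    m <- matrix(.splicedPos(ix), ncol = 3L, byrow = TRUE)
    paste(ix$chrom, ix$strand, m[, 1], m[, 2], m[, 3])
  })
  names(codKeys) <- ids
  n <- length(ids)
  pairs <- data.frame(orf1 = character(0), orf2 = character(0),
                      shared_codons = integer(0), shared_start = logical(0),
                      shared_stop = logical(0), overlap_ge = logical(0))
  if (n >= 2L) {
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      shared <- intersect(codKeys[[a]], codKeys[[b]])
      if (length(shared) == 0L) next
      ka <- codKeys[[a]]; kb <- codKeys[[b]]
      pairs <- rbind(pairs, data.frame(
        orf1 = ids[a], orf2 = ids[b], shared_codons = length(shared),
        shared_start = ka[1] == kb[1],
        shared_stop = ka[length(ka)] == kb[length(kb)],
        overlap_ge = length(shared) / min(length(ka), length(kb)) >=
          overlapFraction))
    }
  }
  g <- if (nrow(pairs) > 0L)
    graph_from_data_frame(pairs[, c("orf1", "orf2")], directed = FALSE,
                          vertices = ids)
  else graph_from_data_frame(data.frame(from = character(0),
                                        to = character(0)),
                             directed = FALSE, vertices = ids)
  memb <- components(g)$membership[ids]
  list(membership = memb, pairs = pairs)
}

legacyOrdinal <- function(name) {
  m <- regmatches(name, regexec("^c([0-9XYM]+)riboseqorf([0-9]+)$", name))
  vapply(m, function(x) if (length(x) == 3L) as.integer(x[3]) else
    NA_integer_, 1L)
}

legacyChromPrefix <- function(chrom) paste0("c", sub("^chr", "", chrom))

#' Assign catalog names
#'
#' ORFs holding a legacy name of the form `c<chrom>riboseqorf<k>` keep
#' it; remaining ORFs on each chromosome are numbered upwards from the
#' maximum legacy ordinal on that chromosome, in genomic-start order.
#' Legacy names of other forms (e.g. the old `norep` names) are not
#' reused as catalog names but are carried in the `legacy_names` output
#' of the catalog.
#'
#' @param orfs An [OrfSet]; legacy names are taken from its
#'   `legacy_name` column.
#' @return Named character vector mapping orf_id to catalog name.
#' @export
assignNames <- function(orfs) {
  od <- orfData(orfs)
  ids <- od$orf_id
  legacy <- od$legacy_name
  dup <- legacy[!is.na(legacy)][duplicated(legacy[!is.na(legacy)])]
  if (length(dup)) stop("duplicate legacy names: ",
                        paste(unique(dup), collapse = ", "))
  idx <- .grlIndex(orfs@blocks)
  chrom <- vapply(idx, function(ix) ix$chrom, "")
  startPos <- vapply(idx, function(ix) ix$starts[1], 1L)
  ord <- legacyOrdinal(legacy)
  nm <- ifelse(!is.na(ord), legacy, NA_character_)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    k <- max(c(0L, ord[sel]), na.rm = TRUE)
    todo <- which(sel & is.na(nm))
    todo <- todo[order(startPos[todo], ids[todo])]
    for (i in todo) {
      k <- k + 1L
      nm[i] <- paste0(legacyChromPrefix(ch), "riboseqorf", k)
    }
  }
  if (anyDuplicated(nm)) stop("name collision while assigning names")
  setNames(nm, ids)
}

lengthBinLabel <- function(lenNt, binWidth = 20L, maxNt = 500L) {
  lo <- pmin((pmax(lenNt, 1L) - 1L) %/% binWidth * binWidth, maxNt)
  ifelse(lo >= maxNt, paste0(">", maxNt),
         paste0(lo + 1L, "-", lo + binWidth))
}

#' Catalog stage accounting
#'
#' The bookkeeping identity of the catalog pipeline: starting from the
#' compiled record count, removing unmapped records and duplicates gives
#' the unique-sequence count, and removing the same-frame-CDS and
#' pseudogene exclusions gives the Comprehensive set.
#'
#' @param compiled Total input records.
#' @param unmapped Records not mappable to any transcript.
#' @param duplicates Identical-sequence records removed by collapsing.
#' @param excluded Same-frame CDS / pseudogene exclusions (scalar or
#'   vector, summed).
#' @param primary Optional Primary-set size.
#' @return Named integer vector with `unique_sequences` and
#'   `comprehensive` derived from the inputs.
#' @export
stageArithmetic <- function(compiled, unmapped, duplicates, excluded,
                            primary = NA_integer_) {
  uniq <- compiled - unmapped - duplicates
  comp <- uniq - sum(excluded)
  if (comp < 0) stop("stage counts are not conserved")
  c(compiled = as.integer(compiled), unmapped = as.integer(unmapped),
    duplicates = as.integer(duplicates), excluded = as.integer(sum(excluded)),
    unique_sequences = as.integer(uniq), comprehensive = as.integer(comp),
    primary = as.integer(primary))
}

#' Retention accounting against a previous catalog
#'
#' @param previousTotal Size of the previous catalog.
#' @param removed Integer vector of per-reason removal counts.
#' @return Number of previous-catalog ORFs retained.
#' @export
retainedFromPrevious <- function(previousTotal, removed) {
  out <- previousTotal - sum(removed)
  if (out < 0) stop("removed more than the previous total")
  as.integer(out)
}

#' Composition percentage at printed precision
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal digits to round the percentage to.
#' @return `round(100 * numerator / denominator, digits)`.
#' @export
compositionPct <- function(numerator, denominator, digits = 1L) {
  round(100 * numerator / denominator, digits)
}

#' Compare pass rates between two strata
#'
#' Recomputes the stratified pass percentages and the chi-square test of
#' equal proportions from the two numerator/denominator pairs.
#'
#' @param pass1,n1 Passing and total counts in stratum 1.
#' @param pass2,n2 Same for stratum 2.
#' @param digits Decimal digits for the percentages.
#' @param correct Yates continuity correction (default `FALSE`).
#' @return List with `pct1`, `pct2`, `statistic`, `p_value`.
#' @export
passRateComparison <- function(pass1, n1, pass2, n2, digits = 2L,
                               correct = FALSE) {
  tab <- matrix(c(pass1, n1 - pass1, pass2, n2 - pass2), nrow = 2,
                byrow = TRUE)
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(pct1 = compositionPct(pass1, n1, digits),
       pct2 = compositionPct(pass2, n2, digits),
       statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Build the Comprehensive and Primary catalogs
#'
#' Runs the full pipeline: collapse identical records, map to the
#' annotation and apply the same-frame-CDS / pseudogene exclusions,
#' assign host transcripts, classify into the seven ncORF types, score
#' each ORF in every dataset, compute PPM over the universe of kept
#' ORFs plus annotated CDS bodies, apply the pass thresholds and the
#' any-dataset Primary rule, cluster isoforms, assign catalog names,
#' and account for every input record.
#'
#' @param orfs An [OrfSet] of compiled candidate ORFs.
#' @param tx A [TranscriptSet].
#' @param tracks List of [PsiteTrack]s (one per test dataset).
#' @param thresholds List of [ThresholdSet]s, named by dataset id (or a
#'   single set). Datasets without thresholds raise an error.
#' @param window Drop-off flank size in nt.
#' @param includeStop Include the stop codon in PIF/Uniformity bodies.
#' @param overlapFraction Isoform overlap flag fraction.
#' @return A list with `records` (the catalog data.frame), `orfs` (the
#'   Comprehensive [OrfSet] with hosts and types filled), `report` (a
#'   [CatalogReport]), `scores` (long per-dataset score table),
#'   `excluded` (stage exclusion list with reasons) and `clusters`.
#' @export
buildCatalog <- function(orfs, tx, tracks, thresholds, window = 15L,
                         includeStop = FALSE, overlapFraction = 0.9) {
  if (is(tracks, "PsiteTrack")) tracks <- list(tracks)
  if (is(thresholds, "ThresholdSet")) {
    if (length(tracks) == 1L) {
      # a single threshold set applies to the single dataset
      thresholds@datasetId <- datasetId(tracks[[1]])
    }
    thresholds <- setNames(list(thresholds), thresholds@datasetId)
  }
  compiled <- length(orfIds(orfs))

  col <- collapseIdentical(orfs)
  mp <- mapAndExclude(col$orfs, tx)
  kept <- mp$orfs
  ids <- orfIds(kept)

  od <- orfData(kept)
  od$host_transcript <- vapply(ids, function(i)
    assignHostTranscript(tx, mp$compatible[[i]]), "")
  txd0 <- txData(tx)
  txIdx <- .txIndex(tx)
  cdsIdxAll <- .grlIndex(tx@cds)
  keptIdx <- .grlIndex(kept@blocks)
  od$orf_type <- vapply(seq_along(ids), function(k) {
    host <- od$host_transcript[k]
    j <- match(host, txd0$transcript_id)
    .classifyIdx(keptIdx[[k]], txIdx[[host]], cdsIdxAll[[j]],
                 txd0$gene_biotype[j], txd0$transcript_biotype[j],
                 ids[k], host)
  }, "")
  kept <- new("OrfSet", blocks = kept@blocks, orfData = od)

  # annotated CDS bodies join the PPM universe, per dataset
  txd <- txData(tx)
  cdsTx <- txd$transcript_id[txd$transcript_biotype == "protein_coding" &
                               lengths(tx@cds) > 0]
  cdsIdx <- lapply(cdsTx, function(tid) .blockIndex(cdsOf(tx, tid)))
  cdsUniverse <- lapply(tracks, function(trk) {
    tIdx <- .trackIndex(trk)
    rows <- lapply(seq_along(cdsTx), function(k) {
      ix <- cdsIdx[[k]]
      pos <- .splicedPos(ix)
      data.frame(orf_id = paste0("CDS:", cdsTx[k]),
                 n_psites = sum(.countsAtIdx(tIdx, ix$chrom, ix$strand,
                                             pos)),
                 length = length(pos))
    })
    do.call(rbind, rows)
  })
  names(cdsUniverse) <- vapply(tracks, datasetId, "")

  scores <- if (length(ids))
    scoreOrfs(kept, tx, tracks, window = window, includeStop = includeStop,
              cdsUniverse = cdsUniverse)
  else data.frame(orf_id = character(0), dataset_id = character(0),
                  pif = numeric(0), uniformity = numeric(0),
                  dropoff = numeric(0), n_psites = numeric(0),
                  ppm = numeric(0))

  dsIds <- vapply(tracks, datasetId, "")
  missingThr <- setdiff(dsIds, names(thresholds))
  if (length(missingThr))
    stop("no thresholds for dataset(s): ",
         paste(missingThr, collapse = ", "))
  scores$pass <- FALSE
  for (ds in dsIds) {
    sel <- scores$dataset_id == ds
    scores$pass[sel] <- passesThresholds(scores[sel, , drop = FALSE],
                                         thresholds[[ds]])
  }
  passAny <- vapply(ids, function(i) {
    fl <- scores$pass[scores$orf_id == i]
    if (length(fl) == 0L) FALSE else selectPrimary(fl)
  }, TRUE)
  ppmAny <- vapply(ids, function(i)
    any(scores$ppm[scores$orf_id == i] > 1), TRUE)

  clusters <- clusterIsoforms(kept, overlapFraction = overlapFraction)
  catalogNames <- if (length(ids)) assignNames(kept) else character(0)

  bodyLenNt <- (orfData(kept)$n_codons - 1L) * 3L
  records <- data.frame(
    orf_id = ids,
    name = unname(catalogNames[ids]),
    host_transcript = orfData(kept)$host_transcript,
    gene_id = txd$gene_id[match(orfData(kept)$host_transcript,
                                txd$transcript_id)],
    orf_type = orfData(kept)$orf_type,
    start_codon = orfData(kept)$start_codon,
    n_codons = orfData(kept)$n_codons,
    length_nt = bodyLenNt,
    primary = unname(passAny),
    ppm_gt1_any = unname(ppmAny),
    isoform_cluster = unname(clusters$membership[ids]),
    source_datasets = vapply(orfData(kept)$source_datasets,
                             paste, "", collapse = ","),
    legacy_names_v35 = orfData(kept)$legacy_name,
    stringsAsFactors = FALSE)
  for (ds in dsIds) {
    s <- scores[scores$dataset_id == ds, , drop = FALSE]
    j <- match(ids, s$orf_id)
    for (m in c("pif", "uniformity", "dropoff", "ppm", "n_psites", "pass"))
      records[[paste0(m, ".", ds)]] <- s[[m]][j]
  }

  excTab <- table(factor(mp$excluded$reason,
                         levels = c("unmapped", "same_frame_cds",
                                    "pseudogene")))
  counts <- c(compiled = compiled,
              duplicate = col$duplicates,
              unmapped = as.integer(excTab[["unmapped"]]),
              excluded_same_frame_cds = as.integer(
                excTab[["same_frame_cds"]]),
              excluded_pseudogene = as.integer(excTab[["pseudogene"]]),
              unique_sequences = compiled - col$duplicates -
                as.integer(excTab[["unmapped"]]),
              comprehensive = length(ids),
              primary = sum(passAny))
  perType <- as.data.frame(table(orf_type = records$orf_type),
                           stringsAsFactors = FALSE)
  names(perType)[2] <- "comprehensive"
  pt <- table(records$orf_type[records$primary])
  perType$primary <- as.integer(pt[perType$orf_type])
  perType$primary[is.na(perType$primary)] <- 0L

  bins <- lengthBinLabel(records$length_nt)
  perBin <- as.data.frame(table(length_bin = bins), stringsAsFactors = FALSE)
  names(perBin)[2] <- "comprehensive"
  pb <- table(bins[records$primary])
  perBin$primary <- as.integer(pb[perBin$length_bin])
  perBin$primary[is.na(perBin$primary)] <- 0L

  report <- new("CatalogReport", counts = counts, perType = perType,
                perLengthBin = perBin)
  validObject(report)
  list(records = records, orfs = kept, report = report, scores = scores,
       excluded = mp$excluded, clusters = clusters)
}
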