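#' @include AllClasses.R constructors.R coordinates.R psite-tracks.R
#' @importFrom stats rgamma rpois rmultinom
#' @importFrom Biostrings DNAStringSet writeXStringSet readDNAStringSet
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic benchmark: a toy genome with spliced
#' multi-exon transcripts of every relevant biotype, planted ORFs of all
#' seven types plus decoys, and P-site tracks with tunable frame
#' fidelity, per-codon intensity dispersion and post-stop leakage.
#'
#' Defaults describe a deep pooled dataset: frame fidelity 0.85 (the
#' overall 3-nt periodicity of a large pooled body-map resource), 20
#' P-sites per codon on average with gamma-shape-1 (exponential)
#' per-codon variability, and 5% post-stop leakage.
#'
#' @param seed Integer RNG seed.
#' @param nCodingGenes Number of coding genes (>= 2 exercises every
#'   assignment branch).
#' @param frameFidelity Probability `f` that a P-site falls on frame 0
#'   of its codon.
#' @param psitesPerCodon Mean P-sites per sense codon.
#' @param dispersion Gamma shape of the per-codon intensity (smaller =
#'   more dispersed).
#' @param postStopLeakage Expected in-frame after-window count as a
#'   fraction `lambda` of the realized in-frame before-window count;
#'   expected Drop-off is `1 / (1 + lambda)`.
#' @param includeCdsSignal Simulate translation over annotated CDSs too
#'   (needed for calibration and periodicity QC).
#' @return A named list of class `simConfig`.
#' @export
simConfig <- function(seed = 1L, nCodingGenes = 2L, frameFidelity = 0.85,
                      psitesPerCodon = 20, dispersion = 1,
                      postStopLeakage = 0.05, includeCdsSignal = TRUE) {
  stopifnot(frameFidelity >= 0, frameFidelity <= 1, psitesPerCodon >= 0,
            dispersion > 0, postStopLeakage >= 0, nCodingGenes >= 1)
  structure(list(seed = as.integer(seed),
                 nCodingGenes = as.integer(nCodingGenes),
                 frameFidelity = frameFidelity,
                 psitesPerCodon = psitesPerCodon,
                 dispersion = dispersion,
                 postStopLeakage = postStopLeakage,
                 includeCdsSignal = includeCdsSignal),
            class = "simConfig")
}

GENE_SPACING <- 7000L
CODING_ANCHOR0 <- 1000L

## Transcript-offset layout of the planted features on the coding-gene
## template (exons 1-300, 501-1100, 1401-2200 relative to anchor;
## spliced length 1700; CDS offsets 401-1300).
CODING_LAYOUT <- list(
  uORF = c(271L, 330L),        # spans the exon1/exon2 junction
  uoORF = c(382L, 441L),       # alt frame over the CDS start
  intORF = c(502L, 561L),      # alt frame inside the CDS
  dORF = c(1350L, 1409L),
  doORF = c(1270L, 1329L),     # alt frame over the CDS end
  minimal = c(50L, 55L),       # start-stop uORF
  frameshift = c(131L, 190L),  # true uORF geometry, frame-1 signal
  zerocov = c(1450L, 1494L),   # dORF geometry, never covered
  clone = c(431L, 490L))       # same-frame sub-interval of the CDS

codingGeneModel <- function(anchor, strandChar, chrom) {
  ex <- GRanges(chrom,
                IRanges(anchor + c(0L, 500L, 1400L),
                        anchor + c(299L, 1099L, 2199L)),
                strand = strandChar)
  ex
}

#' Simulate a toy annotation with planted ORFs and known truth
#'
#' Builds a deterministic toy genome: `nCodingGenes` three-exon coding
#' genes on chr1 (alternating strands; gene 1 additionally carries a
#' retained-intron non-coding transcript hosting a PT-ORF, gene 2 two
#' extra isoforms exercising the APPRIS/TSL and readthrough assignment
#' branches, and an intronic decoy), plus a two-exon lncRNA gene and an
#' overlapping pseudogene on chr2. Each coding gene carries planted
#' uORF, uoORF, intORF, dORF, doORF and a minimal start-stop ORF, along
#' with frame-shifted, zero-coverage and same-frame-CDS-clone decoys;
#' the lncRNA gene carries two isoform lncRNA-ORFs sharing their stop
#' codon and a pseudogene-overlapping decoy. Two duplicate records from
#' a second synthetic study exercise the collapse stage.
#'
#' @param config A [simConfig()].
#' @return A list with `genome` (a [Biostrings::DNAStringSet]), `tx`
#'   ([TranscriptSet]), `orfs` ([OrfSet] of compiled candidate records,
#'   duplicates included), and `truth` (data.frame: `orf_id`, `gene_id`,
#'   `expected_host`, `expected_type`, `decoy`, `expected_stage`).
#' @seealso [simulatePsites()], [writeSimulation()]
#' @export
simulateAnnotation <- function(config = simConfig()) {
  set.seed(config$seed)
  nGenes <- config$nCodingGenes

  exons <- list(); cds <- list(); txrows <- list()
  blocks <- list(); startCodons <- character(0); sources <- list()
  truth <- list()

  addTx <- function(id, gene, gbio, tbio, ex, cd = NULL, mane = FALSE,
                    appris = NA_integer_, tsl = NA_integer_,
                    readthrough = FALSE) {
    exons[[id]] <<- ex
    if (!is.null(cd)) cds[[id]] <<- cd
    txrows[[id]] <<- data.frame(transcript_id = id, gene_id = gene,
                                gene_biotype = gbio,
                                transcript_biotype = tbio,
                                mane_select = mane, appris_rank = appris,
                                tsl = tsl, readthrough = readthrough)
  }

  for (g in seq_len(nGenes)) {
    anchor <- CODING_ANCHOR0 + (g - 1L) * GENE_SPACING
    strandChar <- if (g %% 2L == 1L) "+" else "-"
    gid <- paste0("SIMG", g)
    tid <- paste0("SIMT", g)
    ex <- codingGeneModel(anchor, strandChar, "chr1")
    addTx(tid, gid, "protein_coding", "protein_coding", ex,
          mane = (g != 2L), appris = if (g == 2L) 2L else 1L,
          tsl = 1L)
    if (g == 2L) {
      addTx(paste0(tid, "c"), gid, "protein_coding", "protein_coding",
            ex, appris = 2L, tsl = 2L)
      addTx(paste0(tid, "r"), gid, "protein_coding", "protein_coding",
            ex, appris = 1L, tsl = 1L, readthrough = TRUE)
    }
    if (g == 1L) {
      exRI <- GRanges("chr1", IRanges(anchor + c(0L, 500L),
                                      anchor + c(299L, 2199L)),
                      strand = strandChar)
      addTx(paste0(tid, "b"), gid, "protein_coding", "retained_intron",
            exRI)
    }
  }

  # lncRNA gene + overlapping pseudogene on chr2
  lncEx <- GRanges("chr2", IRanges(c(2000L, 2600L), c(2399L, 2999L)),
                   strand = "+")
  addTx("SIMTL", "SIMGL", "lncRNA", "lncRNA", lncEx, tsl = 1L)
  psgEx <- GRanges("chr2", IRanges(2180L, 2299L), strand = "+")
  addTx("SIMTP", "SIMGP", "pseudogene", "processed_pseudogene", psgEx)

  txData <- do.call(rbind, txrows)
  tx <- TranscriptSet(exons = exons, cds = list(), txData = txData)
  # CDS blocks come from transcript offsets 401-1300 of each coding gene
  for (g in seq_len(nGenes)) {
    tid <- paste0("SIMT", g)
    cd <- offsetsToBlocks(tx, tid, 401L, 1300L)
    cds[[tid]] <- cd
    if (g == 2L) {
      cds[[paste0(tid, "c")]] <- cd
      cds[[paste0(tid, "r")]] <- cd
    }
  }
  tx <- TranscriptSet(exons = exons, cds = cds, txData = txData)

  addOrf <- function(id, bl, startCodon, gene, host, type, decoy,
                     stage, study = "study1") {
    blocks[[id]] <<- bl
    startCodons[id] <<- startCodon
    sources[[id]] <<- study
    truth[[id]] <<- data.frame(orf_id = id, gene_id = gene,
                               expected_host = host, expected_type = type,
                               decoy = decoy, expected_stage = stage)
  }

  for (g in seq_len(nGenes)) {
    gid <- paste0("SIMG", g)
    tid <- paste0("SIMT", g)
    host <- tid  # MANE (g odd) or TSL winner (g = 2: SIMT2 has tsl 1)
    types <- c(uORF = "uORF", uoORF = "uoORF", intORF = "intORF",
               dORF = "dORF", doORF = "doORF", minimal = "uORF")
    # alt-frame ORFs overlapping the CDS inherit mixed periodic signal,
    # so the truth table only promises them the Comprehensive set
    stage <- c(uORF = "primary_eligible", uoORF = "comprehensive",
               intORF = "comprehensive", dORF = "primary_eligible",
               doORF = "comprehensive", minimal = "primary_eligible")
    for (nm in names(types)) {
      rngOff <- CODING_LAYOUT[[nm]]
      addOrf(paste0(gid, "_", nm),
             offsetsToBlocks(tx, tid, rngOff[1], rngOff[2]),
             if (nm == "uoORF") "CTG" else "ATG",
             gid, host, types[[nm]], "none", stage[[nm]])
    }
    addOrf(paste0(gid, "_frameshift"),
           offsetsToBlocks(tx, tid, CODING_LAYOUT$frameshift[1],
                           CODING_LAYOUT$frameshift[2]),
           "ATG", gid, host, "uORF", "frameshift", "comprehensive_only")
    addOrf(paste0(gid, "_zerocov"),
           offsetsToBlocks(tx, tid, CODING_LAYOUT$zerocov[1],
                           CODING_LAYOUT$zerocov[2]),
           "ATG", gid, host, "dORF", "zero_coverage", "comprehensive_only")
    addOrf(paste0(gid, "_clone"),
           offsetsToBlocks(tx, tid, CODING_LAYOUT$clone[1],
                           CODING_LAYOUT$clone[2]),
           "ATG", gid, host, NA_character_, "same_frame_cds", "excluded")
    if (g == 1L) {
      anchor <- CODING_ANCHOR0
      addOrf("SIMG1_PT",
             GRanges("chr1", IRanges(anchor + 1150L, anchor + 1209L),
                     strand = "+"),
             "ATG", gid, paste0(tid, "b"), "PT-ORF", "none",
             "primary_eligible")
    }
    if (g == 2L) {
      anchor <- CODING_ANCHOR0 + GENE_SPACING
      addOrf("SIMG2_intronic",
             GRanges("chr1", IRanges(anchor + 350L, anchor + 409L),
                     strand = "-"),
             "ATG", gid, NA_character_, NA_character_, "intronic",
             "unmapped")
    }
  }

  addOrf("SIMGL_lncA", offsetsToBlocks(tx, "SIMTL", 101L, 160L), "ATG",
         "SIMGL", "SIMTL", "lncRNA-ORF", "none", "primary_eligible")
  addOrf("SIMGL_lncB", offsetsToBlocks(tx, "SIMTL", 131L, 160L), "GTG",
         "SIMGL", "SIMTL", "lncRNA-ORF", "none", "primary_eligible")
  addOrf("SIMGL_psg", offsetsToBlocks(tx, "SIMTL", 201L, 260L), "ATG",
         "SIMGL", NA_character_, NA_character_, "pseudogene", "excluded")

  # duplicate records from a second synthetic study
  addOrf("SIMG1_uORF_dup2", blocks[["SIMG1_uORF"]], "ATG", "SIMG1",
         "SIMT1", "uORF", "duplicate", "duplicate", study = "study2")
  if (nGenes >= 2L)
    addOrf("SIMG2_dORF_dup2", blocks[["SIMG2_dORF"]], "ATG", "SIMG2",
           "SIMT2", "dORF", "duplicate", "duplicate", study = "study2")

  orfs <- OrfSet(blocks, startCodon = unname(startCodons[names(blocks)]),
                 sourceDatasets = sources[names(blocks)])

  chromLen <- c(chr1 = CODING_ANCHOR0 + nGenes * GENE_SPACING + 3000L,
                chr2 = 6000L)
  genome <- lapply(chromLen, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  plant <- function(bl, senseBases) {
    chrom <- as.character(seqnames(bl))[1]
    pos <- splicedPositions(bl)
    bases <- strsplit(senseBases, "")[[1]]
    if (as.character(strand(bl))[1] == "-") bases <- comp[bases]
    genome[[chrom]][pos[seq_along(bases)]] <<- bases
    genome[[chrom]][pos[(length(pos) - 2L):length(pos)]] <<-
      if (as.character(strand(bl))[1] == "-") comp[c("T", "G", "A")]
      else c("T", "G", "A")
  }
  for (id in names(blocks)) plant(blocks[[id]], startCodons[[id]])
  for (tid in names(cds)) plant(cds[[tid]], "ATG")
  genome <- DNAStringSet(vapply(genome, paste, "", collapse = ""))

  list(genome = genome, tx = tx, orfs = orfs,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       config = config)
}

#' Simulate P-site tracks over a simulated annotation
#'
#' Per sense codon of each covered planted ORF (and, optionally, of each
#' annotated CDS), an intensity is drawn from a gamma distribution with
#' the configured mean and shape, the codon's P-site count from a
#' Poisson of that intensity, and the counts are placed multinomially on
#' the codon's three bases: frame 0 with probability `f`, frames 1 and 2
#' with `(1 - f) / 2` each (frame-shifted decoys get the rotated
#' probabilities, peaking on frame 1). In-frame reads are then added to
#' the 15-nt window after each stop codon at a Poisson rate of `lambda`
#' times the realized in-frame count in the 15-nt window before it, so
#' the expected Drop-off is `1 / (1 + lambda)`. Zero-coverage decoys
#' receive nothing.
#'
#' @param sim Result of [simulateAnnotation()].
#' @param datasetId Track label.
#' @param seed RNG seed (defaults to the simulation's seed).
#' @param frameFidelity,psitesPerCodon,dispersion,postStopLeakage
#'   Overrides of the simulation config.
#' @return A [PsiteTrack].
#' @export
simulatePsites <- function(sim, datasetId = "simdata",
                           seed = sim$config$seed,
                           frameFidelity = sim$config$frameFidelity,
                           psitesPerCodon = sim$config$psitesPerCodon,
                           dispersion = sim$config$dispersion,
                           postStopLeakage = sim$config$postStopLeakage) {
  set.seed(seed)
  f <- frameFidelity
  chromV <- character(0); posV <- integer(0); strandV <- character(0)
  countV <- integer(0)
  emit <- function(chrom, pos, strandChar, count) {
    keep <- count > 0
    chromV <<- c(chromV, rep(chrom, sum(keep)))
    posV <<- c(posV, pos[keep])
    strandV <<- c(strandV, rep(strandChar, sum(keep)))
    countV <<- c(countV, count[keep])
  }

  txIdx <- .txIndex(sim$tx)
  orfIdx <- .grlIndex(sim$orfs@blocks)

  simulateBody <- function(ix, host, shifted) {
    cod <- matrix(.splicedPos(ix), ncol = 3L, byrow = TRUE)
    nSense <- nrow(cod) - 1L
    if (nSense < 1L) return(invisible())
    chrom <- ix$chrom
    strandChar <- ix$strand
    lam <- rgamma(nSense, shape = dispersion,
                  scale = psitesPerCodon / dispersion)
    nPer <- rpois(nSense, lam)
    probs <- if (shifted) c((1 - f) / 2, f, (1 - f) / 2)
             else c(f, (1 - f) / 2, (1 - f) / 2)
    placed <- matrix(0L, nSense, 3L)
    for (i in seq_len(nSense)) {
      if (nPer[i] > 0)
        placed[i, ] <- as.integer(rmultinom(1, nPer[i], probs))
    }
    emit(chrom, as.vector(t(cod[seq_len(nSense), , drop = FALSE])),
         strandChar, as.vector(t(placed)))
    # post-stop leakage, in the ORF's frame
    if (postStopLeakage > 0 && !is.na(host)) {
      hostIx <- txIdx[[host]]
      fw <- .stopFlanks(ix, hostIx)
      if (fw$before$size > 0L && fw$after$size > 0L) {
        befOff <- fw$before$start:fw$before$end
        befG <- .t2g(hostIx, befOff)
        befFr <- .frameOf(ix, hostIx, befG)
        inOrf <- match(befG, as.vector(t(cod[seq_len(nSense), ,
                                             drop = FALSE])))
        bodyFlat <- as.vector(t(placed))
        B <- sum(bodyFlat[inOrf[befFr == 0L & !is.na(inOrf)]])
        if (B > 0) {
          aftOff <- fw$after$start:fw$after$end
          aftG <- .t2g(hostIx, aftOff)
          aftFr <- .frameOf(ix, hostIx, aftG)
          targets <- aftG[aftFr == 0L]
          A <- rpois(1, postStopLeakage * B)
          if (A > 0 && length(targets) > 0) {
            alloc <- as.integer(rmultinom(1, A,
                                          rep(1, length(targets))))
            emit(chrom, targets, strandChar, alloc)
          }
        }
      }
    }
  }

  truth <- sim$truth
  for (i in seq_len(nrow(truth))) {
    d <- truth$decoy[i]
    if (d %in% c("zero_coverage", "duplicate", "same_frame_cds")) next
    simulateBody(orfIdx[[truth$orf_id[i]]],
                 truth$expected_host[i], shifted = d == "frameshift")
  }
  if (sim$config$includeCdsSignal) {
    for (g in seq_len(sim$config$nCodingGenes)) {
      tid <- paste0("SIMT", g)
      simulateBody(.blockIndex(cdsOf(sim$tx, tid)), tid, shifted = FALSE)
    }
  }
  psiteTrack(datasetId, chromV, posV, strandV, countV)
}

#' Write a simulation to standard formats
#'
#' Emits the annotation as GTF, the compiled ORFs as BED12 plus a
#' metadata TSV, the genome as FASTA, the truth table as TSV, and a
#' P-site bedGraph pair per requested dataset.
#'
#' @param sim Result of [simulateAnnotation()].
#' @param dir Output directory (created if needed).
#' @param datasets Character vector of dataset labels to simulate tracks
#'   for (seeds `seed`, `seed + 1`, ...).
#' @return Named list of written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir, datasets = "simdata") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    gtf = file.path(dir, "annotation.gtf"),
    bed = file.path(dir, "orfs.bed"),
    meta = file.path(dir, "orfs_meta.tsv"),
    fasta = file.path(dir, "genome.fa"),
    truth = file.path(dir, "truth.tsv"))
  writeAnnotation(sim$tx, paths$gtf)
  writeOrfs(sim$orfs, paths$bed)
  od <- orfData(sim$orfs)
  write.table(data.frame(name = od$orf_id, start_codon = od$start_codon,
                         source_datasets = vapply(od$source_datasets,
                                                  paste, "",
                                                  collapse = ","),
                         legacy_name = od$legacy_name),
              paths$meta, sep = "\t", quote = FALSE, row.names = FALSE)
  writeXStringSet(sim$genome, paths$fasta)
  write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (k in seq_along(datasets)) {
    ds <- datasets[k]
    trk <- simulatePsites(sim, datasetId = ds,
                          seed = sim$config$seed + k - 1L)
    pp <- file.path(dir, paste0(ds, "_plus.bedgraph"))
    mp <- file.path(dir, paste0(ds, "_minus.bedgraph"))
    writeBedgraphPair(trk, pp, mp)
    paths[[paste0(ds, "_plus")]] <- pp
    paths[[paste0(ds, "_minus")]] <- mp
  }
  invisible(paths)
}

#' Verify recorded start codons against a genome
#'
#' @param orfs An [OrfSet] with `start_codon` metadata.
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @return Logical vector per ORF (`NA` where no start codon is
#'   recorded).
#' @export
verifyStartCodons <- function(orfs, genome) {
  ids <- orfIds(orfs)
  expected <- orfData(orfs)$start_codon
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  got <- vapply(ids, function(i) {
    bl <- orfBlocks(orfs, i)
    pos <- splicedPositions(bl)[1:3]
    chrom <- as.character(seqnames(bl))[1]
    b <- strsplit(as.character(genome[[chrom]]), "")[[1]][pos]
    if (as.character(strand(bl))[1] == "-") b <- comp[b]
    paste(b, collapse = "")
  }, "")
  out <- got == expected
  out[is.na(expected)] <- NA
  setNames(out, ids)
}
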