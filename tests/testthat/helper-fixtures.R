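suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

gr <- function(chrom, starts, ends, strand) {
  GRanges(chrom, IRanges(starts, ends), strand = strand)
}

## Two-exon transcript: exons 1-100 and 201-300 (1-based closed),
## spliced length 200; optional CDS over spliced offsets 31-90.
twoExonTx <- function(strandChar = "+", withCds = TRUE,
                      id = "TXP", gene = "GP") {
  ex <- gr("chr1", c(1, 201), c(100, 300), strandChar)
  cds <- if (!withCds) NULL
    else if (strandChar == "+") gr("chr1", 31, 90, strandChar)
    else gr("chr1", 211, 270, strandChar)
  TranscriptSet(
    exons = setNames(list(ex), id),
    cds = if (is.null(cds)) list() else setNames(list(cds), id),
    txData = data.frame(transcript_id = id, gene_id = gene,
                        gene_biotype = "protein_coding",
                        transcript_biotype = "protein_coding"))
}

## Brute-force spliced enumeration, written directly from the exon
## ranges: genomic positions in 5'->3' transcript order. Independent of
## the package's arithmetic implementation.
bfSplicedPositions <- function(exonsGR) {
  s <- start(exonsGR); e <- end(exonsGR)
  o <- order(s)
  pos <- unlist(lapply(o, function(i) s[i]:e[i]))
  if (as.character(strand(exonsGR))[1] == "-") rev(pos) else pos
}

bfGenomeToTranscript <- function(exonsGR, g) {
  match(g, bfSplicedPositions(exonsGR))
}

bfOrfCodons <- function(blocksGR) {
  p <- bfSplicedPositions(blocksGR)
  matrix(p, ncol = 3, byrow = TRUE)
}

## A track from explicit (pos, count) pairs on one chrom/strand.
trackFrom <- function(pos, count, chrom = "chr1", strandChar = "+",
                      id = "t") {
  psiteTrack(id, chrom = rep(chrom, length(pos)), pos = pos,
             strand = rep(strandChar, length(pos)), count = count)
}

## Random sparse track on chr1, both strands, seeded.
randomTrack <- function(seed, n = 60, id = paste0("r", seed)) {
  set.seed(seed)
  psiteTrack(id,
             chrom = rep("chr1", n),
             pos = sample.int(500, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             count = sample.int(9, n, replace = TRUE))
}

## Counts of a track as a plain named vector key -> count.
trackAsVector <- function(track) {
  cts <- track@counts
  setNames(as.numeric(cts$score),
           paste(as.character(seqnames(cts)), as.character(strand(cts)),
                 start(cts)))
}

## Annotation with assignment-priority variants for one gene, all
## sharing the same exon structure.
priorityTx <- function() {
  ex <- gr("chr1", c(1, 201), c(100, 300), "+")
  mk <- function(n) setNames(rep(list(ex), length(n)), n)
  ids <- c("T_mane", "T_appris1", "T_appris3", "T_tsl2", "T_read",
           "T_nc")
  TranscriptSet(
    exons = mk(ids),
    cds = list(T_mane = gr("chr1", 31, 90, "+"),
               T_appris1 = gr("chr1", 31, 90, "+"),
               T_appris3 = gr("chr1", 31, 90, "+"),
               T_tsl2 = gr("chr1", 31, 90, "+"),
               T_read = gr("chr1", 31, 90, "+")),
    txData = data.frame(
      transcript_id = ids,
      gene_id = "GP",
      gene_biotype = "protein_coding",
      transcript_biotype = c(rep("protein_coding", 5),
                             "processed_transcript"),
      mane_select = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
      appris_rank = c(1L, 1L, 3L, 1L, 1L, 1L),
      tsl = c(1L, 1L, 1L, 2L, 1L, 2L),
      readthrough = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)))
}

## Subset an OrfSet by id, preserving metadata.
subsetForIds <- function(orfs, ids) {
  OrfSet(setNames(lapply(ids, function(i) orfBlocks(orfs, i)), ids),
         startCodon = orfData(orfs)$start_codon[match(ids, orfIds(orfs))],
         hostTranscript =
           orfData(orfs)$host_transcript[match(ids, orfIds(orfs))])
}

## Attach host transcripts (e.g. from a simulation truth table).
withHosts <- function(orfs, hosts) {
  ids <- orfIds(orfs)
  OrfSet(setNames(lapply(ids, function(i) orfBlocks(orfs, i)), ids),
         startCodon = orfData(orfs)$start_codon,
         hostTranscript = unname(hosts[ids]))
}

## Simulation ORFs with truth-table hosts attached, decoys excludable.
simOrfsWithTruthHosts <- function(sim, keepDecoys = "none") {
  tr <- sim$truth[sim$truth$decoy %in% keepDecoys, ]
  sub <- subsetForIds(sim$orfs, tr$orf_id)
  withHosts(sub, setNames(tr$expected_host, tr$orf_id))
}
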