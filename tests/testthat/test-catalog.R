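test_that("identical ORFs collapse with merged provenance", {
  b <- gr("chr1", c(11, 21), c(14, 25), "+")
  orfs <- OrfSet(list(a = b, b = b, c = gr("chr1", 12, 26, "+")),
                 sourceDatasets = list("s1", "s2", "s1"),
                 legacyName = c(NA, "c1riboseqorf9", NA))
  col <- collapseIdentical(orfs)
  expect_equal(col$duplicates, 1L)
  expect_setequal(orfIds(col$orfs), c("a", "c"))
  od <- orfData(col$orfs)
  expect_equal(od$source_datasets[[match("a", od$orf_id)]], c("s1", "s2"))
  expect_equal(od$legacy_name[match("a", od$orf_id)], "c1riboseqorf9")
})

test_that("records differing by a single base both survive collapsing", {
  orfs <- OrfSet(list(a = gr("chr1", 11, 19, "+"),
                      b = gr("chr1", 12, 20, "+")))
  expect_equal(collapseIdentical(orfs)$duplicates, 0L)
})

test_that("collapsing a mixed fixture counts duplicate pairs", {
  base <- lapply(seq(10, 70, by = 10), function(s)
    gr("chr1", s + 1, s + 9, "+"))
  names(base) <- paste0("u", seq_along(base))
  dups <- base[c(1, 3, 5)]
  names(dups) <- paste0("d", 1:3)
  orfs <- OrfSet(c(base, dups))
  col <- collapseIdentical(orfs)
  expect_equal(length(orfIds(col$orfs)), 7L)
  expect_equal(col$duplicates, 3L)
  # oracle: pairwise equality count
  keys <- vapply(orfIds(orfs), function(i) {
    b <- orfBlocks(orfs, i)
    paste(start(b), end(b), collapse = ";")
  }, "")
  expect_equal(col$duplicates, sum(duplicated(keys)))
})

## Annotation for exclusion tests: coding transcript with CDS 31-90
## (offsets = genomic here), an NMD transcript with CDS 211-240, and a
## same-strand pseudogene at 401-500.
exclusionTx <- function() {
  TranscriptSet(
    exons = list(TC = gr("chr1", c(1, 201), c(100, 300), "+"),
                 TN = gr("chr1", c(1, 201), c(100, 300), "+"),
                 TP = gr("chr1", 401, 500, "+")),
    cds = list(TC = gr("chr1", 31, 90, "+"),
               TN = gr("chr1", 211, 240, "+")),
    txData = data.frame(
      transcript_id = c("TC", "TN", "TP"),
      gene_id = c("GC", "GC", "GPSG"),
      gene_biotype = c("protein_coding", "protein_coding", "pseudogene"),
      transcript_biotype = c("protein_coding", "nonsense_mediated_decay",
                             "processed_pseudogene")))
}

test_that("mapping requires junction-exact containment", {
  tx <- exclusionTx()
  orfs <- OrfSet(list(
    intronic = gr("chr1", 121, 129, "+"),        # inside the intron
    junctionSkip = gr("chr1", c(91, 111), c(100, 112), "+"),  # wrong junction
    spliced = gr("chr1", c(95, 201), c(100, 203), "+"),       # exact junction
    strandFlip = gr("chr1", 11, 19, "-")))
  mp <- mapAndExclude(orfs, tx)
  expect_setequal(mp$excluded$orf_id[mp$excluded$reason == "unmapped"],
                  c("intronic", "junctionSkip", "strandFlip"))
  expect_true("spliced" %in% orfIds(mp$orfs))
  expect_setequal(mp$compatible[["spliced"]], c("TC", "TN"))
})

test_that("same-frame CDS overlap excludes, alternative frame survives", {
  tx <- exclusionTx()
  orfs <- OrfSet(list(
    sameFrame = gr("chr1", 40, 60, "+"),    # 40-31 = 9: in CDS frame
    altFrame = gr("chr1", 41, 61, "+"),     # shifted by +1 nt
    nmdFrame = gr("chr1", 214, 225, "+"),   # in the NMD CDS frame
    psgHit = gr("chr1", c(95, 201), c(100, 203), "+")))
  # move psgHit onto the pseudogene
  orfs <- OrfSet(list(sameFrame = gr("chr1", 40, 60, "+"),
                      altFrame = gr("chr1", 41, 61, "+"),
                      nmdFrame = gr("chr1", 214, 225, "+"),
                      uorfLike = gr("chr1", 11, 19, "+")))
  mp <- mapAndExclude(orfs, tx)
  exc <- setNames(mp$excluded$reason, mp$excluded$orf_id)
  expect_equal(unname(exc["sameFrame"]), "same_frame_cds")
  expect_equal(unname(exc["nmdFrame"]), "same_frame_cds")
  expect_setequal(orfIds(mp$orfs), c("altFrame", "uorfLike"))
  # oracle: phase comparison — altFrame start offset differs from CDS
  # start offset by 10, not a multiple of 3
  expect_false((41 - 31) %% 3 == 0)
})

test_that("pseudogene overlap excludes on the same strand only", {
  tx <- exclusionTx()
  # lncRNA host overlapping the pseudogene span lets the ORF map
  tx2 <- TranscriptSet(
    exons = c(list(TL = gr("chr1", 391, 520, "+"),
                   TLm = gr("chr1", 391, 520, "-")),
              as.list(tx@exons)),
    cds = as.list(tx@cds),
    txData = rbind(
      data.frame(transcript_id = c("TL", "TLm"),
                 gene_id = c("GL", "GLM"),
                 gene_biotype = "lncRNA", transcript_biotype = "lncRNA",
                 mane_select = FALSE, appris_rank = NA_integer_,
                 tsl = NA_integer_, readthrough = FALSE),
      as.data.frame(txData(tx))))
  orfs <- OrfSet(list(onPsg = gr("chr1", 411, 419, "+"),
                      oppStrand = gr("chr1", 421, 429, "-")))
  mp <- mapAndExclude(orfs, tx2)
  exc <- setNames(mp$excluded$reason, mp$excluded$orf_id)
  expect_equal(unname(exc["onPsg"]), "pseudogene")
  expect_true("oppStrand" %in% orfIds(mp$orfs))
})

test_that("host assignment follows readthrough < MANE < APPRIS < TSL < coding", {
  tx <- priorityTx()
  all6 <- c("T_mane", "T_appris1", "T_appris3", "T_tsl2", "T_read", "T_nc")
  expect_equal(assignHostTranscript(tx, all6), "T_mane")
  expect_equal(assignHostTranscript(tx, c("T_appris1", "T_appris3")),
               "T_appris1")
  expect_equal(assignHostTranscript(tx, c("T_appris1", "T_tsl2")),
               "T_appris1")
  # readthrough demoted below everything, even a non-coding transcript
  expect_equal(assignHostTranscript(tx, c("T_read", "T_nc")), "T_nc")
  # coding beats non-coding at equal support
  expect_equal(assignHostTranscript(tx, c("T_nc", "T_tsl2")), "T_tsl2")
  expect_error(assignHostTranscript(tx, character(0)), "empty")
})

test_that("host assignment is invariant to candidate order", {
  tx <- priorityTx()
  all6 <- c("T_mane", "T_appris1", "T_appris3", "T_tsl2", "T_read", "T_nc")
  set.seed(5)
  for (k in 1:20) {
    perm <- sample(all6)
    expect_equal(assignHostTranscript(tx, perm), "T_mane")
    perm2 <- sample(setdiff(all6, "T_mane"))
    expect_equal(assignHostTranscript(tx, perm2), "T_appris1")
  }
})

test_that("classification covers all seven types and rejects spanning ORFs", {
  sim <- simulateAnnotation(simConfig(seed = 8))
  tr <- sim$truth[sim$truth$decoy == "none", ]
  got <- vapply(seq_len(nrow(tr)), function(i)
    classifyOrfType(sim$orfs, tr$orf_id[i], sim$tx,
                    tr$expected_host[i]), "")
  expect_equal(got, tr$expected_type)
  expect_setequal(unique(got),
                  c("uORF", "uoORF", "intORF", "dORF", "doORF",
                    "lncRNA-ORF", "PT-ORF"))
  # an ORF spanning 5'UTR + CDS + 3'UTR is not representable
  tx <- twoExonTx("+")  # CDS offsets 31..90
  expect_error(classifyOrfType(gr("chr1", 22, 96, "+"), "x", tx, "TXP"),
               "not representable")
})

test_that("isoform clusters are connected components of codon sharing", {
  # A and B share their stop, C overlaps A's span in a different frame,
  # D is elsewhere
  orfs <- OrfSet(list(
    A = gr("chr1", 11, 40, "+"),
    B = gr("chr1", 23, 40, "+"),   # same frame as A: 23-11 divisible by 3
    C = gr("chr1", 12, 35, "+"),   # shifted frame: no shared codon
    D = gr("chr1", 101, 112, "+")))
  cl <- clusterIsoforms(orfs)
  expect_equal(cl$membership[["A"]], cl$membership[["B"]])
  expect_false(cl$membership[["A"]] == cl$membership[["C"]])
  expect_false(cl$membership[["A"]] == cl$membership[["D"]])
  pr <- cl$pairs
  expect_equal(nrow(pr), 1L)
  expect_true(pr$shared_stop)
  expect_false(pr$shared_start)
  # B has 6 codons, all shared with A
  expect_equal(pr$shared_codons, 6L)
  expect_true(pr$overlap_ge)
})

test_that("clustering equals the brute-force transitive closure on the simulation", {
  sim <- simulateAnnotation(simConfig(seed = 12))
  col <- collapseIdentical(sim$orfs)
  cl <- clusterIsoforms(col$orfs)
  ids <- orfIds(col$orfs)
  codSets <- lapply(ids, function(i) {
    m <- orfCodons(col$orfs, i)
    b <- orfBlocks(col$orfs, i)
    paste(as.character(seqnames(b))[1], as.character(strand(b))[1],
          m[, 1], m[, 2], m[, 3])
  })
  names(codSets) <- ids
  # brute force: repeated merging until fixpoint
  groups <- as.list(ids)
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      if (is.null(groups[[i]])) next
      for (j in seq_along(groups)) {
        if (j <= i || is.null(groups[[j]])) next
        share <- length(intersect(
          unlist(codSets[groups[[i]]]), unlist(codSets[groups[[j]]]))) > 0
        if (share) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  groups <- Filter(Negate(is.null), groups)
  bf <- integer(0)
  for (k in seq_along(groups)) bf[groups[[k]]] <- k
  # same partition (up to label permutation)
  expect_equal(length(unique(cl$membership)), length(groups))
  tab <- table(cl$membership[ids], bf[ids])
  expect_true(all(colSums(tab > 0) == 1) && all(rowSums(tab > 0) == 1))
})

test_that("naming numbers upward from the per-chromosome legacy maximum", {
  orfs <- OrfSet(list(
    keep = gr("chr1", 501, 509, "+"),
    new1 = gr("chr1", 101, 109, "+"),
    new2 = gr("chr1", 301, 309, "+"),
    xnew = gr("chrX", 11, 19, "+")),
    legacyName = c("c1riboseqorf5", NA, NA, NA))
  nm <- assignNames(orfs)
  expect_equal(unname(nm["keep"]), "c1riboseqorf5")
  expect_equal(unname(nm["new1"]), "c1riboseqorf6")
  expect_equal(unname(nm["new2"]), "c1riboseqorf7")
  expect_equal(unname(nm["xnew"]), "cXriboseqorf1")
  expect_false(anyDuplicated(nm) > 0)
  # a non-catalog legacy name (old norep style) is not reused
  orfs2 <- OrfSet(list(a = gr("chr2", 11, 19, "+")),
                  legacyName = "c2norep2")
  expect_equal(unname(assignNames(orfs2)["a"]), "c2riboseqorf1")
  expect_error(assignNames(OrfSet(
    list(a = gr("chr1", 11, 19, "+"), b = gr("chr1", 31, 39, "+")),
    legacyName = c("c1riboseqorf2", "c1riboseqorf2"))), "duplicate")
})

test_that("the full catalog build accounts for every record and partitions types", {
  sim <- simulateAnnotation(simConfig(seed = 6))
  trk <- simulatePsites(sim, "bodymap_v45", seed = 6)
  res <- buildCatalog(sim$orfs, sim$tx, list(trk),
                      defaultThresholds("bodymap_v45"))
  cnt <- stageCounts(res$report)
  expect_equal(cnt[["compiled"]], nrow(sim$truth))
  expect_equal(cnt[["compiled"]],
               cnt[["duplicate"]] + cnt[["unmapped"]] +
                 cnt[["excluded_same_frame_cds"]] +
                 cnt[["excluded_pseudogene"]] + cnt[["comprehensive"]])
  expect_equal(cnt[["duplicate"]],
               sum(sim$truth$decoy == "duplicate"))
  expect_equal(cnt[["unmapped"]], sum(sim$truth$decoy == "intronic"))
  expect_equal(cnt[["excluded_same_frame_cds"]],
               sum(sim$truth$decoy == "same_frame_cds"))
  expect_equal(cnt[["excluded_pseudogene"]],
               sum(sim$truth$decoy == "pseudogene"))
  # every comprehensive ORF gets exactly one type; counts sum up
  expect_equal(sum(res$report@perType$comprehensive),
               cnt[["comprehensive"]])
  expect_false(any(is.na(res$records$orf_type)))
  # hosts and types match the planted truth
  tr <- sim$truth[match(res$records$orf_id, sim$truth$orf_id), ]
  keepTruth <- tr$decoy %in% c("none", "frameshift", "zero_coverage")
  expect_equal(res$records$host_transcript[keepTruth],
               tr$expected_host[keepTruth])
  expect_equal(res$records$orf_type[keepTruth],
               tr$expected_type[keepTruth])
  # naming is deterministic and injective
  res2 <- buildCatalog(sim$orfs, sim$tx,
                       list(simulatePsites(sim, "bodymap_v45", seed = 6)),
                       defaultThresholds("bodymap_v45"))
  expect_identical(res$records$name, res2$records$name)
  expect_false(anyDuplicated(res$records$name) > 0)
  # length-bin summary covers the comprehensive set
  expect_equal(sum(res$report@perLengthBin$comprehensive),
               cnt[["comprehensive"]])
})

test_that("stage arithmetic and retention accounting reproduce their inputs", {
  s <- stageArithmetic(compiled = 100, unmapped = 10, duplicates = 20,
                       excluded = c(5, 3))
  expect_equal(s[["unique_sequences"]], 70L)
  expect_equal(s[["comprehensive"]], 62L)
  expect_error(stageArithmetic(10, 5, 5, 5), "not conserved")
  expect_equal(retainedFromPrevious(100, c(10, 5)), 85L)
  expect_error(retainedFromPrevious(10, 20), "more than")
})
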