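gtfFixture <- function(path) {
  lines <- c(
    'chr1\tx\ttranscript\t1\t300\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; gene_biotype "protein_coding"; transcript_biotype "protein_coding"; transcript_support_level "1"; tag "MANE_Select"; tag "appris_principal_1";',
    'chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t201\t300\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\tCDS\t31\t90\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\ttranscript\t400\t600\t.\t-\t.\tgene_id "G2"; transcript_id "T2"; gene_biotype "lncRNA"; transcript_biotype "lncRNA";',
    'chr1\tx\texon\t400\t600\t.\t-\t.\tgene_id "G2"; transcript_id "T2";',
    'chr1\tx\ttranscript\t700\t900\t.\t+\t.\tgene_id "G3"; transcript_id "T3"; gene_biotype "transcribed_unprocessed_pseudogene"; transcript_biotype "processed_pseudogene";',
    'chr1\tx\texon\t700\t900\t.\t+\t.\tgene_id "G3"; transcript_id "T3";',
    'chr1\tx\ttranscript\t1000\t1200\t.\t+\t.\tgene_id "G4"; transcript_id "T4"; gene_biotype "protein_coding"; transcript_biotype "protein_coding"; transcript_support_level "2"; tag "readthrough_transcript"; tag "appris_alternative_2";',
    'chr1\tx\texon\t1000\t1200\t.\t+\t.\tgene_id "G4"; transcript_id "T4";',
    'chr1\tx\ttranscript\t1300\t1500\t.\t+\t.\tgene_id "G5"; transcript_id "T5"; gene_biotype "snoRNA"; transcript_biotype "snoRNA";',
    'chr1\tx\texon\t1300\t1500\t.\t+\t.\tgene_id "G5"; transcript_id "T5";')
  writeLines(lines, path)
  path
}

test_that("GTF coordinates and attributes parse into transcript models", {
  tx <- readAnnotation(gtfFixture(withr::local_tempfile(fileext = ".gtf")))
  ex <- exonsOf(tx, "T1")
  expect_equal(start(ex), c(1L, 201L))
  expect_equal(end(ex), c(100L, 300L))
  td <- as.data.frame(txData(tx))
  r1 <- td[td$transcript_id == "T1", ]
  expect_true(r1$mane_select)
  expect_equal(r1$appris_rank, 1L)
  expect_equal(r1$tsl, 1L)
  expect_false(r1$readthrough)
  r4 <- td[td$transcript_id == "T4", ]
  expect_true(r4$readthrough)
  expect_equal(r4$appris_rank, 7L)
  expect_equal(r4$tsl, 2L)
  # biotype normalization
  expect_equal(td$gene_biotype[match(c("T2", "T3", "T5"),
                                     td$transcript_id)],
               c("lncRNA", "pseudogene", "other"))
  # a transcript without a CDS feature has empty cds blocks
  expect_length(cdsOf(tx, "T2"), 0)
})

test_that("malformed GTF lines and out-of-exon CDS are rejected with context", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c('chr1\tx\texon\t1\t100', "bad line"), p)
  expect_error(readAnnotation(p), "line 1")
  gtfFixture(p)
  lines <- readLines(p)
  lines <- c(lines, 'chr1\tx\tCDS\t120\t150\t.\t+\t.\tgene_id "G1"; transcript_id "T1";')
  writeLines(lines, p)
  expect_error(readAnnotation(p), "T1")
})

test_that("annotation write then re-read reproduces the models", {
  tx <- readAnnotation(gtfFixture(withr::local_tempfile(fileext = ".gtf")))
  p2 <- withr::local_tempfile(fileext = ".gtf")
  writeAnnotation(tx, p2)
  tx2 <- readAnnotation(p2)
  expect_identical(transcriptIds(tx2), transcriptIds(tx))
  for (id in transcriptIds(tx)) {
    expect_equal(as.data.frame(exonsOf(tx2, id))[1:5],
                 as.data.frame(exonsOf(tx, id))[1:5])
    expect_equal(as.data.frame(cdsOf(tx2, id))[1:5],
                 as.data.frame(cdsOf(tx, id))[1:5])
  }
  expect_equal(as.data.frame(txData(tx2)), as.data.frame(txData(tx)))
})

test_that("BED12 ORFs parse with codon counts and transcription-ordered blocks", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t10\t19\torfA\t0\t+\t10\t19\t0\t1\t9,\t0,",
    "chr1\t30\t45\torfB\t0\t+\t30\t45\t0\t2\t6,3,\t0,12,",
    "chr1\t50\t62\torfC\t0\t-\t50\t62\t0\t2\t6,3,\t0,9,"), p)
  orfs <- readOrfs(p)
  expect_equal(orfData(orfs)$n_codons, c(3L, 3L, 3L))
  bB <- orfBlocks(orfs, "orfB")
  expect_equal(start(bB), c(31L, 43L))
  expect_equal(width(bB), c(6L, 3L))
  # minus-strand ORF: codons enumerate from the 3'-most genomic block
  m <- orfCodons(orfs, "orfC")
  expect_equal(m[1, ], c(62, 61, 60))
})

test_that("ORFs with length not divisible by three are rejected by name", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tbadorf\t0\t+\t10\t20\t0\t1\t10,\t0,",
               "chr1\t30\t39\tgoodorf\t0\t+\t30\t39\t0\t1\t9,\t0,"), p)
  expect_error(readOrfs(p), "badorf")
})

test_that("BED12 write then re-read reproduces every ORF", {
  sim <- simulateAnnotation(simConfig(seed = 5))
  p <- withr::local_tempfile(fileext = ".bed")
  writeOrfs(sim$orfs, p)
  back <- readOrfs(p)
  expect_setequal(orfIds(back), orfIds(sim$orfs))
  for (id in orfIds(sim$orfs)) {
    expect_equal(as.data.frame(orfBlocks(back, id))[1:5],
                 as.data.frame(orfBlocks(sim$orfs, id))[1:5],
                 info = id)
  }
})

test_that("ORF metadata TSV joins on name", {
  p <- withr::local_tempfile(fileext = ".bed")
  m <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t10\t19\torfA\t0\t+\t10\t19\t0\t1\t9,\t0,", p)
  writeLines(c("name\tstart_codon\tsource_datasets\tlegacy_name",
               "orfA\tCTG\ts1,s2\tc1riboseqorf7"), m)
  orfs <- readOrfs(p, meta = m)
  od <- orfData(orfs)
  expect_equal(od$start_codon, "CTG")
  expect_equal(od$legacy_name, "c1riboseqorf7")
  expect_equal(od$source_datasets[[1]], c("s1", "s2"))
})

test_that("catalog TSV round-trips values and renders missing scores as NA", {
  sim <- simulateAnnotation(simConfig(seed = 2))
  trk <- simulatePsites(sim, "ds1", seed = 2)
  res <- buildCatalog(sim$orfs, sim$tx, list(trk),
                      defaultThresholds("bodymap_v45"))
  prefix <- file.path(withr::local_tempdir(), "catalog")
  paths <- writeCatalog(res$records, res$orfs, prefix)
  expect_true(all(file.exists(paths)))
  back <- readCatalog(paths[["tsv"]])
  expect_equal(nrow(back), nrow(res$records))
  # zero-coverage ORF: all three scores missing, never primary
  z <- back[back$orf_id == "SIMG1_zerocov", ]
  expect_true(is.na(z$pif.ds1) && is.na(z$dropoff.ds1))
  expect_false(z$primary)
  raw <- readLines(paths[["tsv"]])
  expect_true(any(grepl("\tNA\t", raw)))
  # numeric round trip to 6 decimals
  expect_equal(round(back$pif.ds1, 6), round(res$records$pif.ds1, 6))
  expect_equal(round(back$ppm.ds1, 6), round(res$records$ppm.ds1, 6))
  # BED names match the catalog names
  bed <- readOrfs(paths[["bed"]])
  expect_setequal(orfIds(bed), res$records$name)
})

test_that("writeCatalog refuses records missing scored ORFs", {
  sim <- simulateAnnotation(simConfig(seed = 2))
  trk <- simulatePsites(sim, "ds1", seed = 2)
  res <- buildCatalog(sim$orfs, sim$tx, list(trk),
                      defaultThresholds("bodymap_v45"))
  expect_error(writeCatalog(res$records[-1, ], res$orfs,
                            file.path(withr::local_tempdir(), "x")),
               "unscored")
})
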