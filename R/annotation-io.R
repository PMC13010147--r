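#' @include AllClasses.R
#' @importFrom utils read.delim write.table
NULL

APPRIS_RANKS <- c(appris_principal_1 = 1L, appris_principal_2 = 2L,
                  appris_principal_3 = 3L, appris_principal_4 = 4L,
                  appris_principal_5 = 5L, appris_alternative_1 = 6L,
                  appris_alternative_2 = 7L)

gtfAttr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0(key, ' "([^"]*)"'), attr))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
}

gtfTags <- function(attr) {
  regmatches(attr, gregexpr('tag "([^"]*)"', attr))
}

normalizeGeneBiotype <- function(x) {
  out <- rep("other", length(x))
  out[x %in% c("protein_coding")] <- "protein_coding"
  out[x %in% c("lncRNA", "lincRNA")] <- "lncRNA"
  out[grepl("pseudogene", x)] <- "pseudogene"
  out[is.na(x)] <- "other"
  out
}

#' Read a transcript annotation from GTF
#'
#' Parses an Ensembl-dialect GTF (features `transcript`, `exon`, `CDS`;
#' attributes `gene_id`, `transcript_id`, `gene_biotype`,
#' `transcript_biotype`, `transcript_support_level`, and the repeated
#' `tag` attribute carrying `MANE_Select`, `appris_*` and
#' `readthrough_transcript`) into a [TranscriptSet]. GTF 1-based closed
#' coordinates are kept as-is (the internal GRanges convention).
#'
#' A dedicated parser is used because repeated `tag` attributes carry the
#' MANE/APPRIS/readthrough annotations and must all be retained.
#'
#' @param path Path to a GTF file.
#' @return A [TranscriptSet].
#' @seealso [writeAnnotation()]
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 9L))
    stop("malformed GTF line ", lineNo[which(nf != 9L)[1]],
         ": expected 9 tab-separated fields")
  tab <- data.frame(chrom = vapply(f, `[`, "", 1L),
                    type = vapply(f, `[`, "", 3L),
                    start = as.integer(vapply(f, `[`, "", 4L)),
                    end = as.integer(vapply(f, `[`, "", 5L)),
                    strand = vapply(f, `[`, "", 7L),
                    attr = vapply(f, `[`, "", 9L))
  if (anyNA(tab$start) || anyNA(tab$end))
    stop("malformed GTF line ",
         lineNo[which(is.na(tab$start) | is.na(tab$end))[1]],
         ": non-numeric coordinates")
  tab$transcript_id <- gtfAttr(tab$attr, "transcript_id")

  isTx <- tab$type == "transcript"
  txAttr <- tab$attr[isTx]
  ids <- tab$transcript_id[isTx]
  if (anyNA(ids)) stop("transcript feature without transcript_id")
  tags <- gtfTags(txAttr)
  hasTag <- function(tagName)
    vapply(tags, function(t) any(grepl(paste0('"', tagName, '"'), t)), TRUE)
  apprisRank <- vapply(tags, function(t) {
    hit <- sub('tag "([^"]*)"', "\\1", t)
    r <- APPRIS_RANKS[hit[hit %in% names(APPRIS_RANKS)]]
    if (length(r)) min(r) else NA_integer_
  }, 1L)
  tslRaw <- gtfAttr(txAttr, "transcript_support_level")
  tsl <- suppressWarnings(as.integer(sub("^(\\d+).*", "\\1", tslRaw)))
  txd <- DataFrame(
    transcript_id = ids,
    gene_id = gtfAttr(txAttr, "gene_id"),
    gene_biotype = normalizeGeneBiotype(gtfAttr(txAttr, "gene_biotype")),
    transcript_biotype = gtfAttr(txAttr, "transcript_biotype"),
    mane_select = hasTag("MANE_Select"),
    appris_rank = apprisRank,
    tsl = tsl,
    readthrough = hasTag("readthrough_transcript"))

  grFor <- function(type) {
    sub <- tab[tab$type == type & tab$transcript_id %in% ids, , drop = FALSE]
    gr <- GRanges(sub$chrom, IRanges(sub$start, sub$end), strand = sub$strand)
    grl <- S4Vectors::split(gr, factor(sub$transcript_id, levels = ids))
    sort(grl)
  }
  ts <- new("TranscriptSet", exons = grFor("exon"), cds = grFor("CDS"),
            txData = txd)
  validObject(ts)
  ts
}

#' Write a TranscriptSet as Ensembl-dialect GTF
#'
#' @param tx A [TranscriptSet].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(tx, path, source = "riboCatalog") {
  txd <- txData(tx)
  out <- character(0)
  for (i in seq_len(nrow(txd))) {
    id <- txd$transcript_id[i]
    ex <- exonsOf(tx, id)
    cd <- cdsOf(tx, id)
    chrom <- as.character(seqnames(ex))[1]
    str <- as.character(strand(ex))[1]
    tags <- c(if (isTRUE(txd$mane_select[i])) "MANE_Select",
              if (!is.na(txd$appris_rank[i]))
                names(APPRIS_RANKS)[txd$appris_rank[i]],
              if (isTRUE(txd$readthrough[i])) "readthrough_transcript")
    attr <- paste0('gene_id "', txd$gene_id[i], '"; transcript_id "', id,
                   '"; gene_biotype "', txd$gene_biotype[i],
                   '"; transcript_biotype "', txd$transcript_biotype[i], '";',
                   if (!is.na(txd$tsl[i]))
                     paste0(' transcript_support_level "', txd$tsl[i], '";')
                   else "",
                   paste0(' tag "', tags, '";', collapse = ""))
    line <- function(type, s, e)
      paste(chrom, source, type, s, e, ".", str, ".", attr, sep = "\t")
    out <- c(out,
             line("transcript", min(start(ex)), max(end(ex))),
             mapply(line, "exon", start(ex), end(ex)),
             if (length(cd)) mapply(line, "CDS", start(cd), end(cd)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read candidate ORFs from BED12
#'
#' BED12 blocks are the spliced ORF including the stop codon as the last
#' 3 nt (the published catalog convention); `thickStart`/`thickEnd` are
#' ignored. An optional metadata TSV (columns `name`, and any of
#' `source_datasets` -- comma-separated study labels --, `start_codon`,
#' `legacy_name`) is joined on the BED name.
#'
#' @param path Path to a BED12 file.
#' @param meta Optional path to a metadata TSV.
#' @return An [OrfSet], in file order.
#' @seealso [writeOrfs()]
#' @export
readOrfs <- function(path, meta = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks))
    gr$blocks <- IRanges::IRangesList(lapply(width(gr), function(w)
      IRanges(1L, w)))
  ids <- gr$name
  if (is.null(ids) || anyNA(ids)) stop("BED records must be named")
  if (anyDuplicated(ids)) stop("duplicated ORF names in BED: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  totalLen <- sum(width(gr$blocks))
  bad <- totalLen %% 3L != 0L | totalLen < 6L
  if (any(bad))
    stop("ORF length not a multiple of 3 (or < 2 codons): ",
         paste(ids[bad], collapse = ", "))
  blocks <- GRangesList(lapply(seq_along(gr), function(i) {
    b <- gr$blocks[[i]]
    GRanges(as.character(seqnames(gr))[i],
            IRanges::shift(b, start(gr)[i] - 1L),
            strand = as.character(strand(gr))[i])
  }))
  names(blocks) <- ids
  od <- DataFrame(orf_id = ids,
                  start_codon = NA_character_,
                  n_codons = as.integer(totalLen / 3L),
                  source_datasets = IRanges::CharacterList(
                    replicate(length(ids), character(0), simplify = FALSE)),
                  legacy_name = NA_character_,
                  host_transcript = NA_character_,
                  orf_type = NA_character_)
  if (!is.null(meta)) {
    mt <- read.delim(meta, stringsAsFactors = FALSE)
    j <- match(ids, mt$name)
    if ("start_codon" %in% names(mt)) od$start_codon <- mt$start_codon[j]
    if ("legacy_name" %in% names(mt)) od$legacy_name <- mt$legacy_name[j]
    if ("source_datasets" %in% names(mt)) {
      src <- strsplit(ifelse(is.na(mt$source_datasets[j]), "",
                             mt$source_datasets[j]), ",")
      od$source_datasets <- IRanges::CharacterList(src)
    }
  }
  orfs <- new("OrfSet", blocks = blocks, orfData = od)
  validObject(orfs)
  orfs
}

#' Write an OrfSet as BED12
#'
#' @param orfs An [OrfSet].
#' @param path Output path.
#' @param names Optional character vector of record names (defaults to
#'   the ORF ids).
#' @return `path`, invisibly.
#' @export
writeOrfs <- function(orfs, path, names = NULL) {
  ids <- orfIds(orfs)
  if (is.null(names)) names <- ids
  gr <- unlist(range(orfs@blocks), use.names = FALSE)
  gr$name <- names
  gr$blocks <- IRanges::IRangesList(lapply(seq_along(ids), function(i) {
    b <- orfBlocks(orfs, ids[i])
    IRanges::shift(IRanges(start(b), end(b)), 1L - start(gr)[i])
  }))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write and read the catalog table
#'
#' `writeCatalog()` writes the per-ORF catalog records as a UTF-8
#' tab-separated table (missing scores rendered as `NA`) and a companion
#' BED12 carrying the same names. `readCatalog()` reads the TSV back.
#'
#' @param records A data.frame of catalog records, as produced by
#'   [buildCatalog()]; must include an `orf_id` column and per-dataset
#'   score columns.
#' @param orfs The [OrfSet] the records describe.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.bed`.
#' @return Named character vector of the written paths, invisibly.
#' @export
writeCatalog <- function(records, orfs, prefix) {
  if (!all(orfIds(orfs) %in% records$orf_id))
    stop("unscored ORFs: ",
         paste(setdiff(orfIds(orfs), records$orf_id), collapse = ", "))
  tsv <- paste0(prefix, ".tsv")
  bed <- paste0(prefix, ".bed")
  write.table(records, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  nm <- if ("name" %in% names(records))
    records$name[match(orfIds(orfs), records$orf_id)] else NULL
  writeOrfs(orfs, bed, names = nm)
  invisible(c(tsv = tsv, bed = bed))
}

#' @rdname writeCatalog
#' @param path Path of a catalog TSV.
#' @export
readCatalog <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
             fileEncoding = "UTF-8")
}
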