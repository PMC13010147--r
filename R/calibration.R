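#' @include AllClasses.R
#' @importFrom stats qnorm setNames
NULL

#' Fit a normal reference distribution to CDS scores
#'
#' Moment fit (sample mean, unbiased sample sd) of one metric's score
#' distribution over annotated protein-coding ORFs. These fits anchor
#' the pass thresholds to what canonical translation looks like in the
#' same dataset.
#'
#' @param scores Numeric vector of at least two finite scores in `[0, 1]`.
#' @return Named numeric vector `c(mu = ..., sd = ...)`.
#' @seealso [deriveThresholds()]
#' @export
fitReference <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2L)
    stop("need at least 2 finite reference scores")
  c(mu = mean(scores), sd = stats::sd(scores))
}

#' Derive pass thresholds from reference fits
#'
#' PIF and Uniformity thresholds are the fitted-normal point exceeded by
#' a `tail` fraction (default 95%) of reference CDSs, `mu + qnorm(1 -
#' tail) * sd`; the Drop-off threshold is the fitted mean. All are
#' clamped to `[0, 1]`.
#'
#' @param fits Named list with elements `pif`, `uniformity`, `dropoff`,
#'   each a `c(mu, sd)` vector as returned by [fitReference()].
#' @param datasetId Dataset label.
#' @param tail Coverage fraction for the PIF/Uniformity tail (default
#'   0.95).
#' @return A [ThresholdSet].
#' @export
deriveThresholds <- function(fits, datasetId, tail = 0.95) {
  stopifnot(all(c("pif", "uniformity", "dropoff") %in% names(fits)))
  z <- qnorm(1 - tail)
  lowTail <- function(f) f[["mu"]] + z * f[["sd"]]
  thr <- c(pif = lowTail(fits$pif),
           uniformity = lowTail(fits$uniformity),
           dropoff = fits$dropoff[["mu"]])
  thr <- setNames(pmin(1, pmax(0, thr)),
                  c("pif", "uniformity", "dropoff"))
  fm <- vapply(fits[c("pif", "uniformity", "dropoff")],
               function(f) c(f[["mu"]], f[["sd"]]), numeric(2))
  rownames(fm) <- c("mu", "sd")
  new("ThresholdSet", datasetId = datasetId, fits = fm, thresholds = thr)
}

#' Shipped default threshold sets
#'
#' The published per-dataset thresholds for the two pooled Ribo-seq
#' resources, usable without calibration data: `"bodymap_v45"` (PIF
#' 0.7589, Uniformity 0.713, Drop-off 0.92) and `"ribocrypt_v45"` (PIF
#' 0.5112, Uniformity 0.8779, Drop-off 0.88). Fit parameters were not
#' republished and are `NA`.
#'
#' @param name One of `"bodymap_v45"`, `"ribocrypt_v45"`.
#' @return A [ThresholdSet].
#' @export
defaultThresholds <- function(name = c("bodymap_v45", "ribocrypt_v45")) {
  name <- match.arg(name)
  thr <- switch(name,
    bodymap_v45 = c(pif = 0.7589, uniformity = 0.713, dropoff = 0.92),
    ribocrypt_v45 = c(pif = 0.5112, uniformity = 0.8779, dropoff = 0.88))
  fm <- matrix(NA_real_, 2, 3,
               dimnames = list(c("mu", "sd"), c("pif", "uniformity",
                                                "dropoff")))
  new("ThresholdSet", datasetId = name, fits = fm, thresholds = thr)
}

#' Apply a threshold set to signature scores
#'
#' An ORF passes in a dataset iff all three scores meet their thresholds
#' (inclusive boundary: thresholds are reported to limited precision).
#' Any missing score fails -- absence of evidence never passes.
#'
#' @param scores A data.frame of signature scores (columns `dataset_id`,
#'   `pif`, `uniformity`, `dropoff`), e.g. from [scoreOrfs()].
#' @param thr A [ThresholdSet] with matching `dataset_id`.
#' @return Logical vector, one flag per row of `scores`.
#' @export
passesThresholds <- function(scores, thr) {
  if (!all(scores$dataset_id == thr@datasetId))
    stop("dataset mismatch: scores are for ",
         paste(unique(scores$dataset_id), collapse = ", "),
         " but thresholds for ", thr@datasetId)
  t <- thresholds(thr)
  ok <- !is.na(scores$pif) & !is.na(scores$uniformity) &
    !is.na(scores$dropoff) &
    scores$pif >= t[["pif"]] & scores$uniformity >= t[["uniformity"]] &
    scores$dropoff >= t[["dropoff"]]
  unname(ok)
}

#' Primary-set selection rule
#'
#' An ORF enters the Primary set when it passes the thresholds in any of
#' the evaluated datasets.
#'
#' @param passFlags Logical vector (or one-row matrix) of per-dataset
#'   pass flags for one ORF; at least one dataset.
#' @return `TRUE` iff any flag is `TRUE`.
#' @export
selectPrimary <- function(passFlags) {
  stopifnot(length(passFlags) >= 1L)
  any(passFlags, na.rm = TRUE)
}

#' Serialize / read threshold sets as key-value text
#'
#' Flat `key = value` files (a TOML subset): `dataset`, then
#' `<metric>.threshold`, `<metric>.mu`, `<metric>.sd`.
#'
#' @param thr A [ThresholdSet].
#' @param path Output (or input) path.
#' @return `writeThresholds()`: `path` invisibly; `readThresholds()`:
#'   a [ThresholdSet].
#' @export
writeThresholds <- function(thr, path) {
  lines <- c(sprintf('dataset = "%s"', thr@datasetId))
  for (m in c("pif", "uniformity", "dropoff")) {
    lines <- c(lines,
               sprintf("%s.threshold = %.10g", m, thr@thresholds[[m]]),
               sprintf("%s.mu = %.10g", m, thr@fits["mu", m]),
               sprintf("%s.sd = %.10g", m, thr@fits["sd", m]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeThresholds
#' @export
readThresholds <- function(path) {
  kv <- parseKeyValue(readLines(path))
  fm <- matrix(NA_real_, 2, 3,
               dimnames = list(c("mu", "sd"),
                               c("pif", "uniformity", "dropoff")))
  thr <- setNames(numeric(3), colnames(fm))
  for (m in colnames(fm)) {
    thr[[m]] <- as.numeric(kv[[paste0(m, ".threshold")]])
    fm["mu", m] <- as.numeric(kv[[paste0(m, ".mu")]])
    fm["sd", m] <- as.numeric(kv[[paste0(m, ".sd")]])
  }
  new("ThresholdSet", datasetId = kv[["dataset"]], fits = fm,
      thresholds = thr)
}

## Minimal flat key = value parser (TOML subset, quoted or bare scalars).
parseKeyValue <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed key-value line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    val <- sub('^"(.*)"$', "\\1", val)
    out[[key]] <- val
  }
  out
}
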