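#' Assign reads to designs by barcode matching
#'
#' Each read's barcode (its first `barcodeLength` bases) is compared to every
#' manifest barcode; the read is assigned to the unique design within
#' `maxMismatch` Hamming distance. Reads matching no design, or equidistant
#' from several, are discarded and tallied.
#'
#' @param reads character vector of read sequences (or bare barcodes).
#' @param manifest data.frame with `id` and `barcode` columns; barcodes must
#'   be unique.
#' @param maxMismatch maximum Hamming distance for an assignment (default 1).
#' @param barcodeLength barcode length (default: manifest barcode width).
#' @return List with `counts` (named integer per design), `nAmbiguous` and
#'   `nUnmatched`.
#' @examples
#' man <- data.frame(id = c("a", "b"), barcode = c("AAAA", "TTTT"))
#' countBarcodes(c("AAAA", "AAAT", "ATAT"), man, barcodeLength = 4)$counts
#' @export
countBarcodes <- function(reads, manifest, maxMismatch = 1L,
                          barcodeLength = NULL) {
  if (anyDuplicated(manifest$barcode)) {
    stop("duplicate barcodes in manifest")
  }
  if (is.null(barcodeLength)) barcodeLength <- nchar(manifest$barcode[1])
  bcMat <- vapply(
    strsplit(manifest$barcode, ""), identity, character(barcodeLength)
  )
  counts <- setNames(integer(nrow(manifest)), manifest$id)
  nAmb <- 0L
  nUn <- 0L
  readBc <- substr(reads, 1L, barcodeLength)
  tab <- table(readBc)
  for (j in seq_along(tab)) {
    bc <- strsplit(names(tab)[j], "")[[1]]
    if (length(bc) < barcodeLength) {
      nUn <- nUn + tab[[j]]
      next
    }
    d <- colSums(bcMat != bc)
    dm <- min(d)
    if (dm > maxMismatch) {
      nUn <- nUn + tab[[j]]
    } else if (sum(d == dm) > 1L) {
      nAmb <- nAmb + tab[[j]]
    } else {
      i <- which.min(d)
      counts[i] <- counts[i] + tab[[j]]
    }
  }
  list(counts = counts, nAmbiguous = nAmb, nUnmatched = nUn)
}

#' Depth-normalize counts to fragments per million
#'
#' For an `MpraExperiment`, adds `dna_fpm` and `rna_fpm` assays; for a plain
#' matrix, normalizes each column. Per library (column x material),
#' `fpm = count / total * 1e6`, so FPM totals are conserved at exactly 1e6.
#'
#' @param x an [MpraExperiment-class] or a count matrix.
#' @return The same container with FPM values.
#' @examples
#' m <- matrix(c(40, 1999960), 2, 1)
#' normalizeFpm(m)[1, 1]
#' @export
normalizeFpm <- function(x) {
  if (is(x, "MpraExperiment")) {
    a <- assays(x)
    a$dna_fpm <- normalizeFpm(assay(x, "dna"))
    a$rna_fpm <- normalizeFpm(assay(x, "rna"))
    SummarizedExperiment::assays(x) <- a
    return(x)
  }
  totals <- colSums(x)
  if (any(totals <= 0)) stop("library total must be > 0 in every column")
  sweep(x, 2, totals, "/") * 1e6
}

.fpmAssay <- function(x, material) {
  nm <- paste0(material, "_fpm")
  if (!nm %in% assayNames(x)) x <- normalizeFpm(x)
  assay(x, nm)
}

#' Flag designs with sufficient DNA coverage
#'
#' A design is kept iff its DNA FPM is at least `threshold` in at least one
#' replicate library (the inclusive >= 20 FPM rule); RNA coverage plays no
#' role in the filter.
#'
#' @param x an [MpraExperiment-class].
#' @param threshold FPM threshold (default 20).
#' @return Named logical vector over designs.
#' @export
filterCoverage <- function(x, threshold = 20) {
  dnaFpm <- .fpmAssay(x, "dna")
  keep <- apply(dnaFpm >= threshold, 1, any)
  setNames(as.logical(keep), rownames(x))
}

#' Per-replicate and mean enhancer activity scores
#'
#' Activity of a design in a replicate is `log2((RNA_fpm + 1)/(DNA_fpm + 1))`
#' (a pseudocount of 1 on both materials); the summary activity is the
#' arithmetic mean over replicates. Designs failing the DNA coverage filter
#' are scored but flagged.
#'
#' @param x an [MpraExperiment-class].
#' @param threshold coverage-filter FPM threshold passed to
#'   [filterCoverage()].
#' @return `DataFrame` with design_id, a per-replicate `activity` matrix
#'   column, `meanActivity` and `passedFilter`.
#' @examples
#' dna <- matrix(1e6, 1, 2, dimnames = list("d1", NULL))
#' rna <- matrix(1e6, 1, 2, dimnames = list("d1", NULL))
#' activityScores(MpraExperiment(dna, rna))$meanActivity
#' @export
activityScores <- function(x, threshold = 20) {
  act <- log2((.fpmAssay(x, "rna") + 1) / (.fpmAssay(x, "dna") + 1))
  DataFrame(
    design_id = rownames(x),
    activity = I(act),
    meanActivity = rowMeans(act),
    passedFilter = filterCoverage(x, threshold),
    row.names = rownames(x)
  )
}

#' Replicate reproducibility (pairwise Pearson correlation)
#'
#' Pearson correlation of per-replicate activity scores between all replicate
#' pairs, over designs passing the coverage filter. Warns when any pair falls
#' below `floor`.
#'
#' @param x an [MpraExperiment-class].
#' @param floor warn if any off-diagonal correlation is below this value.
#' @return Symmetric correlation matrix, replicates x replicates.
#' @export
replicateQC <- function(x, floor = 0.8) {
  if (ncol(x) < 2L) stop("replicate QC needs at least 2 replicates")
  act <- activityScores(x)
  m <- act$activity[act$passedFilter, , drop = FALSE]
  r <- stats::cor(m)
  off <- r[upper.tri(r)]
  if (length(off) && any(off < floor)) {
    warning(
      "replicate correlation below ", floor, " (min ",
      signif(min(off), 3), ")"
    )
  }
  r
}
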