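#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   rowData colData
#' @importFrom stats setNames p.adjust sd cor median var
NULL

#' Simulation configuration
#'
#' Bundle of parameters driving every simulator in the package: library
#' geometry, sequencing depths, negative-binomial dispersion, the fraction and
#' strength of truly active regions, annotation-track structure and trio-cohort
#' sizes. One `seed` expands deterministically into independent per-generator
#' substreams, so regenerating one input never perturbs another.
#'
#' @slot seed integer; master seed for all generators.
#' @slot nRegions number of candidate enhancer regions.
#' @slot regionLength region length in bp (>= 171).
#' @slot nReplicates number of biological replicates.
#' @slot dnaDepth,rnaDepth total sequencing reads per replicate library.
#' @slot nbDispersion NB dispersion alpha (> 0); variance is mu + alpha * mu^2.
#' @slot activeFraction proportion of regions with true enhancer activity.
#' @slot activityLog2fcRange length-2 numeric; true log2 RNA/DNA multipliers of
#'   active regions are drawn uniformly from this interval.
#' @slot variantEffectFraction proportion of REF/ALT pairs carrying a true
#'   allelic effect.
#' @slot variantEffectLog2fc absolute true log2 fold change of effect variants.
#' @slot annotationCount,annotationInformativeCount number of simulated
#'   annotation tracks and how many are informative about activity.
#' @slot annotationBaseRate baseline per-region overlap probability of a track.
#' @slot annotationWeight log-odds increment of overlap for active regions on
#'   informative tracks (logistic link).
#' @slot chromLengths named numeric; chromosome sizes of the synthetic genome.
#' @slot nChd,nControl trio-cohort sizes (probands).
#' @slot dnvMu,dnvSize negative-binomial parameters of the per-participant
#'   ncDNV count (defaults reproduce median 8, interquartile range 6-11).
#' @slot cohortEffectFraction fraction of case-cohort ncDNVs placed inside
#'   high-annotation (active-region) context.
#'
#' @export
setClass("SimConfig",
  representation(
    seed = "integer",
    nRegions = "integer",
    regionLength = "integer",
    nReplicates = "integer",
    dnaDepth = "numeric",
    rnaDepth = "numeric",
    nbDispersion = "numeric",
    activeFraction = "numeric",
    activityLog2fcRange = "numeric",
    variantEffectFraction = "numeric",
    variantEffectLog2fc = "numeric",
    annotationCount = "integer",
    annotationInformativeCount = "integer",
    annotationBaseRate = "numeric",
    annotationWeight = "numeric",
    chromLengths = "numeric",
    nChd = "integer",
    nControl = "integer",
    dnvMu = "numeric",
    dnvSize = "numeric",
    cohortEffectFraction = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  prop <- c(
    activeFraction = object@activeFraction,
    variantEffectFraction = object@variantEffectFraction,
    annotationBaseRate = object@annotationBaseRate,
    cohortEffectFraction = object@cohortEffectFraction
  )
  bad <- prop < 0 | prop > 1
  if (any(bad)) {
    msg <- c(msg, paste0(names(prop)[bad], " must lie in [0, 1]"))
  }
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
  if (object@dnaDepth <= 0 || object@rnaDepth <= 0) {
    msg <- c(msg, "sequencing depths must be > 0")
  }
  if (object@annotationInformativeCount > object@annotationCount) {
    msg <- c(msg, "annotationInformativeCount must be <= annotationCount")
  }
  if (object@regionLength < 171L) {
    msg <- c(msg, "regionLength must be >= 171 bp")
  }
  if (length(object@activityLog2fcRange) != 2L ||
      diff(object@activityLog2fcRange) < 0) {
    msg <- c(msg, "activityLog2fcRange must be a non-decreasing interval")
  }
  if (object@nChd <= 0L || object@nControl <= 0L) {
    msg <- c(msg, "cohort sizes must be > 0")
  }
  if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0)) {
    msg <- c(msg, "chromLengths must be named and positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param seed master seed (integer).
#' @param nRegions,regionLength,nReplicates library geometry.
#' @param dnaDepth,rnaDepth per-replicate sequencing depths.
#' @param nbDispersion NB dispersion alpha.
#' @param activeFraction,activityLog2fcRange activity structure.
#' @param variantEffectFraction,variantEffectLog2fc allelic-effect structure.
#' @param annotationCount,annotationInformativeCount,annotationBaseRate,annotationWeight
#'   annotation-track structure.
#' @param chromLengths named numeric chromosome sizes.
#' @param nChd,nControl,dnvMu,dnvSize,cohortEffectFraction trio-cohort
#'   parameters.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(seed = 1, nRegions = 50)
#' cfg
#' @export
SimConfig <- function(seed = 1L, nRegions = 200L, regionLength = 400L,
                      nReplicates = 4L, dnaDepth = 2e6, rnaDepth = 2e6,
                      nbDispersion = 0.05, activeFraction = 0.3,
                      activityLog2fcRange = c(1, 3),
                      variantEffectFraction = 0.1, variantEffectLog2fc = 1.5,
                      annotationCount = 40L, annotationInformativeCount = 5L,
                      annotationBaseRate = 0.2, annotationWeight = 2.5,
                      chromLengths = c(chrS1 = 6e5, chrS2 = 4e5),
                      nChd = 200L, nControl = 300L,
                      dnvMu = 8.25, dnvSize = 11,
                      cohortEffectFraction = 0) {
  new("SimConfig",
    seed = as.integer(seed), nRegions = as.integer(nRegions),
    regionLength = as.integer(regionLength),
    nReplicates = as.integer(nReplicates),
    dnaDepth = dnaDepth, rnaDepth = rnaDepth, nbDispersion = nbDispersion,
    activeFraction = activeFraction,
    activityLog2fcRange = as.numeric(activityLog2fcRange),
    variantEffectFraction = variantEffectFraction,
    variantEffectLog2fc = variantEffectLog2fc,
    annotationCount = as.integer(annotationCount),
    annotationInformativeCount = as.integer(annotationInformativeCount),
    annotationBaseRate = annotationBaseRate,
    annotationWeight = annotationWeight, chromLengths = chromLengths,
    nChd = as.integer(nChd), nControl = as.integer(nControl),
    dnvMu = dnvMu, dnvSize = dnvSize,
    cohortEffectFraction = cohortEffectFraction
  )
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n",
    "  seed: ", object@seed, "\n",
    "  regions: ", object@nRegions, " x ", object@regionLength, " bp, ",
    object@nReplicates, " replicates\n",
    "  depths (DNA/RNA): ", object@dnaDepth, " / ", object@rnaDepth,
    ", NB dispersion ", object@nbDispersion, "\n",
    "  active fraction: ", object@activeFraction, " (log2 mult in [",
    object@activityLog2fcRange[1], ", ", object@activityLog2fcRange[2], "])\n",
    "  annotations: ", object@annotationCount, " (",
    object@annotationInformativeCount, " informative)\n",
    "  cohorts: ", object@nChd, " CHD / ", object@nControl, " control\n",
    sep = ""
  )
})

#' Ground truth of a simulation
#'
#' Records what the generators planted, so tests can score recovery: the true
#' per-region activity multiplier, per-pair allelic effects, which annotation
#' tracks are informative (and their logistic weights), and any planted motif
#' instances.
#'
#' @slot multipliers named numeric; true log2 RNA/DNA multiplier per region.
#' @slot pairEffects named character; "none", "up" or "down" per REF/ALT pair.
#' @slot informativeTracks character; ids of informative annotation tracks.
#' @slot trackWeights named numeric; logistic weight per informative track.
#' @slot plantedMotifs DataFrame with columns motif_id, region_id, offset,
#'   strand (possibly zero rows).
#' @export
setClass("GroundTruth",
  representation(
    multipliers = "numeric",
    pairEffects = "character",
    informativeTracks = "character",
    trackWeights = "numeric",
    plantedMotifs = "DataFrame"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (is.null(names(object@multipliers))) {
    msg <- c(msg, "multipliers must be named by region id")
  }
  if (length(object@pairEffects) &&
      !all(object@pairEffects %in% c("none", "up", "down"))) {
    msg <- c(msg, "pairEffects values must be none/up/down")
  }
  if (nrow(object@plantedMotifs) > 0 &&
      !all(object@plantedMotifs$region_id %in% names(object@multipliers))) {
    msg <- c(msg, "planted motifs must reference existing regions")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth: ", length(object@multipliers), " regions (",
    sum(object@multipliers != 0), " active), ",
    sum(object@pairEffects != "none"), "/", length(object@pairEffects),
    " effect pairs, ", length(object@informativeTracks),
    " informative tracks, ", nrow(object@plantedMotifs),
    " planted motifs\n",
    sep = ""
  )
})

#' Container for MPRA count data
#'
#' A thin [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#' with two required assays, `dna` and `rna`, holding raw barcode counts for
#' each design (rows) in each replicate (columns). Depth-normalized FPM assays
#' are added by [normalizeFpm()].
#'
#' @export
setClass("MpraExperiment", contains = "SummarizedExperiment")

setValidity("MpraExperiment", function(object) {
  msg <- character()
  if (!all(c("dna", "rna") %in% assayNames(object))) {
    msg <- c(msg, "assays 'dna' and 'rna' are required")
  } else {
    if (any(assay(object, "dna") < 0) || any(assay(object, "rna") < 0)) {
      msg <- c(msg, "counts must be non-negative")
    }
  }
  if (is.null(rownames(object))) msg <- c(msg, "designs must be named (rownames)")
  if (length(msg)) msg else TRUE
})

#' Construct an MpraExperiment from DNA and RNA count matrices
#'
#' @param dna,rna integer matrices, designs x replicates, identical dimnames.
#' @param rowData optional per-design metadata.
#' @param ... passed to `SummarizedExperiment()`.
#' @return An [MpraExperiment-class].
#' @examples
#' dna <- matrix(rpois(8, 100), 4, 2, dimnames = list(paste0("d", 1:4), NULL))
#' rna <- matrix(rpois(8, 100), 4, 2, dimnames = list(paste0("d", 1:4), NULL))
#' MpraExperiment(dna, rna)
#' @export
MpraExperiment <- function(dna, rna, rowData = NULL, ...) {
  stopifnot(identical(dim(dna), dim(rna)))
  if (is.null(colnames(dna))) {
    colnames(dna) <- colnames(rna) <- paste0("rep", seq_len(ncol(dna)))
  }
  args <- list(assays = list(dna = dna, rna = rna), ...)
  if (!is.null(rowData)) args$rowData <- rowData
  se <- do.call(SummarizedExperiment, args)
  new("MpraExperiment", se)
}

#' @describeIn MpraExperiment DNA count matrix accessor.
#' @param x an MpraExperiment.
#' @export
dnaCounts <- function(x) assay(x, "dna")

#' @describeIn MpraExperiment RNA count matrix accessor.
#' @export
rnaCounts <- function(x) assay(x, "rna")

setMethod("show", "MpraExperiment", function(object) {
  cat("MpraExperiment: ", nrow(object), " designs x ", ncol(object),
    " replicates; assays: ", paste(assayNames(object), collapse = ", "),
    "\n",
    sep = ""
  )
})

#' Position weight matrix with background model
#'
#' Column-stochastic base-probability model of a transcription-factor binding
#' site, stored as a 4 x L matrix (rows A, C, G, T), together with the
#' background base frequencies used for log-odds scoring and exact p-values.
#'
#' @slot id motif identifier.
#' @slot family motif family label.
#' @slot matrix 4 x L numeric, columns sum to 1.
#' @slot background length-4 numeric base frequencies (A, C, G, T).
#' @export
setClass("PositionWeightMatrix",
  representation(
    id = "character", family = "character",
    matrix = "matrix", background = "numeric"
  )
)

setValidity("PositionWeightMatrix", function(object) {
  msg <- character()
  m <- object@matrix
  if (nrow(m) != 4L) msg <- c(msg, "matrix must have 4 rows (A, C, G, T)")
  if (ncol(m) < 2L) msg <- c(msg, "motif length must be >= 2")
  if (any(abs(colSums(m) - 1) > 1e-9)) {
    msg <- c(msg, "matrix columns must sum to 1 (tolerance 1e-9)")
  }
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-9) {
    msg <- c(msg, "background must be 4 frequencies summing to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PositionWeightMatrix
#'
#' @param id motif identifier.
#' @param matrix 4 x L probability matrix; rows are A, C, G, T.
#' @param background background base frequencies (default uniform).
#' @param family motif family label (defaults to `id`).
#' @return A [PositionWeightMatrix-class].
#' @examples
#' m <- matrix(c(
#'   0.97, 0.01, 0.01, 0.01,
#'   0.01, 0.97, 0.01, 0.01,
#'   0.01, 0.01, 0.97, 0.01
#' ), nrow = 4)
#' PositionWeightMatrix("toy", m)
#' @export
PositionWeightMatrix <- function(id, matrix, background = rep(0.25, 4),
                                 family = id) {
  rownames(matrix) <- c("A", "C", "G", "T")
  new("PositionWeightMatrix",
    id = id, family = family,
    matrix = matrix, background = background
  )
}

#' @describeIn PositionWeightMatrix motif length in bp.
#' @param x a PositionWeightMatrix.
#' @export
motifLength <- function(x) ncol(x@matrix)

#' @describeIn PositionWeightMatrix consensus sequence (modal base per column).
#' @export
motifConsensus <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x@matrix, 2, which.max)], collapse = "")
}

setMethod("show", "PositionWeightMatrix", function(object) {
  cat("PositionWeightMatrix '", object@id, "' (family ", object@family,
    "), length ", motifLength(object), ", consensus ",
    motifConsensus(object), "\n",
    sep = ""
  )
})

#' Fitted EpiCard annotation model
#'
#' Sparse LASSO model mapping annotation-overlap features of a genomic window
#' to predicted MPRA activity (continuous family) or to the log-odds of being
#' an active enhancer (binary family). Scores are reported on the linear
#' predictor scale.
#'
#' @slot family "continuous" or "binary".
#' @slot coefficients named numeric, original feature scale (zeros retained).
#' @slot intercept numeric.
#' @slot lambda penalty at which the model was extracted (cross-validated
#'   lambda divided by ten).
#' @slot metadata list; folds, seed, cross-validation lambda.
#' @export
setClass("EpiCardModel",
  representation(
    family = "character", coefficients = "numeric",
    intercept = "numeric", lambda = "numeric", metadata = "list"
  )
)

setValidity("EpiCardModel", function(object) {
  msg <- character()
  if (!object@family %in% c("continuous", "binary")) {
    msg <- c(msg, "family must be 'continuous' or 'binary'")
  }
  if (any(!is.finite(object@coefficients)) || !is.finite(object@intercept)) {
    msg <- c(msg, "coefficients and intercept must be finite")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EpiCardModel", function(object) {
  cat("EpiCardModel (", object@family, "): ",
    sum(object@coefficients != 0), "/", length(object@coefficients),
    " nonzero features, lambda = ", signif(object@lambda, 4), "\n",
    sep = ""
  )
})

#' @describeIn EpiCardModel named coefficient vector (zeros included).
#' @param object an EpiCardModel.
#' @export
epicardCoef <- function(object) object@coefficients
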