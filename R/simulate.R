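#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect resize mcols mcols<-
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq
#'   writeXStringSet
#' @importFrom stats rnbinom rgamma runif rnorm rbinom quantile
NULL

# One master seed expands into independent substreams so regenerating one
# input never shifts the randomness of another.
.substream <- function(config, k) {
  set.seed((config@seed %% 100003L) * 131L + k)
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a synthetic genome and candidate-region table
#'
#' Generates random chromosome sequences of the configured lengths and places
#' `nRegions` non-overlapping candidate enhancer regions on them (0-based
#' half-open internally; exported BED keeps that convention). Deterministic
#' under a fixed seed.
#'
#' @param config a [SimConfig-class].
#' @return A list with `genome` (a `DNAStringSet`) and `regions` (a `GRanges`
#'   with a `region_id` metadata column).
#' @examples
#' sim <- simulateGenome(SimConfig(seed = 1, nRegions = 20))
#' length(sim$regions)
#' @export
simulateGenome <- function(config) {
  .substream(config, 1L)
  L <- config@regionLength
  gap <- 20L
  slots <- floor(config@chromLengths / (L + gap))
  if (sum(slots) < config@nRegions) {
    stop(
      "cannot place ", config@nRegions, " regions of ", L,
      " bp on chromosomes totalling ", sum(config@chromLengths), " bp"
    )
  }
  genome <- DNAStringSet(vapply(
    config@chromLengths, .randomDna, character(1)
  ))
  names(genome) <- names(config@chromLengths)

  # spread regions over chromosomes proportionally to capacity, then place
  # each region in its own slot with random jitter inside the slot
  perChrom <- floor(config@nRegions * slots / sum(slots))
  while (sum(perChrom) < config@nRegions) {
    i <- which.max(slots - perChrom)
    perChrom[i] <- perChrom[i] + 1L
  }
  chrom <- character(0)
  startAt <- integer(0)
  for (i in seq_along(genome)) {
    if (perChrom[i] == 0L) next
    pick <- sort(sample(slots[i], perChrom[i]))
    slotStart <- (pick - 1L) * (L + gap)
    jitter <- sample(0:gap, perChrom[i], replace = TRUE)
    chrom <- c(chrom, rep(names(genome)[i], perChrom[i]))
    startAt <- c(startAt, slotStart + jitter + 1L)
  }
  regs <- GRanges(chrom, IRanges(start = startAt, width = L))
  regs <- regs[order(as.character(seqnames(regs)), start(regs))]
  mcols(regs)$region_id <- sprintf("region_%04d", seq_along(regs))
  names(regs) <- mcols(regs)$region_id
  list(genome = genome, regions = regs)
}

#' Draw the ground truth of a simulation
#'
#' Assigns a true log2 activity multiplier to a random `activeFraction` of
#' regions (uniform over `activityLog2fcRange`), allelic effects to a random
#' `variantEffectFraction` of REF/ALT pairs, and designates the informative
#' annotation tracks with their logistic weights.
#'
#' @param regions `GRanges` from [simulateGenome()].
#' @param config a [SimConfig-class].
#' @return A [GroundTruth-class].
#' @export
simulateTruth <- function(regions, config) {
  .substream(config, 2L)
  ids <- names(regions)
  n <- length(ids)
  mult <- setNames(numeric(n), ids)
  nActive <- round(config@activeFraction * n)
  if (nActive > 0) {
    act <- sample(ids, nActive)
    mult[act] <- runif(
      nActive, config@activityLog2fcRange[1], config@activityLog2fcRange[2]
    )
  }
  effects <- setNames(rep("none", n), ids)
  nEff <- round(config@variantEffectFraction * n)
  if (nEff > 0) {
    eff <- sample(ids, nEff)
    effects[eff] <- sample(c("up", "down"), nEff, replace = TRUE)
  }
  nInf <- config@annotationInformativeCount
  informative <- sprintf("track_%03d", seq_len(nInf))
  new("GroundTruth",
    multipliers = mult, pairEffects = effects,
    informativeTracks = informative,
    trackWeights = setNames(rep(config@annotationWeight, nInf), informative),
    plantedMotifs = DataFrame(
      motif_id = character(), region_id = character(),
      offset = integer(), strand = character()
    )
  )
}

#' Simulate DNA/RNA barcode counts
#'
#' DNA counts are negative binomial around each design's library abundance
#' times sequencing depth (variance mu + alpha * mu^2); RNA means equal the
#' DNA relative abundance times `2^trueLog2Multiplier` times RNA depth, with
#' the same dispersion. Abundances are gamma-distributed to emulate uneven
#' oligo synthesis.
#'
#' @param truth a [GroundTruth-class]; one design per region.
#' @param config a [SimConfig-class].
#' @param designIds optional subset/ordering of design ids (default: all
#'   regions in `truth`).
#' @param multipliers optional named override of true log2 multipliers (e.g.
#'   for ALT designs carrying an allelic effect).
#' @return An [MpraExperiment-class] with `dna` and `rna` assays and the true
#'   multiplier in `rowData()$trueLog2`.
#' @examples
#' cfg <- SimConfig(seed = 1, nRegions = 30)
#' truth <- simulateTruth(simulateGenome(cfg)$regions, cfg)
#' se <- simulateCounts(truth, cfg)
#' se
#' @export
simulateCounts <- function(truth, config, designIds = NULL,
                           multipliers = NULL) {
  if (config@nbDispersion <= 0) stop("nbDispersion must be > 0")
  .substream(config, 3L)
  ids <- if (is.null(designIds)) names(truth@multipliers) else designIds
  if (!all(ids %in% names(truth@multipliers))) {
    stop("all design ids must be present in the ground truth")
  }
  mult <- truth@multipliers[ids]
  if (!is.null(multipliers)) mult[names(multipliers)] <- multipliers
  n <- length(ids)
  k <- config@nReplicates
  size <- 1 / config@nbDispersion
  abundance <- rgamma(n, shape = 5, rate = 5)
  abundance <- abundance / sum(abundance)
  muDna <- abundance * config@dnaDepth
  muRna <- abundance * 2^mult * config@rnaDepth
  dna <- matrix(rnbinom(n * k, mu = rep(muDna, k), size = size), n, k)
  rna <- matrix(rnbinom(n * k, mu = rep(muRna, k), size = size), n, k)
  dimnames(dna) <- dimnames(rna) <-
    list(ids, paste0("rep", seq_len(k)))
  MpraExperiment(dna, rna,
    rowData = DataFrame(trueLog2 = unname(mult), row.names = ids)
  )
}

#' Simulate annotation tracks
#'
#' Informative tracks overlap each region with probability
#' `plogis(qlogis(baseRate) + weight * active)`, i.e. active regions are
#' overlapped at raised odds; uninformative tracks overlap independently of
#' activity at the base rate. Overlapping intervals are jittered around the
#' region and carry a non-negative `score` value column.
#'
#' @param regions `GRanges` of candidate regions.
#' @param truth a [GroundTruth-class].
#' @param config a [SimConfig-class].
#' @return Named list of `GRanges` tracks (possibly empty) with a `score`
#'   column.
#' @export
simulateAnnotations <- function(regions, truth, config) {
  .substream(config, 4L)
  active <- truth@multipliers[names(regions)] != 0
  baseLogit <- stats::qlogis(config@annotationBaseRate)
  tracks <- vector("list", config@annotationCount)
  names(tracks) <- sprintf("track_%03d", seq_len(config@annotationCount))
  for (t in seq_len(config@annotationCount)) {
    id <- names(tracks)[t]
    w <- if (id %in% truth@informativeTracks) truth@trackWeights[[id]] else 0
    p <- stats::plogis(baseLogit + w * active)
    hit <- runif(length(regions)) < p
    if (!any(hit)) {
      tracks[[t]] <- GRanges(score = numeric())
      next
    }
    hr <- regions[hit]
    jitterL <- sample(0:60, sum(hit), replace = TRUE)
    jitterR <- sample(0:60, sum(hit), replace = TRUE)
    gr <- GRanges(
      seqnames(hr),
      IRanges(
        start = pmax(1L, start(hr) - jitterL),
        end = end(hr) + jitterR
      )
    )
    mcols(gr)$score <- abs(rnorm(length(gr), mean = 2, sd = 1))
    tracks[[t]] <- sort(gr)
  }
  tracks
}

#' Simulate CHD-like and control-like trio cohorts
#'
#' Per-participant noncoding de novo variant counts are negative binomial with
#' `dnvMu`/`dnvSize` (defaults give a median of 8 and interquartile range
#' 6-11). With `cohortEffectFraction > 0`, that fraction of case-cohort
#' variants is placed inside active regions (high-annotation context); all
#' other variants land uniformly on the genome.
#'
#' @param config a [SimConfig-class].
#' @param genome `DNAStringSet` from [simulateGenome()] (for ref alleles).
#' @param regions `GRanges` of candidate regions (needed when
#'   `cohortEffectFraction > 0`).
#' @param truth a [GroundTruth-class] (needed when `cohortEffectFraction > 0`).
#' @return List of two data.frames (`chd`, `control`) with columns chrom, pos
#'   (1-based), ref, alt, participant.
#' @export
simulateCohort <- function(config, genome, regions = NULL, truth = NULL) {
  .substream(config, 5L)
  activeRegions <- NULL
  if (config@cohortEffectFraction > 0) {
    if (is.null(regions) || is.null(truth)) {
      stop("regions and truth are required when cohortEffectFraction > 0")
    }
    activeRegions <- regions[truth@multipliers[names(regions)] != 0]
  }
  drawCohort <- function(nPart, prefix, enriched) {
    counts <- rnbinom(nPart, mu = config@dnvMu, size = config@dnvSize)
    total <- sum(counts)
    participant <- rep(sprintf("%s_%04d", prefix, seq_len(nPart)), counts)
    chrom <- character(total)
    pos <- integer(total)
    inActive <- enriched &
      runif(total) < config@cohortEffectFraction &
      length(activeRegions) > 0
    nAct <- sum(inActive)
    if (nAct > 0) {
      pick <- sample(length(activeRegions), nAct, replace = TRUE)
      chrom[inActive] <- as.character(seqnames(activeRegions))[pick]
      pos[inActive] <- start(activeRegions)[pick] +
        sample.int(width(activeRegions)[1], nAct, replace = TRUE) - 1L
    }
    nBg <- total - nAct
    if (nBg > 0) {
      chromPick <- sample(names(genome), nBg,
        replace = TRUE, prob = width(genome)
      )
      chrom[!inActive] <- chromPick
      pos[!inActive] <- vapply(
        chromPick,
        function(cn) sample.int(length(genome[[cn]]) - 200L, 1L) + 100L,
        integer(1)
      )
    }
    ref <- vapply(
      seq_len(total),
      function(i) as.character(subseq(genome[[chrom[i]]], pos[i], pos[i])),
      character(1)
    )
    alt <- vapply(ref, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      participant = participant, stringsAsFactors = FALSE
    )
  }
  list(
    chd = drawCohort(config@nChd, "chd", enriched = TRUE),
    control = drawCohort(config@nControl, "ctrl", enriched = FALSE)
  )
}

#' Write simulated genome and regions to disk
#'
#' FASTA for the genome, BED (0-based half-open) for the region table.
#' Byte-identical across runs with the same configuration.
#'
#' @param sim list from [simulateGenome()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
exportSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  bed <- file.path(dir, "regions.bed")
  writeXStringSet(sim$genome, fa)
  df <- data.frame(
    chrom = as.character(seqnames(sim$regions)),
    start = start(sim$regions) - 1L,
    end = end(sim$regions),
    name = names(sim$regions)
  )
  utils::write.table(df, bed,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(c(fasta = fa, bed = bed))
}
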