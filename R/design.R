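#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

.asDna <- function(x) if (is(x, "DNAString")) x else DNAString(as.character(x))

#' Design a self-priming STARR oligo pair for a 400 bp region
#'
#' Each 400 bp assay region is encoded on two 230 nt oligonucleotides with a
#' 20 bp 3' overlap; the 5' ends carry 20 bp primer binding sites, so that
#' self-priming PCR extends the annealed pair to the full 400 bp insert
#' flanked by primers. The left oligo is `primerLeft + region[1..210]` on the
#' top strand; the right oligo is the reverse complement of
#' `region[191..400] + revcomp(primerRight)`, i.e. it reads
#' `primerRight + revcomp(region[191..400])` 5'->3'.
#'
#' @param region 400 bp sequence (character or `DNAString`).
#' @param primerLeft,primerRight 20 bp primer binding sites.
#' @param id identifier used in error messages.
#' @return List with `left` and `right` `DNAString`s, both 230 nt.
#' @examples
#' reg <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
#'   collapse = ""
#' )
#' pair <- designStarrPair(reg)
#' nchar(as.character(pair$left))
#' @export
designStarrPair <- function(region,
                            primerLeft = "AGGACCGGATCAACTCGAGT",
                            primerRight = "TCGACGAATTCGGCCTTAAG",
                            id = "region") {
  region <- .asDna(region)
  if (length(region) != 400L) {
    stop("region '", id, "' has length ", length(region), ", expected 400")
  }
  primerLeft <- .asDna(primerLeft)
  primerRight <- .asDna(primerRight)
  if (length(primerLeft) != 20L || length(primerRight) != 20L) {
    stop("primers must be 20 nt")
  }
  left <- Biostrings::xscat(primerLeft, subseq(region, 1L, 210L))
  right <- Biostrings::xscat(
    primerRight, reverseComplement(subseq(region, 191L, 400L))
  )
  list(left = DNAString(left), right = DNAString(right))
}

#' Assemble a STARR oligo pair back into its 400 bp region
#'
#' In-silico self-priming assembly: strips the primers, reverse-complements
#' the right oligo, verifies the 20 bp overlap and returns the reconstructed
#' region. Errors if the overlap disagrees.
#'
#' @param pair list with `left` and `right` as from [designStarrPair()].
#' @inheritParams designStarrPair
#' @return The 400 bp `DNAString`.
#' @export
assembleStarrPair <- function(pair,
                              primerLeft = "AGGACCGGATCAACTCGAGT",
                              primerRight = "TCGACGAATTCGGCCTTAAG") {
  left <- .asDna(pair$left)
  right <- .asDna(pair$right)
  leftIns <- subseq(left, 21L, length(left)) # region[1..210]
  rightIns <- reverseComplement(subseq(right, 21L, length(right)))
  ovLeft <- subseq(leftIns, length(leftIns) - 19L, length(leftIns))
  ovRight <- subseq(rightIns, 1L, 20L)
  if (as.character(ovLeft) != as.character(ovRight)) {
    stop("oligo pair 3' overlaps disagree; not a valid self-priming pair")
  }
  DNAString(Biostrings::xscat(
    leftIns, subseq(rightIns, 21L, length(rightIns))
  ))
}

#' Generate a set of well-separated barcodes
#'
#' Random 15 nt (by default) barcodes with pairwise Hamming distance at least
#' `minHamming` and no homopolymer run longer than `maxHomopolymer`, to guard
#' against sequencing errors and barcode hopping between similar oligos.
#' Greedy rejection sampling; deterministic under `seed`.
#'
#' @param n number of barcodes.
#' @param length barcode length in nt.
#' @param minHamming minimum pairwise Hamming distance.
#' @param maxHomopolymer longest allowed single-base run.
#' @param seed integer seed.
#' @return Character vector of `n` barcodes.
#' @examples
#' bc <- assignBarcodes(10, seed = 1)
#' anyDuplicated(bc)
#' @export
assignBarcodes <- function(n, length = 15L, minHamming = 3L,
                           maxHomopolymer = 4L, seed = 1L) {
  if (n > 4^length) {
    stop("cannot draw ", n, " distinct barcodes of length ", length)
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  accepted <- matrix(NA_integer_, nrow = length, ncol = n)
  got <- 0L
  attempts <- 0L
  maxAttempts <- 2000L * n + 10000L
  homo <- function(v) max(rle(v)$lengths)
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts) {
      stop(
        "barcode pool exhausted: could not find ", n,
        " barcodes with min Hamming ", minHamming
      )
    }
    cand <- sample.int(4L, length, replace = TRUE)
    if (homo(cand) > maxHomopolymer) next
    if (got > 0L) {
      d <- colSums(accepted[, seq_len(got), drop = FALSE] != cand)
      if (min(d) < minHamming) next
    }
    got <- got + 1L
    accepted[, got] <- cand
  }
  apply(accepted, 2, function(v) paste(bases[v], collapse = ""))
}

.fragmentStarts <- function(regionLength = 400L, fragLength = 171L) {
  # F1 flush left, F2 centered, F3 flush right; adjacent overlaps >= 55 bp
  c(
    F1 = 1L,
    F2 = as.integer(floor((regionLength - fragLength) / 2)) + 1L,
    F3 = regionLength - fragLength + 1L
  )
}

#' Design a tiling-deletion mutagenesis library for one 400 bp region
#'
#' The region is represented as three overlapping 171 bp fragments (F1 flush
#' left, F2 centered, F3 flush right). Each fragment yields one wild-type
#' oligo plus 17 deletion oligos, removing the 10 bp window at offsets 0, 10,
#' ..., 160 (covering positions 1-170; the 171st base is untiled). Every
#' design gets a distinct barcode.
#'
#' @param region 400 bp sequence.
#' @param regionId identifier prefix for design ids.
#' @param barcodes character vector of at least 54 unused barcodes.
#' @return A `DataFrame` of 54 designs with columns id, role, fragment,
#'   deletion_offset, insert, barcode, frag_start (1-based within region).
#' @examples
#' reg <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
#'   collapse = ""
#' )
#' dsg <- designTiling(reg, "r1", assignBarcodes(54, seed = 3))
#' table(dsg$role)
#' @export
designTiling <- function(region, regionId, barcodes) {
  region <- .asDna(region)
  if (length(region) != 400L) {
    stop("region '", regionId, "' has length ", length(region), ", expected 400")
  }
  nNeeded <- 3L * 18L
  if (length(barcodes) < nNeeded) {
    stop("barcode pool exhausted: need ", nNeeded, ", got ", length(barcodes))
  }
  starts <- .fragmentStarts(400L, 171L)
  rows <- vector("list", nNeeded)
  k <- 0L
  for (f in names(starts)) {
    frag <- subseq(region, starts[[f]], starts[[f]] + 170L)
    fragChar <- as.character(frag)
    k <- k + 1L
    rows[[k]] <- data.frame(
      id = paste(regionId, f, "WT", sep = "_"), role = "WT_FRAGMENT",
      fragment = f, deletion_offset = NA_integer_, insert = fragChar,
      frag_start = starts[[f]], stringsAsFactors = FALSE
    )
    for (off in seq(0L, 160L, by = 10L)) {
      k <- k + 1L
      del <- paste0(
        substr(fragChar, 1L, off),
        substr(fragChar, off + 11L, 171L)
      )
      rows[[k]] <- data.frame(
        id = paste(regionId, f, sprintf("del%03d", off), sep = "_"),
        role = "DELETION", fragment = f, deletion_offset = off,
        insert = del, frag_start = starts[[f]], stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$barcode <- barcodes[seq_len(nNeeded)]
  DataFrame(out)
}

#' Design a REF/ALT oligo pair for a variant
#'
#' The REF insert is the 171 bp genome slice centered on the variant (for an
#' SNV the variant base sits at 1-based offset 86); the ALT insert substitutes
#' the alternate allele with identical flanks, so an indel shifts the insert
#' length by `nchar(alt) - nchar(ref)`. For multi-base alleles the REF
#' allele's first base is centered.
#'
#' @param variant list or one-row data.frame with `chrom`, `pos` (1-based),
#'   `ref`, `alt` and optionally `id`.
#' @param genome named `DNAStringSet`.
#' @param barcodes character vector of at least 2 unused barcodes.
#' @return A `DataFrame` with two rows (roles REF and ALT).
#' @export
designRefAlt <- function(variant, genome, barcodes = c(NA, NA)) {
  chrom <- as.character(variant$chrom)
  pos <- as.integer(variant$pos)
  ref <- as.character(variant$ref)
  alt <- as.character(variant$alt)
  vid <- if (!is.null(variant$id)) {
    as.character(variant$id)
  } else {
    paste0(chrom, ":", pos, ref, ">", alt)
  }
  if (!chrom %in% names(genome)) stop("chromosome ", chrom, " not in genome")
  chromSeq <- genome[[chrom]]
  flank <- 85L # (171 - 1) / 2 on each side of the centered base
  startPos <- pos - flank
  endPos <- pos + flank
  if (startPos < 1L || endPos > length(chromSeq)) {
    stop(
      "variant ", vid, " too close to a chromosome end for 171 bp flanks"
    )
  }
  refIns <- as.character(subseq(chromSeq, startPos, endPos))
  genomeAllele <- substr(refIns, flank + 1L, flank + nchar(ref))
  if (nchar(ref) > nchar(refIns) - flank ||
      genomeAllele != ref) {
    stop(
      "ref allele mismatch at ", chrom, ":", pos, ": genome has '",
      genomeAllele, "', variant table says '", ref, "'"
    )
  }
  altIns <- paste0(
    substr(refIns, 1L, flank), alt,
    substr(refIns, flank + nchar(ref) + 1L, 171L)
  )
  DataFrame(data.frame(
    id = paste(vid, c("REF", "ALT"), sep = "_"),
    role = c("REF", "ALT"),
    variant_id = vid, chrom = chrom, pos = pos,
    insert = c(refIns, altIns),
    barcode = barcodes[1:2],
    stringsAsFactors = FALSE
  ))
}

#' Prioritize noncoding de novo variants for MPRA testing
#'
#' A variant is retained if it is noncoding (outside any supplied coding
#' exon) and at least one of: (1) it lies inside a supplied enhancer interval
#' whose closest gene (by linear TSS distance, ties broken by lower
#' coordinate) carries at least `minGeneDnvs` cohort ncDNVs; (2) it lies
#' within `tssWindow` bp of the TSS of a prioritized gene; (3) it carries an
#' external priority flag.
#'
#' @param variants data.frame with chrom, pos (1-based), and optionally a
#'   logical `priority_flag` column.
#' @param geneTable data.frame with gene, chrom, tss (1-based) and a logical
#'   `prioritized` column.
#' @param enhancers `GRanges` of enhancer intervals (may be empty).
#' @param tssWindow distance to a prioritized TSS, bp (default 20 kb).
#' @param minGeneDnvs cohort ncDNV count required of an enhancer's closest
#'   gene.
#' @param codingExons optional `GRanges`; variants inside are dropped.
#' @return The retained subset of `variants` with a `reason` column.
#' @export
prioritizeVariants <- function(variants, geneTable, enhancers,
                               tssWindow = 20000L, minGeneDnvs = 3L,
                               codingExons = NULL) {
  if (is.null(geneTable$tss)) stop("gene table must carry a 'tss' column")
  vgr <- GRanges(variants$chrom, IRanges(variants$pos, width = 1L))

  noncoding <- rep(TRUE, nrow(variants))
  if (!is.null(codingExons) && length(codingExons)) {
    noncoding <- !IRanges::overlapsAny(vgr, codingExons)
  }

  # closest gene per variant: linear TSS distance, tie -> lower coordinate
  closestGene <- function(chrom, pos) {
    cand <- geneTable[geneTable$chrom == chrom, , drop = FALSE]
    if (!nrow(cand)) return(NA_character_)
    d <- abs(cand$tss - pos)
    cand <- cand[order(d, cand$tss), , drop = FALSE]
    cand$gene[1]
  }
  vGene <- mapply(closestGene, variants$chrom, variants$pos)
  geneDnvCounts <- table(vGene)

  nearPriorTss <- vapply(seq_len(nrow(variants)), function(i) {
    cand <- geneTable[
      geneTable$chrom == variants$chrom[i] & geneTable$prioritized, ,
      drop = FALSE
    ]
    nrow(cand) > 0 && any(abs(cand$tss - variants$pos[i]) <= tssWindow)
  }, logical(1))

  inEnhancer <- rep(FALSE, nrow(variants))
  if (length(enhancers)) {
    hits <- findOverlaps(vgr, enhancers)
    if (length(hits)) {
      enhGene <- mapply(
        closestGene,
        as.character(seqnames(enhancers)),
        (start(enhancers) + end(enhancers)) %/% 2L
      )
      enhOk <- !is.na(enhGene) &
        enhGene %in% names(geneDnvCounts)[geneDnvCounts >= minGeneDnvs]
      inEnhancer[S4Vectors::queryHits(hits)] <-
        inEnhancer[S4Vectors::queryHits(hits)] |
        enhOk[S4Vectors::subjectHits(hits)]
    }
  }

  flagged <- if (!is.null(variants$priority_flag)) {
    as.logical(variants$priority_flag)
  } else {
    rep(FALSE, nrow(variants))
  }

  keep <- noncoding & (inEnhancer | nearPriorTss | flagged)
  out <- variants[keep, , drop = FALSE]
  out$reason <- paste0(
    ifelse(inEnhancer[keep], "enhancer;", ""),
    ifelse(nearPriorTss[keep], "tss20kb;", ""),
    ifelse(flagged[keep], "flag;", "")
  )
  out
}
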