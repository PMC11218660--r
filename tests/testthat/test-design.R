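test_that("STARR pairs have the published geometry and assemble exactly", {
  # 2 x 230 - 20 (overlap) - 2 x 20 (primers) = 400
  expect_equal(2 * 230 - 20 - 2 * 20, 400)
  for (s in 1:10) {
    reg <- randomSeq(400, seed = 100 + s)
    pair <- designStarrPair(reg)
    expect_equal(length(pair$left), 230)
    expect_equal(length(pair$right), 230)
    expect_identical(as.character(assembleStarrPair(pair)), reg)
  }
  expect_error(designStarrPair(randomSeq(399), id = "bad1"), "bad1")
})

test_that("tiling designs partition each fragment into 17 ten-bp tiles", {
  reg <- randomSeq(400, seed = 11)
  bc <- assignBarcodes(54, seed = 4)
  dsg <- designTiling(reg, "r1", bc)
  expect_equal(nrow(dsg), 54)
  expect_equal(sum(dsg$role == "WT_FRAGMENT"), 3)
  for (f in c("F1", "F2", "F3")) {
    del <- dsg[dsg$fragment == f & dsg$role == "DELETION", ]
    expect_equal(nrow(del), 17)
    expect_true(all(nchar(del$insert) == 161))
    # deleted windows tile positions 1-170 with no gaps or overlaps
    covered <- unlist(lapply(del$deletion_offset, function(o) (o + 1):(o + 10)))
    expect_identical(sort(covered), 1:170)
    wt <- dsg[dsg$fragment == f & dsg$role == "WT_FRAGMENT", ]
    expect_equal(nchar(wt$insert), 171)
    # deletion inserts really are the WT minus the window
    o <- del$deletion_offset[5]
    expect_identical(
      del$insert[5],
      paste0(substr(wt$insert, 1, o), substr(wt$insert, o + 11, 171))
    )
  }
  expect_false(anyDuplicated(dsg$barcode) > 0)
  # fragments re-extract identically from the region (round trip)
  for (i in which(dsg$role == "WT_FRAGMENT")) {
    expect_identical(
      dsg$insert[i],
      substr(reg, dsg$frag_start[i], dsg$frag_start[i] + 170)
    )
  }
  expect_error(designTiling(reg, "r1", bc[1:10]), "exhausted")
})

test_that("REF/ALT designs center the variant and honor indel arithmetic", {
  genome <- Biostrings::DNAStringSet(c(chr1 = randomSeq(2000, seed = 3)))
  pos <- 1000L
  ref <- as.character(Biostrings::subseq(genome[["chr1"]], pos, pos))
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  dsg <- designRefAlt(
    list(chrom = "chr1", pos = pos, ref = ref, alt = alt), genome
  )
  expect_equal(nchar(dsg$insert), c(171L, 171L))
  expect_identical(
    dsg$insert[1],
    as.character(Biostrings::subseq(genome[["chr1"]], pos - 85, pos + 85))
  )
  diffAt <- which(strsplit(dsg$insert[1], "")[[1]] !=
    strsplit(dsg$insert[2], "")[[1]])
  expect_identical(diffAt, 86L)

  # 1 bp deletion: ALT insert is 170 bp with identical flanks
  ref2 <- as.character(Biostrings::subseq(genome[["chr1"]], pos, pos + 1))
  del <- designRefAlt(
    list(chrom = "chr1", pos = pos, ref = ref2, alt = substr(ref2, 1, 1)),
    genome
  )
  expect_equal(nchar(del$insert[2]), 170L)
  expect_identical(substr(del$insert[1], 1, 86), substr(del$insert[2], 1, 86))

  wrong <- setdiff(c("A", "C", "G", "T"), ref)[2]
  expect_error(
    designRefAlt(list(chrom = "chr1", pos = pos, ref = wrong, alt = alt),
      genome),
    "mismatch"
  )
})

test_that("barcode sets satisfy distance and homopolymer constraints", {
  bc <- assignBarcodes(1000, length = 15, minHamming = 3, seed = 2)
  expect_length(unique(bc), 1000)
  expect_true(all(nchar(bc) == 15))
  # brute-force pairwise Hamming distances via one-hot encoding
  onehot <- t(vapply(strsplit(bc, ""), function(ch) {
    as.numeric(outer(c("A", "C", "G", "T"), ch, "==") )
  }, numeric(60)))
  shared <- tcrossprod(onehot)
  dists <- 15 - shared[upper.tri(shared)]
  expect_gte(min(dists), 3)
  expect_true(all(vapply(strsplit(bc, ""), function(ch) {
    max(rle(ch)$lengths) <= 4
  }, logical(1))))
  expect_identical(bc, assignBarcodes(1000, length = 15, seed = 2))
  expect_error(assignBarcodes(4^15 + 1), "distinct")
})

test_that("variant prioritization applies the 20 kb TSS and enhancer rules", {
  genes <- data.frame(
    gene = c("g1", "g2", "g3"), chrom = "chr1",
    tss = c(100000L, 500000L, 300000L),
    prioritized = c(TRUE, FALSE, FALSE)
  )
  mkv <- function(pos, flag = FALSE) {
    data.frame(chrom = "chr1", pos = pos, priority_flag = flag)
  }
  enh <- GenomicRanges::GRanges("chr1", IRanges::IRanges(299000, 301000))

  near <- prioritizeVariants(mkv(100000L + 19999L), genes, enh)
  expect_equal(nrow(near), 1)
  far <- prioritizeVariants(mkv(100000L + 20001L), genes, enh)
  expect_equal(nrow(far), 0)

  # enhancer rule needs the closest gene to carry >= 3 cohort ncDNVs
  few <- prioritizeVariants(mkv(c(300100L, 300200L)), genes, enh)
  expect_equal(nrow(few), 0)
  many <- prioritizeVariants(mkv(c(300100L, 300200L, 300300L)), genes, enh)
  expect_equal(nrow(many), 3)

  # coding variants are dropped regardless of other qualifications
  exon <- GenomicRanges::GRanges("chr1", IRanges::IRanges(99000, 101000))
  coding <- prioritizeVariants(mkv(100500L), genes, enh, codingExons = exon)
  expect_equal(nrow(coding), 0)

  # TSS-distance tie resolves to the lower-coordinate gene deterministically
  genesTie <- data.frame(
    gene = c("a", "b"), chrom = "chr1", tss = c(1000L, 3000L),
    prioritized = c(FALSE, FALSE)
  )
  enh2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1900, 2100))
  v <- data.frame(chrom = "chr1", pos = c(2000L, 2000L, 2000L))
  got <- prioritizeVariants(v, genesTie, enh2)
  expect_equal(nrow(got), 3) # gene "a" (lower tss) accumulates all 3 ncDNVs
})
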