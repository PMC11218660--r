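test_that("MEME-like motif files parse into valid PWMs", {
  path <- system.file("extdata", "example_motifs.meme", package = "MPRAcard")
  pwms <- readMeme(path)
  expect_named(pwms, c("GATA_like", "TBOX_like"))
  expect_equal(motifLength(pwms$GATA_like), 6)
  expect_equal(motifConsensus(pwms$TBOX_like), "AGGTG")
  expect_equal(pwms$GATA_like@background, rep(0.25, 4))
  expect_true(validObject(pwms$GATA_like))
})

test_that("consensus hits of a strict PWM get the background-product p", {
  pwm <- strictConsensusPwm("ACGTA")
  hit <- scanPwm(paste0("TT", "ACGTA", "TT"), pwm)
  expect_true(hit$hit)
  expect_equal(hit$position, 3L)
  expect_identical(hit$p, 0.25^5) # bit-exact under uniform background
  expect_equal(motifScore(hit), -log10(0.25^5))
})

test_that("3-bp PWM p-values equal the exhaustive 64-trimer fractions", {
  pwm <- randomPwm(3, seed = 21)
  dist <- pwmScoreDistribution(pwm)
  oracle <- enumeratePwmTail(pwm)
  # every achievable integer score agrees bit-for-bit with the enumeration
  achievable <- which(dist$probs > 0) + dist$minScore - 1L
  for (s in achievable) {
    expect_identical(dist$pTail(s), oracle(s))
  }
})

test_that("DP p-values are exact for motifs up to 6 bp", {
  for (L in 4:6) {
    pwm <- randomPwm(L, seed = 30 + L)
    dist <- pwmScoreDistribution(pwm)
    oracle <- enumeratePwmTail(pwm)
    achievable <- which(dist$probs > 0) + dist$minScore - 1L
    probe <- achievable[round(seq(1, length(achievable), length.out = 25))]
    for (s in probe) expect_identical(dist$pTail(s), oracle(s))
  }
  # non-uniform background: agreement to floating-point accumulation error
  pwm <- randomPwm(5, seed = 44, background = c(0.3, 0.2, 0.2, 0.3))
  dist <- pwmScoreDistribution(pwm)
  oracle <- enumeratePwmTail(pwm)
  achievable <- which(dist$probs > 0) + dist$minScore - 1L
  for (s in achievable[seq(1, length(achievable), length.out = 10)]) {
    expect_equal(dist$pTail(s), oracle(s), tolerance = 1e-12)
  }
})

test_that("best scores are strand symmetric", {
  pwm <- randomPwm(6, seed = 8)
  for (i in 1:10) {
    s <- randomSeq(30, seed = 200 + i)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s))
    )
    a <- scanPwm(s, pwm)
    b <- scanPwm(rc, pwm)
    expect_identical(a$scoreInt, b$scoreInt)
  }
})

test_that("motif score semantics: -log10 p, absent hits score 0", {
  expect_equal(pToMotifScore(1e-3), 3)
  expect_equal(motifScoreToP(3), 1e-3)
  # a score delta of 2 is exactly a 100-fold p change
  expect_equal(motifScoreToP(1.7) / motifScoreToP(3.7), 100)
  short <- scanPwm("ACG", strictConsensusPwm("ACGTAA"))
  expect_false(short$hit)
  expect_equal(motifScore(short), 0)
})

test_that("variant-induced motif loss and gain are classified", {
  pwm <- plantedPwm()
  flankL <- randomSeq(40, seed = 31)
  flankR <- randomSeq(40, seed = 32)
  refSeq <- paste0(flankL, "ACGTAAAAAA", flankR) # motif at 41..50
  altSeq <- refSeq
  substr(altSeq, 43, 43) <- "T" # strict position 3 (G -> T)
  changes <- classifyMotifChanges(
    refSeqs = refSeq, altSeqs = altSeq, pwms = list(planted = pwm),
    centers = 43L, window = 8L, pairClasses = "MPRA-DA",
    pairIds = "pair1"
  )
  expect_equal(nrow(changes), 1)
  expect_identical(changes$call, "LoM")
  expect_identical(changes$category, "MPRA-DA_LoM")
  expect_lt(changes$delta, -2)
  # the planted-site p moves from ~1e-6 to ~1e-3 (enumeration-backed)
  expect_lt(motifScoreToP(changes$score_ref), 1e-5)
  expect_gt(motifScoreToP(changes$score_alt), 1e-4)
  # the reverse substitution is a gain
  gains <- classifyMotifChanges(
    refSeqs = altSeq, altSeqs = refSeq, pwms = list(planted = pwm),
    centers = 43L, window = 8L, pairClasses = "MPRA-IA"
  )
  expect_identical(gains$call, "GoM")

  # identical sequences: no deltas, nothing called
  same <- classifyMotifChanges(
    refSeqs = refSeq, altSeqs = refSeq, pwms = list(planted = pwm),
    centers = 43L, window = 8L, pairClasses = "MPRA-DA"
  )
  expect_true(all(same$delta == 0))
  expect_true(all(same$call == "none"))

  # sub-threshold deltas stay uncalled
  below <- classifyMotifChanges(
    refSeqs = refSeq, altSeqs = altSeq, pwms = list(planted = pwm),
    centers = 43L, window = 8L, pairClasses = "MPRA-DA",
    deltaThreshold = abs(changes$delta) + 0.1
  )
  expect_identical(below$call, "none")
})

test_that("signed motif odds ratios follow the formula and the sign rule", {
  mkChanges <- function(nEffChanged, nEff, nCtlChanged, nCtl,
                        effClass = "MPRA-IA", effCall = "GoM") {
    S4Vectors::DataFrame(
      pair_id = sprintf("p%03d", seq_len(nEff + nCtl)),
      motif_id = "m",
      class = c(rep(effClass, nEff), rep("MPRA-NS", nCtl)),
      call = c(
        rep(effCall, nEffChanged), rep("none", nEff - nEffChanged),
        rep(effCall, nCtlChanged), rep("none", nCtl - nCtlChanged)
      )
    )
  }
  # P_mc = 0.5, P_mn = 0.1, activator sign -> OR = 9
  or1 <- motifOddsRatio(mkChanges(10, 20, 2, 20), "m")
  expect_equal(or1$or_value, 9)
  expect_equal(or1$n_sign, 1)
  # equal proportions -> |OR| = 1
  or2 <- motifOddsRatio(mkChanges(5, 20, 5, 20), "m")
  expect_equal(abs(or2$or_value), 1)
  # repressor-consistent: gain in MPRA-DA -> negative OR
  or3 <- motifOddsRatio(
    mkChanges(10, 20, 2, 20, effClass = "MPRA-DA", effCall = "GoM"), "m"
  )
  expect_equal(or3$n_sign, -1)
  expect_lt(or3$or_value, 0)
  # zero cell triggers Haldane smoothing with a flag
  or4 <- motifOddsRatio(mkChanges(0, 20, 2, 20), "m")
  expect_true(or4$smoothed)
  expect_true(is.finite(or4$or_value))
})

test_that("a planted causal motif ranks highly among decoys", {
  set.seed(55)
  causal <- plantedPwm("causal")
  decoys <- lapply(1:30, function(i) {
    randomPwm(6, id = paste0("decoy", i), seed = 600 + i)
  })
  names(decoys) <- vapply(decoys, function(p) p@id, character(1))
  pwms <- c(list(causal = causal), decoys)
  nPairs <- 24
  refs <- alts <- character(nPairs)
  classes <- rep(c("MPRA-DA", "MPRA-NS"), each = nPairs / 2)
  for (i in seq_len(nPairs)) {
    fl <- randomSeq(40, seed = 700 + i)
    fr <- randomSeq(40, seed = 800 + i)
    refs[i] <- paste0(fl, "ACGTAAAAAA", fr)
    alts[i] <- refs[i]
    if (classes[i] == "MPRA-DA") substr(alts[i], 43, 43) <- "T"
  }
  changes <- classifyMotifChanges(refs, alts, pwms,
    centers = 43L, window = 8L, pairClasses = classes)
  ranking <- motifFrequencyRanking(changes)
  expect_lte(ranking$rank[ranking$motif_id == "causal"], 5)
  # never-perturbed motifs are excluded from the ranking
  expect_false(any(!ranking$motif_id %in% changes$motif_id))
  expect_true(all(ranking$freq_effect > 0))
})
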