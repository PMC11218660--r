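randomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# near-deterministic PWM whose consensus is the unique maximal-score word
strictConsensusPwm <- function(consensus, id = "strict",
                               background = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  idx <- match(strsplit(consensus, "")[[1]], bases)
  m <- matrix(0.01, nrow = 4, ncol = length(idx))
  m[cbind(idx, seq_along(idx))] <- 0.97
  PositionWeightMatrix(id, m, background = background)
}

randomPwm <- function(L, id = "rand", seed = 1,
                      background = rep(0.25, 4)) {
  set.seed(seed)
  m <- matrix(rgamma(4 * L, shape = 0.8), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  PositionWeightMatrix(id, m, background = background)
}

# independent oracle: exact PWM match p-values by exhaustive enumeration of
# all 4^L words, using the same discretization contract as the scanner
enumeratePwmTail <- function(pwm, pseudocount = 1e-3, granularity = 1e-3) {
  m <- sweep(pwm@matrix + pseudocount, 2,
    colSums(pwm@matrix + pseudocount), "/")
  S <- matrix(as.integer(round(log2(m / pwm@background) / granularity)),
    nrow = 4)
  L <- ncol(S)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- integer(nrow(words))
  probs <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    idx <- words[i, ]
    scores[i] <- sum(S[cbind(idx, seq_len(L))])
    probs[i] <- prod(pwm@background[idx])
  }
  function(scoreInt) sum(probs[scores >= scoreInt])
}

# independent oracle: enrichment score by direct double-loop evaluation
bruteForceEs <- function(ranked, subset) {
  N <- length(ranked)
  n <- length(subset)
  vapply(seq_len(N), function(i) {
    hits <- 0
    for (t in seq_len(i)) if (ranked[t] %in% subset) hits <- hits + 1
    hits / n - i / N
  }, numeric(1))
}

# MpraExperiment whose FPM values equal the supplied matrices: a filler
# design tops each library up to 1e6 total counts
seFromFpm <- function(dnaFpm, rnaFpm) {
  ids <- rownames(dnaFpm)
  if (is.null(ids)) {
    ids <- paste0("d", seq_len(nrow(dnaFpm)))
  }
  dna <- rbind(dnaFpm, filler = 1e6 - colSums(dnaFpm))
  rna <- rbind(rnaFpm, filler = 1e6 - colSums(rnaFpm))
  rownames(dna) <- rownames(rna) <- c(ids, "filler")
  MpraExperiment(dna, rna)
}

# 10-mer PWM with 5 strict positions (ACGTA) and 5 weakly A-favored ones:
# a mismatch at a strict position drops the exact match p by ~3 decades,
# because all 4^5 weak-position variants of the consensus outrank it
plantedPwm <- function(id = "planted") {
  strict <- vapply(c("A", "C", "G", "T", "A"), function(b) {
    v <- rep(0.01, 4)
    v[match(b, c("A", "C", "G", "T"))] <- 0.97
    v
  }, numeric(4))
  weak <- matrix(rep(c(0.28, 0.24, 0.24, 0.24), 5), nrow = 4)
  PositionWeightMatrix(id, cbind(strict, weak))
}
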