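#' Read motifs from a MEME-like matrix file
#'
#' Minimal reader for the MEME motif text format: `MOTIF` headers, optional
#' `Background letter frequencies` line, and `letter-probability matrix`
#' blocks with one row per motif position (columns A, C, G, T).
#'
#' @param path file path.
#' @return Named list of [PositionWeightMatrix-class] objects.
#' @export
readMeme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgLine <- grep("^Background letter frequencies", lines)
  if (length(bgLine)) {
    tok <- strsplit(trimws(lines[bgLine[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    bg <- vals[!is.na(vals)][1:4]
  }
  motifStarts <- grep("^MOTIF", lines)
  if (!length(motifStarts)) stop("no MOTIF entries found in ", path)
  out <- list()
  for (s in motifStarts) {
    nameTok <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    id <- nameTok[2]
    family <- if (length(nameTok) >= 3) nameTok[3] else id
    j <- s + 1L
    while (j <= length(lines) &&
           !grepl("letter-probability matrix", lines[j])) {
      j <- j + 1L
    }
    if (j > length(lines)) stop("motif ", id, " has no probability matrix")
    rows <- list()
    j <- j + 1L
    while (j <= length(lines)) {
      tok <- suppressWarnings(
        as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]])
      )
      if (length(tok) != 4L || any(is.na(tok))) break
      rows[[length(rows) + 1L]] <- tok
      j <- j + 1L
    }
    mat <- t(do.call(rbind, rows))
    out[[id]] <- PositionWeightMatrix(id, mat, background = bg,
      family = family)
  }
  out
}

# Integer-discretized per-position log-odds scores. A pseudocount is added to
# each probability cell (renormalized) before taking log2 odds against the
# background; scores are rounded to units of `granularity`, so the scanner
# and the exact null distribution share one discrete score space.
.pwmIntScores <- function(pwm, pseudocount = 1e-3, granularity = 1e-3) {
  m <- sweep(pwm@matrix + pseudocount, 2,
    colSums(pwm@matrix + pseudocount), "/")
  s <- log2(m / pwm@background)
  matrix(as.integer(round(s / granularity)), nrow = 4,
    dimnames = list(c("A", "C", "G", "T"), NULL))
}

#' Exact null distribution of a PWM score
#'
#' Dynamic programming over the discretized per-position score distribution:
#' positions are independent under the background model, so the total-score
#' distribution is the convolution of the four-point per-position
#' distributions. Returns the tail function used for match p-values; for
#' short motifs this is exactly the fraction of all length-L words at or
#' above a score.
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param pseudocount per-cell pseudocount before log-odds (default 1e-3).
#' @param granularity score discretization step in log2 units (default 1e-3).
#' @return List with `minScore`, `probs` (distribution over integer scores
#'   from `minScore`), and `pTail(scoreInt)`, the exact P(score >= scoreInt).
#' @export
pwmScoreDistribution <- function(pwm, pseudocount = 1e-3,
                                 granularity = 1e-3) {
  S <- .pwmIntScores(pwm, pseudocount, granularity)
  L <- ncol(S)
  bg <- pwm@background
  lo <- sum(apply(S, 2, min))
  hi <- sum(apply(S, 2, max))
  probs <- numeric(hi - lo + 1L) # index 1 <-> score lo
  # initialise with position 1
  cur <- numeric(max(S[, 1]) - min(S[, 1]) + 1L)
  curLo <- min(S[, 1])
  for (b in 1:4) {
    idx <- S[b, 1] - curLo + 1L
    cur[idx] <- cur[idx] + bg[b]
  }
  for (j in seq_len(L)[-1]) {
    sj <- S[, j]
    newLo <- curLo + min(sj)
    new <- numeric(length(cur) + max(sj) - min(sj))
    nz <- which(cur > 0)
    for (b in 1:4) {
      shift <- sj[b] - min(sj)
      new[nz + shift] <- new[nz + shift] + cur[nz] * bg[b]
    }
    cur <- new
    curLo <- newLo
  }
  probs[seq_along(cur) + (curLo - lo)] <- cur
  tail <- rev(cumsum(rev(probs)))
  list(
    minScore = lo,
    probs = probs,
    pTail = function(scoreInt) {
      i <- scoreInt - lo + 1L
      if (i <= 1L) return(1)
      if (i > length(tail)) return(0)
      tail[i]
    }
  )
}

.seqToCodes <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
  match(chars, c("A", "C", "G", "T"))
}

#' Scan a sequence with a PWM and report the best hit with an exact p-value
#'
#' Scores every offset on both strands whose match overlaps the given window
#' (log2 odds against the background, pseudocount 1e-3 per cell) and returns
#' the best hit; the p-value is the exact tail probability of that score
#' under the background model from [pwmScoreDistribution()].
#'
#' @param sequence character or `DNAString`.
#' @param pwm a [PositionWeightMatrix-class].
#' @param window optional length-2 integer, 1-based positions in `sequence`;
#'   only matches overlapping `[window[1], window[2]]` are considered
#'   (default: the whole sequence).
#' @param dist optional precomputed [pwmScoreDistribution()] result.
#' @param pseudocount,granularity scoring parameters, see
#'   [pwmScoreDistribution()].
#' @return List with hit (logical), position, strand, score (log2 units),
#'   scoreInt and p. `hit = FALSE` when the sequence is shorter than the
#'   motif or no offset overlaps the window.
#' @export
scanPwm <- function(sequence, pwm, window = NULL, dist = NULL,
                    pseudocount = 1e-3, granularity = 1e-3) {
  codes <- .seqToCodes(sequence)
  L <- motifLength(pwm)
  n <- length(codes)
  if (n < L) {
    return(list(hit = FALSE, position = NA_integer_, strand = NA_character_,
      score = NA_real_, scoreInt = NA_integer_, p = NA_real_))
  }
  if (is.null(window)) window <- c(1L, n)
  S <- .pwmIntScores(pwm, pseudocount, granularity)
  Srev <- S[4:1, L:1, drop = FALSE] # reverse-complement strand scores
  offsets <- seq_len(n - L + 1L)
  offsets <- offsets[offsets <= window[2] & offsets + L - 1L >= window[1]]
  if (!length(offsets)) {
    return(list(hit = FALSE, position = NA_integer_, strand = NA_character_,
      score = NA_real_, scoreInt = NA_integer_, p = NA_real_))
  }
  scoreAt <- function(M) {
    vapply(offsets, function(o) {
      idx <- codes[o:(o + L - 1L)]
      if (anyNA(idx)) return(NA_integer_)
      sum(M[cbind(idx, seq_len(L))])
    }, integer(1))
  }
  fwd <- scoreAt(S)
  rev_ <- scoreAt(Srev)
  scores <- c(fwd, rev_)
  if (all(is.na(scores))) {
    return(list(hit = FALSE, position = NA_integer_, strand = NA_character_,
      score = NA_real_, scoreInt = NA_integer_, p = NA_real_))
  }
  best <- which.max(scores)
  strand <- if (best <= length(offsets)) "+" else "-"
  pos <- offsets[(best - 1L) %% length(offsets) + 1L]
  scoreInt <- scores[best]
  if (is.null(dist)) {
    dist <- pwmScoreDistribution(pwm, pseudocount, granularity)
  }
  list(
    hit = TRUE, position = pos, strand = strand,
    score = scoreInt * granularity, scoreInt = scoreInt,
    p = dist$pTail(scoreInt)
  )
}

#' Motif score of a best hit
#'
#' The motif score is the negative log10 of the best hit's exact p-value, so
#' a score difference of 2 between two oligos corresponds to a 100-fold
#' change in motif match p-value. A missing hit scores 0.
#'
#' @param hit result of [scanPwm()].
#' @return Numeric score in -log10(p) units.
#' @export
motifScore <- function(hit) {
  if (!isTRUE(hit$hit) || is.na(hit$p)) return(0)
  -log10(hit$p)
}

#' Convert between motif scores and p-values
#'
#' `motifScoreToP()` inverts the -log10 transform; `pToMotifScore()` applies
#' it.
#' @param score motif score, -log10(p) units.
#' @param p p-value.
#' @return The converted value.
#' @export
motifScoreToP <- function(score) 10^(-score)

#' @rdname motifScoreToP
#' @export
pToMotifScore <- function(p) -log10(p)

#' Classify variant-induced motif changes
#'
#' For each REF/ALT (or WT/mutant) pair and each motif, scores both
#' sequences within a window centered on the variant (±8 bp for variant
#' libraries, ±10 bp for deletion libraries), keeps motifs with p < `pKeep`
#' in at least one member, and calls loss-of-motif (delta <= -`deltaThreshold`)
#' or gain-of-motif (delta >= `deltaThreshold`) on the score difference
#' `alt - ref`.
#'
#' @param refSeqs,altSeqs character vectors of pair member sequences.
#' @param pwms list of [PositionWeightMatrix-class] objects.
#' @param centers 1-based variant positions within the sequences (recycled;
#'   default: sequence centers).
#' @param window half-width of the scan window around the center (default 8).
#' @param pairClasses activity classes of the pairs (MPRA-DA / MPRA-IA /
#'   MPRA-NS), used for the category label.
#' @param pairIds pair identifiers.
#' @param deltaThreshold absolute score difference calling a change
#'   (default 2, i.e. a 100-fold p change).
#' @param pKeep keep motifs with best-hit p below this in >= 1 member
#'   (default 1e-3).
#' @return `DataFrame` with pair_id, motif_id, score_ref, score_alt, delta,
#'   call (LoM/GoM/none) and category.
#' @export
classifyMotifChanges <- function(refSeqs, altSeqs, pwms,
                                 centers = NULL, window = 8L,
                                 pairClasses = NULL,
                                 pairIds = NULL,
                                 deltaThreshold = 2, pKeep = 1e-3) {
  n <- length(refSeqs)
  stopifnot(length(altSeqs) == n)
  if (is.null(pairIds)) pairIds <- sprintf("pair_%04d", seq_len(n))
  if (is.null(pairClasses)) pairClasses <- rep("MPRA-NS", n)
  if (is.null(centers)) {
    centers <- (nchar(refSeqs) + 1L) %/% 2L
  }
  centers <- rep_len(centers, n)
  dists <- lapply(pwms, pwmScoreDistribution)
  rows <- list()
  for (m in seq_along(pwms)) {
    pwm <- pwms[[m]]
    for (i in seq_len(n)) {
      winRef <- c(centers[i] - window, centers[i] + window)
      hitR <- scanPwm(refSeqs[i], pwm, window = winRef, dist = dists[[m]])
      # the alt window tracks the same genomic center; indels shift length,
      # recentre on the alt sequence midpoint shift
      shift <- (nchar(altSeqs[i]) - nchar(refSeqs[i]))
      winAlt <- c(centers[i] - window, centers[i] + window + shift)
      hitA <- scanPwm(altSeqs[i], pwm, window = winAlt, dist = dists[[m]])
      pMin <- suppressWarnings(min(c(hitR$p, hitA$p), na.rm = TRUE))
      if (!is.finite(pMin) || pMin >= pKeep) next
      sR <- motifScore(hitR)
      sA <- motifScore(hitA)
      delta <- sA - sR
      call <- if (delta <= -deltaThreshold) {
        "LoM"
      } else if (delta >= deltaThreshold) {
        "GoM"
      } else {
        "none"
      }
      category <- if (call == "none" || pairClasses[i] == "MPRA-NS") {
        "control"
      } else {
        paste0(pairClasses[i], "_", call)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pairIds[i], motif_id = pwm@id,
        class = pairClasses[i],
        score_ref = sR, score_alt = sA, delta = delta,
        call = call, category = category, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(DataFrame(
      pair_id = character(), motif_id = character(), class = character(),
      score_ref = numeric(), score_alt = numeric(), delta = numeric(),
      call = character(), category = character()
    ))
  }
  DataFrame(do.call(rbind, rows))
}

#' Signed motif odds ratio between activity-changed and control pairs
#'
#' For one motif, cross-tabulates motif change (|delta| >= threshold) against
#' enhancer-activity change (MPRA-DA or MPRA-IA vs MPRA-NS) and reports
#' `OR = n * [P_mc (1 - P_mn)] / [P_mn (1 - P_mc)]`, where `P_mc` and `P_mn`
#' are the proportions of activity-changed and control pairs with a motif
#' change, and the sign n is +1 when the motif behaves as an activator
#' (gained in MPRA-IA or lost in MPRA-DA) and -1 when it behaves as a
#' repressor. Zero cells are Haldane-corrected (0.5) with a flag.
#'
#' @param changes `DataFrame` from [classifyMotifChanges()].
#' @param motifId motif to tabulate.
#' @return One-row `DataFrame`: motif_id, p_mc, p_mn, n_sign, or_value,
#'   smoothed.
#' @export
motifOddsRatio <- function(changes, motifId) {
  rows <- changes[changes$motif_id == motifId, , drop = FALSE]
  eff <- rows[rows$class %in% c("MPRA-DA", "MPRA-IA"), , drop = FALSE]
  ctl <- rows[rows$class == "MPRA-NS", , drop = FALSE]
  if (!nrow(eff) || !nrow(ctl)) {
    stop("motif ", motifId, " needs pairs in both activity margins")
  }
  changedEff <- sum(eff$call != "none")
  changedCtl <- sum(ctl$call != "none")
  smoothed <- changedEff == 0 || changedEff == nrow(eff) ||
    changedCtl == 0 || changedCtl == nrow(ctl)
  h <- if (smoothed) 0.5 else 0
  pMc <- (changedEff + h) / (nrow(eff) + 2 * h)
  pMn <- (changedCtl + h) / (nrow(ctl) + 2 * h)
  activator <- sum(eff$class == "MPRA-IA" & eff$call == "GoM") +
    sum(eff$class == "MPRA-DA" & eff$call == "LoM")
  repressor <- sum(eff$class == "MPRA-IA" & eff$call == "LoM") +
    sum(eff$class == "MPRA-DA" & eff$call == "GoM")
  nSign <- if (repressor > activator) -1 else 1
  DataFrame(
    motif_id = motifId, p_mc = pMc, p_mn = pMn, n_sign = nSign,
    or_value = nSign * (pMc * (1 - pMn)) / (pMn * (1 - pMc)),
    smoothed = smoothed
  )
}

#' Rank motifs by perturbation frequency in effect vs neutral pairs
#'
#' For every motif with at least one called change among MPRA-DA/MPRA-IA
#' pairs, reports the frequency of motif changes among effect pairs and
#' among MPRA-NS pairs, their ratio, and the descending rank of that
#' frequency.
#'
#' @param changes `DataFrame` from [classifyMotifChanges()].
#' @return `DataFrame` ranked by effect-class perturbation frequency.
#' @export
motifFrequencyRanking <- function(changes) {
  motifs <- unique(changes$motif_id)
  rows <- lapply(motifs, function(m) {
    sub <- changes[changes$motif_id == m, , drop = FALSE]
    eff <- sub[sub$class %in% c("MPRA-DA", "MPRA-IA"), , drop = FALSE]
    ns <- sub[sub$class == "MPRA-NS", , drop = FALSE]
    nEffChanged <- sum(eff$call != "none")
    if (nEffChanged == 0) return(NULL)
    fEff <- nEffChanged / max(1L, nrow(eff))
    fNs <- sum(ns$call != "none") / max(1L, nrow(ns))
    data.frame(
      motif_id = m, freq_effect = fEff, freq_ns = fNs,
      ratio = if (fNs > 0) fEff / fNs else Inf,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(DataFrame(
      motif_id = character(), freq_effect = numeric(),
      freq_ns = numeric(), ratio = numeric(), rank = integer()
    ))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$freq_effect), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  DataFrame(out)
}
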