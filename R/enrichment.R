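#' Running enrichment score of a region set within a ranked library
#'
#' For a library of N designs ranked by activity and a subset R of n members,
#' the enrichment score at position i is the cumulative fraction of R
#' encountered minus the cumulative fraction of the library:
#' `ES_i = (1/n) * sum_{t <= i} 1[r_t in R] - i/N`. ES is zero at position N
#' by construction; positive values indicate the set concentrates toward the
#' top of the ranking.
#'
#' @param ranked character vector of design ids, ranked by activity
#'   (descending); ranks must be unique.
#' @param subset character vector of member ids; must be a subset of
#'   `ranked`.
#' @return List with `es` (length-N curve) and `meanEs`.
#' @examples
#' enrichmentCurve(letters[1:4], c("a", "d"))$es
#' @export
enrichmentCurve <- function(ranked, subset) {
  if (length(subset) == 0L) stop("subset must contain at least one member")
  if (anyDuplicated(ranked)) stop("ranked list must have unique ids")
  if (!all(subset %in% ranked)) stop("subset must be contained in the ranking")
  N <- length(ranked)
  n <- length(subset)
  member <- ranked %in% subset
  es <- cumsum(member) / n - seq_len(N) / N
  list(es = es, meanEs = mean(es))
}

#' Permutation p-value for an enrichment score
#'
#' The statistic is the mean of the enrichment-score curve. `B` random
#' same-size subsets are drawn; the one-sided p-value is the proportion of
#' random sets whose mean ES is greater than or equal to the observed value
#' when the observed mean ES is positive, or less than or equal when
#' negative. The Bonferroni-corrected p multiplies by the number of subsets
#' tested in the batch.
#'
#' @inheritParams enrichmentCurve
#' @param B number of permutations (default 2000).
#' @param seed integer seed.
#' @param nTests Bonferroni multiplier (number of sets tested together).
#' @return List with meanEs, p, pBonferroni, B.
#' @examples
#' set.seed(1)
#' lib <- sprintf("d%03d", 1:100)
#' enrichmentPvalue(lib, lib[1:5], B = 200, seed = 7)$p
#' @export
enrichmentPvalue <- function(ranked, subset, B = 2000L, seed = 1L,
                             nTests = 1L) {
  obs <- enrichmentCurve(ranked, subset)$meanEs
  N <- length(ranked)
  n <- length(subset)
  set.seed(seed)
  frac <- seq_len(N) / N
  perm <- vapply(seq_len(B), function(b) {
    idx <- sample.int(N, n)
    member <- logical(N)
    member[idx] <- TRUE
    mean(cumsum(member) / n - frac)
  }, numeric(1))
  p <- if (obs > 0) {
    mean(perm >= obs)
  } else if (obs < 0) {
    mean(perm <= obs)
  } else {
    1
  }
  list(meanEs = obs, p = p, pBonferroni = min(1, p * nTests), B = B)
}
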