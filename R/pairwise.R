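#' Paired t-test of REF vs ALT activity
#'
#' The per-replicate activity differences (ALT minus REF, log2 units) are
#' tested with a paired two-sided t statistic on k - 1 degrees of freedom,
#' where k is the number of replicate pairs with both members covered. The
#' log2 fold change is the mean difference. Fewer than 3 complete pairs
#' yields p = 1 and an `undertested` flag; zero-variance differences degrade
#' to p = 0 (nonzero mean) or p = 1 (all-zero) without numeric failure.
#'
#' @param refActivity,altActivity per-replicate activity vectors (log2
#'   units); NAs mark uncovered replicates.
#' @return List with log2fc, t, df, p, undertested.
#' @examples
#' pairTest(c(1, 1.2, 0.8, 1), c(0.2, 0.3, 0.1, 0.2))
#' @export
pairTest <- function(refActivity, altActivity) {
  d <- altActivity - refActivity
  d <- d[is.finite(d)]
  k <- length(d)
  if (k < 3L) {
    return(list(
      log2fc = if (k) mean(d) else NA_real_, t = NA_real_,
      df = k - 1L, p = 1, undertested = TRUE
    ))
  }
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(
      log2fc = m, t = if (m == 0) 0 else sign(m) * Inf, df = k - 1L,
      p = if (m == 0) 1 else 0, undertested = FALSE
    ))
  }
  tStat <- m / (s / sqrt(k))
  list(
    log2fc = m, t = tStat, df = k - 1L,
    p = 2 * stats::pt(-abs(tStat), df = k - 1L), undertested = FALSE
  )
}

#' Classify REF/ALT pairs by differential activity
#'
#' Runs [pairTest()] on every pair, Benjamini-Hochberg adjusts p across all
#' pairs jointly, and classifies: MPRA-DA (`log2fc <= -lfcThreshold`) or
#' MPRA-IA (`log2fc >= lfcThreshold`) when `padj < padjThreshold` and the
#' pair has detectable activity; otherwise MPRA-NS. Detectable activity means
#' at least one member is an active call (default), or nonzero RNA in at
#' least one replicate (`activityRule = "nonzero-rna"`).
#'
#' @param refMatrix,altMatrix pair x replicate activity matrices with
#'   identical row order (one row per pair).
#' @param activeCalls optional `DataFrame` from [testActive()]; looked up by
#'   `refIds`/`altIds`.
#' @param refIds,altIds design ids of each pair's members.
#' @param rnaCounts optional pair x replicate ALT/REF RNA evidence for the
#'   alternative rule (matrix of max RNA counts per pair).
#' @param lfcThreshold absolute log2 fold-change gate (default 0.58).
#' @param padjThreshold BH-adjusted p gate (default 0.05).
#' @param activityRule "active-call" or "nonzero-rna".
#' @return `DataFrame` with pair_id, log2fc, t, p, padj, nActiveMembers and
#'   class; plus a `summary` attribute of per-class counts.
#' @export
classifyPairs <- function(refMatrix, altMatrix, activeCalls = NULL,
                          refIds = rownames(refMatrix),
                          altIds = rownames(altMatrix),
                          rnaCounts = NULL,
                          lfcThreshold = 0.58, padjThreshold = 0.05,
                          activityRule = c("active-call", "nonzero-rna")) {
  activityRule <- match.arg(activityRule)
  stopifnot(nrow(refMatrix) == nrow(altMatrix))
  n <- nrow(refMatrix)
  res <- lapply(seq_len(n), function(i) {
    pairTest(refMatrix[i, ], altMatrix[i, ])
  })
  log2fc <- vapply(res, `[[`, numeric(1), "log2fc")
  tStat <- vapply(res, `[[`, numeric(1), "t")
  p <- vapply(res, `[[`, numeric(1), "p")
  undertested <- vapply(res, `[[`, logical(1), "undertested")
  padj <- stats::p.adjust(p, "BH")

  if (activityRule == "active-call") {
    if (is.null(activeCalls)) {
      nActive <- rep(NA_integer_, n)
      detectable <- rep(FALSE, n)
    } else {
      isActive <- setNames(activeCalls$active, activeCalls$design_id)
      nActive <- ifelse(is.na(isActive[refIds]), 0L, isActive[refIds]) +
        ifelse(is.na(isActive[altIds]), 0L, isActive[altIds])
      detectable <- nActive >= 1L
    }
  } else {
    if (is.null(rnaCounts)) stop("rnaCounts required for the nonzero-rna rule")
    nActive <- NA_integer_
    detectable <- apply(rnaCounts > 0, 1, any)
  }

  cls <- rep("MPRA-NS", n)
  sig <- !undertested & padj < padjThreshold &
    abs(log2fc) >= lfcThreshold & detectable
  cls[sig & log2fc <= -lfcThreshold] <- "MPRA-DA"
  cls[sig & log2fc >= lfcThreshold] <- "MPRA-IA"

  pairId <- if (!is.null(refIds)) {
    paste(refIds, altIds, sep = "|")
  } else {
    sprintf("pair_%04d", seq_len(n))
  }
  out <- DataFrame(
    pair_id = pairId, ref_id = refIds, alt_id = altIds,
    log2fc = log2fc, t = tStat, p = p, padj = padj,
    nActiveMembers = as.integer(nActive), undertested = undertested,
    class = cls
  )
  metadata(out)$summary <- table(factor(
    cls,
    levels = c("MPRA-DA", "MPRA-IA", "MPRA-NS")
  ))
  out
}

#' Summarize a classified tiling-mutagenesis library per fragment
#'
#' Fragments whose wild-type member did not pass the coverage filter are
#' dropped entirely; for the rest, the WT mean activity and the number of
#' deletion tiles classified MPRA-DA / MPRA-IA are reported.
#'
#' @param classed `DataFrame` from [classifyPairs()] on WT/deletion pairs,
#'   with a `fragment_id` column identifying each WT fragment.
#' @param wtCovered named logical; coverage-filter status of each WT design
#'   (names are fragment ids).
#' @param wtActivity named numeric; WT mean activity per fragment id.
#' @return `DataFrame`, one row per retained fragment: fragment_id,
#'   wt_activity, n_deletions, n_da, n_ia.
#' @export
tilingSummary <- function(classed, wtCovered, wtActivity) {
  frag <- classed$fragment_id
  if (is.null(frag)) stop("classed table must carry a 'fragment_id' column")
  keepFrag <- names(wtCovered)[wtCovered]
  classed <- classed[frag %in% keepFrag, , drop = FALSE]
  frag <- classed$fragment_id
  ids <- unique(frag)
  DataFrame(
    fragment_id = ids,
    wt_activity = unname(wtActivity[ids]),
    n_deletions = as.integer(table(frag)[ids]),
    n_da = vapply(ids, function(f) {
      sum(classed$class[frag == f] == "MPRA-DA")
    }, integer(1)),
    n_ia = vapply(ids, function(f) {
      sum(classed$class[frag == f] == "MPRA-IA")
    }, integer(1))
  )
}
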