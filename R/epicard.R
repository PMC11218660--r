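#' @importFrom glmnet cv.glmnet glmnet
NULL

#' Build annotation-overlap features for genomic windows
#'
#' For each window and each annotation track: the total overlap length in bp;
#' and, for tracks carrying a `score` value column, the length-weighted mean
#' value over the overlapped bases and the total value
#' (sum of value x overlap bp). Windows without overlap get 0 (mean 0 by
#' convention).
#'
#' @param windows `GRanges` of query windows.
#' @param tracks named list of `GRanges` annotation tracks; a numeric `score`
#'   metadata column marks a quantitative track.
#' @return Numeric matrix, windows x features, with feature columns
#'   `<track>_overlap` and additionally `<track>_mean`, `<track>_total` for
#'   quantitative tracks.
#' @examples
#' w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300))
#' tr <- list(t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(251, 400),
#'   score = 4
#' ))
#' buildFeatures(w, tr)
#' @export
buildFeatures <- function(windows, tracks) {
  if (is.null(names(tracks))) {
    names(tracks) <- sprintf("track_%03d", seq_along(tracks))
  }
  nW <- length(windows)
  cols <- list()
  for (tn in names(tracks)) {
    tr <- tracks[[tn]]
    if (length(tr) && any(width(tr) < 0)) {
      stop("malformed interval in track ", tn)
    }
    ov <- numeric(nW)
    hasVal <- length(tr) > 0 && "score" %in% names(mcols(tr))
    vTot <- numeric(nW)
    if (length(tr)) {
      hits <- findOverlaps(windows, tr)
      if (length(hits)) {
        pi <- pintersect(
          windows[S4Vectors::queryHits(hits)],
          tr[S4Vectors::subjectHits(hits)]
        )
        w <- width(pi)
        ov <- as.numeric(tapply(
          w, factor(S4Vectors::queryHits(hits), levels = seq_len(nW)),
          sum, default = 0
        ))
        if (hasVal) {
          val <- mcols(tr)$score[S4Vectors::subjectHits(hits)]
          vTot <- as.numeric(tapply(
            w * val, factor(S4Vectors::queryHits(hits), levels = seq_len(nW)),
            sum, default = 0
          ))
        }
      }
    }
    cols[[paste0(tn, "_overlap")]] <- ov
    if (hasVal) {
      cols[[paste0(tn, "_mean")]] <- ifelse(ov > 0, vTot / ov, 0)
      cols[[paste0(tn, "_total")]] <- vTot
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- names(windows)
  out
}

#' Train an EpiCard LASSO model on annotation features
#'
#' Fits a cross-validated LASSO path (`glmnet`, alpha = 1, features
#' standardized internally, coefficients reported on the original scale) and
#' extracts the model at the cross-validated penalty divided by ten, a
#' deliberately conservative choice against overfitting. The continuous
#' family regresses log activity; the binary family is L1-penalized logistic
#' regression on active/inactive labels.
#'
#' @param features windows x features numeric matrix from [buildFeatures()].
#' @param response numeric log-activity (continuous) or 0/1 labels (binary).
#' @param family "continuous" or "binary".
#' @param folds number of cross-validation folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return An [EpiCardModel-class].
#' @export
trainEpiCard <- function(features, response,
                         family = c("continuous", "binary"),
                         folds = 5L, seed = 1L) {
  family <- match.arg(family)
  if (nrow(features) < 2L * folds) {
    stop("need at least ", 2L * folds, " samples for ", folds, "-fold CV")
  }
  featNames <- colnames(features)
  if (stats::var(response) == 0) {
    warning("constant response; returning an intercept-only model")
    int <- if (family == "continuous") {
      mean(response)
    } else {
      stats::qlogis(min(max(mean(response), 1e-6), 1 - 1e-6))
    }
    return(new("EpiCardModel",
      family = family,
      coefficients = setNames(numeric(ncol(features)), featNames),
      intercept = int, lambda = Inf,
      metadata = list(folds = folds, seed = seed, lambdaCV = Inf)
    ))
  }
  glmFamily <- if (family == "continuous") "gaussian" else "binomial"
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = nrow(features)))
  cv <- cv.glmnet(features, response,
    family = glmFamily, alpha = 1,
    foldid = foldid, standardize = TRUE
  )
  lam <- cv$lambda.min / 10
  co <- as.matrix(stats::coef(cv$glmnet.fit, s = lam, exact = FALSE))
  new("EpiCardModel",
    family = family,
    coefficients = setNames(co[-1, 1], featNames),
    intercept = co[1, 1], lambda = lam,
    metadata = list(folds = folds, seed = seed, lambdaCV = cv$lambda.min)
  )
}

#' Predict with an EpiCard model
#'
#' Linear predictor `intercept + features %*% coefficients`; for the binary
#' family this is the log-odds of being an active enhancer, the scale on
#' which EpiCard scores are reported.
#'
#' @param model an [EpiCardModel-class].
#' @param features windows x features matrix with the training columns.
#' @return Numeric score per window.
#' @export
predictEpiCard <- function(model, features) {
  feat <- features[, names(model@coefficients), drop = FALSE]
  drop(model@intercept + feat %*% model@coefficients)
}

#' Score variants with a binary EpiCard model
#'
#' Builds annotation features on the 200 bp (by default) window centered on
#' each variant and returns the linear-predictor EpiCard score. Variants too
#' close to a chromosome end for a full window are skipped with a message.
#'
#' @param model a binary-family [EpiCardModel-class].
#' @param variants data.frame with chrom and pos (1-based).
#' @param tracks named list of annotation `GRanges` (same set used for
#'   training).
#' @param chromLengths named numeric chromosome sizes.
#' @param windowSize scored window size in bp (default 200).
#' @return Numeric vector of scores (NA for skipped variants).
#' @export
epicardScore <- function(model, variants, tracks, chromLengths,
                         windowSize = 200L) {
  if (model@family != "binary") {
    stop("variant scoring uses the binary-family model")
  }
  half <- windowSize %/% 2L
  startPos <- variants$pos - half
  endPos <- startPos + windowSize - 1L
  ok <- startPos >= 1L &
    endPos <= chromLengths[as.character(variants$chrom)]
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    message(sum(!ok), " variant(s) without a full ", windowSize,
      " bp window were skipped")
  }
  scores <- rep(NA_real_, nrow(variants))
  if (any(ok)) {
    w <- GRanges(
      variants$chrom[ok],
      IRanges(start = startPos[ok], end = endPos[ok])
    )
    feats <- buildFeatures(w, tracks)
    scores[ok] <- predictEpiCard(model, feats)
  }
  scores
}

#' Sample odds ratio of a 2x2 table
#'
#' `(a/b) / (c/d)` for counts above/below a cutoff in two cohorts.
#'
#' @param aboveCase,nCase count above cutoff and total in the case cohort.
#' @param aboveControl,nControl likewise for the control cohort.
#' @return The sample odds ratio.
#' @examples
#' oddsRatio2x2(380, 6211, 509, 10224)
#' @export
oddsRatio2x2 <- function(aboveCase, nCase, aboveControl, nControl) {
  (aboveCase * (nControl - aboveControl)) /
    ((nCase - aboveCase) * aboveControl)
}

#' Cohort burden tests on EpiCard scores
#'
#' Compares case and control ncDNV score distributions by a two-sided t-test
#' on the means; sets the cutoff at the 95th percentile (linear
#' interpolation) of the control scores; tabulates above/below-cutoff counts
#' into a 2x2 table reported as a sample odds ratio with Fisher's exact p;
#' and repeats the tabulation on the highest-scoring variant per participant.
#'
#' @param caseScores,controlScores numeric score vectors.
#' @param caseParticipants,controlParticipants participant ids aligned with
#'   the scores (for the per-participant maxima stage).
#' @param percentile control-cohort quantile defining the cutoff
#'   (default 0.95).
#' @return List with means, tP, cutoff, counts, orValue, fisherP, and a
#'   `perParticipant` sub-list with the same fields on per-participant
#'   maxima.
#' @export
burdenTests <- function(caseScores, controlScores,
                        caseParticipants = NULL, controlParticipants = NULL,
                        percentile = 0.95) {
  okCase <- is.finite(caseScores)
  okCtl <- is.finite(controlScores)
  caseScores <- caseScores[okCase]
  controlScores <- controlScores[okCtl]
  if (!is.null(caseParticipants)) caseParticipants <- caseParticipants[okCase]
  if (!is.null(controlParticipants)) {
    controlParticipants <- controlParticipants[okCtl]
  }
  if (length(caseScores) < 2L || length(controlScores) < 2L) {
    stop("each cohort needs at least 2 finite scores")
  }
  tt <- stats::t.test(caseScores, controlScores)
  cutoff <- unname(stats::quantile(controlScores, percentile, type = 7))
  tab <- function(cs, ns) {
    a <- sum(cs > cutoff)
    c_ <- sum(ns > cutoff)
    m <- matrix(c(a, length(cs) - a, c_, length(ns) - c_), 2,
      dimnames = list(c("above", "below"), c("case", "control"))
    )
    list(
      counts = m,
      orValue = oddsRatio2x2(a, length(cs), c_, length(ns)),
      fisherP = stats::fisher.test(m)$p.value
    )
  }
  allTab <- tab(caseScores, controlScores)
  perPart <- NULL
  if (!is.null(caseParticipants) && !is.null(controlParticipants)) {
    maxCase <- tapply(caseScores, caseParticipants, max)
    maxCtl <- tapply(controlScores, controlParticipants, max)
    perPart <- tab(as.numeric(maxCase), as.numeric(maxCtl))
  }
  list(
    meanCase = mean(caseScores), meanControl = mean(controlScores),
    tP = tt$p.value, cutoff = cutoff,
    counts = allTab$counts, orValue = allTab$orValue,
    fisherP = allTab$fisherP,
    perParticipant = perPart
  )
}

#' Univariate Pearson correlations of features with activity
#'
#' Pearson r and two-sided p for every feature column against the activity
#' vector; zero-variance columns are returned as NA with a flag.
#'
#' @param features windows x features numeric matrix (or a single-score
#'   column).
#' @param activity numeric activity vector.
#' @return `DataFrame` with feature, r, p, degenerate.
#' @export
univariateCorrelations <- function(features, activity) {
  features <- as.matrix(features)
  if (nrow(features) < 3L) stop("need at least 3 paired observations")
  res <- lapply(seq_len(ncol(features)), function(j) {
    v <- features[, j]
    if (stats::sd(v) == 0 || stats::sd(activity) == 0) {
      return(data.frame(r = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    ct <- stats::cor.test(v, activity)
    data.frame(
      r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE
    )
  })
  out <- do.call(rbind, res)
  DataFrame(
    feature = colnames(features) %||% as.character(seq_len(ncol(features))),
    out
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
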