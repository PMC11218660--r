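#' Median-of-ratios library size factors
#'
#' For each library (column), the size factor is the median over designs of
#' the ratio of that library's count to the design's geometric mean across
#' libraries, computed over designs with nonzero counts everywhere. If no
#' design is nonzero in every library, falls back to total-count scaling with
#' a warning.
#'
#' @param counts design x library count matrix.
#' @return Positive numeric vector of per-library factors.
#' @examples
#' m <- cbind(a = c(10, 20), b = c(20, 40))
#' mpraSizeFactors(m)
#' @export
mpraSizeFactors <- function(counts) {
  allPos <- rowSums(counts == 0) == 0
  if (!any(allPos)) {
    warning(
      "no design has nonzero counts in all libraries; ",
      "falling back to total-count scaling"
    )
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  m <- counts[allPos, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  apply(m / geo, 2, stats::median)
}

#' Pooled method-of-moments NB dispersion
#'
#' Per-design dispersion alpha for the variance model mu + alpha * mu^2,
#' estimated on size-factor-normalized counts after removing each condition's
#' mean (so the material effect does not inflate the variance), floored at
#' `alphaFloor`.
#'
#' @param counts design x library count matrix.
#' @param sizeFactors per-library size factors.
#' @param condition factor of length ncol(counts) (e.g. DNA/RNA).
#' @param alphaFloor minimum dispersion (default 0.01).
#' @return Named numeric vector of per-design alphas.
#' @export
estimateDispersionMoM <- function(counts, sizeFactors, condition,
                                  alphaFloor = 0.01) {
  norm <- sweep(counts, 2, sizeFactors, "/")
  condition <- as.factor(condition)
  vapply(seq_len(nrow(counts)), function(i) {
    y <- norm[i, ]
    mu <- mean(y)
    if (mu <= 0) return(alphaFloor)
    resid <- unlist(lapply(levels(condition), function(l) {
      v <- y[condition == l]
      v - mean(v)
    }))
    # pooled within-condition variance; df accounts for the removed means
    s2 <- sum(resid^2) / (length(y) - nlevels(condition))
    max((s2 - mu) / mu^2, alphaFloor)
  }, numeric(1)) |> setNames(rownames(counts))
}

# NB log-linear IRLS with fixed dispersion alpha; variance mu + alpha mu^2.
# Returns coefficients, their covariance and a convergence flag.
.nbIrls <- function(y, X, offset, alpha, maxIter = 50L, tol = 1e-8) {
  beta <- qr.solve(X, log(y + 0.5) - offset)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- eta - offset + (y - mu) / mu
    XtW <- t(X * w)
    fisher <- XtW %*% X
    betaNew <- tryCatch(
      drop(solve(fisher, XtW %*% z)),
      error = function(e) NULL
    )
    if (is.null(betaNew) || any(!is.finite(betaNew))) {
      return(list(beta = beta, cov = NULL, converged = FALSE))
    }
    if (max(abs(betaNew - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- betaNew
      converged <- TRUE
      break
    }
    beta <- betaNew
  }
  eta <- drop(X %*% beta) + offset
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  cov <- tryCatch(solve(t(X * w) %*% X), error = function(e) NULL)
  list(beta = beta, cov = cov, converged = converged && !is.null(cov))
}

#' Call active enhancers by a paired negative-binomial material test
#'
#' RNA and DNA counts are treated as two experimental conditions within each
#' replicate: for every design a negative-binomial log-linear model with
#' replicate fixed effects plus a material (RNA vs DNA) effect is fit by
#' iteratively reweighted least squares, with per-library size factors as
#' offsets and a fixed method-of-moments dispersion. A two-sided Wald test on
#' the material coefficient is Benjamini-Hochberg adjusted across designs;
#' active means `padj < 0.05` and a positive log2 fold change.
#'
#' Because the dispersion is a plug-in estimate on few libraries, the Wald
#' statistic is referred to a t distribution on the dispersion estimate's
#' degrees of freedom (2k - 2 for k replicates) rather than a normal; with a
#' normal reference the test is visibly anticonservative at k = 4.
#'
#' @param x an [MpraExperiment-class].
#' @param alphaFloor dispersion floor (default 0.01).
#' @param padjThreshold BH-adjusted significance threshold (default 0.05).
#' @param subset optional logical/character vector of designs to test (e.g.
#'   the coverage filter); untested designs are omitted from the output and
#'   the BH family.
#' @return `DataFrame` with design_id, log2fc, waldStat, p, padj, active and
#'   converged.
#' @examples
#' cfg <- SimConfig(seed = 2, nRegions = 40, dnaDepth = 2e5, rnaDepth = 2e5)
#' truth <- simulateTruth(simulateGenome(cfg)$regions, cfg)
#' calls <- testActive(simulateCounts(truth, cfg))
#' table(calls$active)
#' @export
testActive <- function(x, alphaFloor = 0.01, padjThreshold = 0.05,
                       subset = NULL) {
  if (!is.null(subset)) x <- x[subset, ]
  dna <- dnaCounts(x)
  rna <- rnaCounts(x)
  counts <- cbind(dna, rna)
  k <- ncol(dna)
  colnames(counts) <- c(paste0("dna_", 1:k), paste0("rna_", 1:k))
  material <- factor(rep(c("DNA", "RNA"), each = k), c("DNA", "RNA"))
  replicate <- factor(rep(seq_len(k), 2L))
  sf <- mpraSizeFactors(counts)
  alphas <- estimateDispersionMoM(counts, sf, material, alphaFloor)
  X <- stats::model.matrix(~ replicate + material)
  iMat <- ncol(X) # material coefficient is last
  dfDisp <- ncol(counts) - nlevels(material)
  offset <- log(sf)
  n <- nrow(counts)
  log2fc <- wald <- p <- numeric(n)
  conv <- logical(n)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (all(y == 0)) {
      log2fc[i] <- 0; wald[i] <- 0; p[i] <- 1; conv[i] <- FALSE
      next
    }
    fit <- .nbIrls(y, X, offset, alphas[i])
    if (!fit$converged) {
      log2fc[i] <- fit$beta[iMat] / log(2)
      wald[i] <- NA_real_
      p[i] <- 1
      conv[i] <- FALSE
      next
    }
    se <- sqrt(fit$cov[iMat, iMat])
    log2fc[i] <- fit$beta[iMat] / log(2)
    wald[i] <- fit$beta[iMat] / se
    p[i] <- 2 * stats::pt(-abs(wald[i]), df = dfDisp)
    conv[i] <- TRUE
  }
  padj <- stats::p.adjust(p, "BH")
  DataFrame(
    design_id = rownames(counts),
    log2fc = log2fc, waldStat = wald, p = p, padj = padj,
    active = padj < padjThreshold & log2fc > 0,
    converged = conv,
    row.names = rownames(counts)
  )
}
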