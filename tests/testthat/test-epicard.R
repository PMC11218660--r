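test_that("overlap features follow interval arithmetic", {
  w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300)) # 200 bp
  tracks <- list(
    t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(251, 400),
      score = 4),
    t2 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000),
      score = 2),
    t3 = GenomicRanges::GRanges("chr2", IRanges::IRanges(101, 300),
      score = 1)
  )
  f <- suppressWarnings(buildFeatures(w, tracks))
  expect_equal(unname(f[1, "t1_overlap"]), 50)
  expect_equal(unname(f[1, "t1_mean"]), 4)
  expect_equal(unname(f[1, "t1_total"]), 200)
  expect_equal(unname(f[1, "t2_overlap"]), 200) # containment: full window
  expect_equal(unname(f[1, "t3_overlap"]), 0) # wrong chromosome
  expect_equal(unname(f[1, "t3_mean"]), 0)
  expect_equal(unname(f[1, "t3_total"]), 0)
})

test_that("overlap features are additive over a window partition", {
  set.seed(14)
  track <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(sort(sample(1:5000, 20)), width = 80),
    score = runif(20, 1, 5)
  )
  whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000))
  parts <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1001, 1901, 100), width = 100)
  )
  fw <- buildFeatures(whole, list(t = track))
  fp <- buildFeatures(parts, list(t = track))
  expect_equal(sum(fp[, "t_overlap"]), unname(fw[1, "t_overlap"]))
  expect_equal(sum(fp[, "t_total"]), unname(fw[1, "t_total"]))
})

test_that("LASSO training recovers planted annotation signal", {
  cfg <- SimConfig(
    seed = 61, nRegions = 500, annotationCount = 60,
    annotationInformativeCount = 5, annotationWeight = 4
  )
  sim <- simulateGenome(cfg)
  truth <- simulateTruth(sim$regions, cfg)
  tracks <- simulateAnnotations(sim$regions, truth, cfg)
  feats <- buildFeatures(sim$regions, tracks)
  labels <- as.integer(truth@multipliers[names(sim$regions)] != 0)

  model <- trainEpiCard(feats, labels, family = "binary", seed = 5)
  co <- epicardCoef(model)
  nzTracks <- unique(sub("_(overlap|mean|total)$", "", names(co)[co != 0]))
  expect_gte(sum(truth@informativeTracks %in% nzTracks), 4)

  scores <- predictEpiCard(model, feats)
  auc <- mean(outer(scores[labels == 1], scores[labels == 0], ">"))
  expect_gt(auc, 0.9)

  # continuous family on log activity ratios runs and correlates
  act <- truth@multipliers[names(sim$regions)] +
    rnorm(length(sim$regions), 0, 0.3)
  cmod <- trainEpiCard(feats, act, family = "continuous", seed = 5)
  expect_gt(cor(predictEpiCard(cmod, feats), act), 0.5)
})

test_that("LASSO support is monotone along the penalty path", {
  set.seed(71)
  X <- matrix(rnorm(200 * 30), 200, 30,
    dimnames = list(NULL, paste0("f", 1:30)))
  y <- X[, 1] - 2 * X[, 2] + rnorm(200, 0, 0.5)
  fit <- glmnet::glmnet(X, y, alpha = 1)
  support <- colSums(as.matrix(fit$beta) != 0)
  # lambda decreases along the path; support size must not decrease
  expect_true(all(diff(support) >= 0))
})

test_that("degenerate responses give intercept-only models", {
  X <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("f", 1:5)))
  expect_warning(
    m <- trainEpiCard(X, rep(1, 100), family = "continuous"),
    "constant"
  )
  expect_true(all(epicardCoef(m) == 0))
  expect_equal(predictEpiCard(m, X), rep(1, 100), ignore_attr = TRUE)
  # all-zero features score to the intercept; identical features,
  # identical scores
  m2 <- new("EpiCardModel",
    family = "binary",
    coefficients = c(a = 0.5, b = -1), intercept = 0.2,
    lambda = 0.1, metadata = list()
  )
  z <- matrix(0, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predictEpiCard(m2, z), c(0.2, 0.2), ignore_attr = TRUE)
})

test_that("burden statistics reproduce printed-count odds ratios", {
  expect_equal(round(oddsRatio2x2(380, 6211, 509, 10224), 1), 1.2)
  expect_equal(round(oddsRatio2x2(326, 1062, 435, 1610), 1), 1.2)

  # identical cohorts: OR = 1, t-test p = 1
  set.seed(2)
  s <- rnorm(500)
  bt <- burdenTests(s, s,
    caseParticipants = rep(1:50, 10), controlParticipants = rep(1:50, 10))
  expect_equal(bt$orValue, 1)
  expect_gt(bt$tP, 0.99)
  expect_equal(bt$perParticipant$orValue, 1)
  expect_equal(bt$cutoff, unname(quantile(s, 0.95)))
})

test_that("burden machinery detects a simulated cohort enrichment", {
  # control scores N(0,1); case cohort with a shifted subset so that the
  # fraction above the control 95th percentile is ~1.5x higher
  detected <- vapply(1:200, function(s) {
    set.seed(s)
    ctl <- rnorm(1500 * 8)
    cas <- rnorm(1000 * 8)
    boost <- sample(length(cas), round(0.035 * length(cas)))
    cas[boost] <- rnorm(length(boost), 2.4, 0.5)
    bt <- burdenTests(cas, ctl)
    bt$orValue > 1 && bt$fisherP < 0.05
  }, logical(1))
  expect_gt(mean(detected), 0.8)
})

test_that("univariate correlations handle identity, noise and degeneracy", {
  set.seed(33)
  act <- rnorm(1000)
  X <- cbind(
    same = act, noise = rnorm(1000), neg = -act, flat = rep(1, 1000)
  )
  uc <- univariateCorrelations(X, act)
  expect_equal(uc$r[uc$feature == "same"], 1)
  expect_equal(uc$r[uc$feature == "neg"], -1)
  expect_lt(abs(uc$r[uc$feature == "noise"]), 0.1)
  expect_true(uc$degenerate[uc$feature == "flat"])
  expect_true(is.na(uc$r[uc$feature == "flat"]))
})
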