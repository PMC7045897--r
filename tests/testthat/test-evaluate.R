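test_that("confusion counts tally voxels exactly", {
  g <- array(0, c(10, 10, 1))
  g[1:2, 1:5, 1] <- 1                   # 10 gold voxels in a 100-voxel grid
  cc <- counts(confusionCounts(g, g))
  expect_equal(cc, c(tp = 10, fp = 0, fn = 0, tn = 90))
  empty <- array(0, dim(g))
  cc2 <- counts(confusionCounts(empty, g))
  expect_equal(cc2[["tp"]], 0)
  expect_equal(cc2[["fn"]], 10)
  expect_error(confusionCounts(array(0, c(2, 2, 1)), array(0, c(3, 3, 1))),
               "differ")
  expect_error(confusionCounts(array(0.5, c(2, 2, 1)), array(0, c(2, 2, 1))),
               "binary")
})

test_that("counts match a brute-force per-voxel loop on random masks", {
  for (seed in 1:5) {
    p <- randomMask(c(6, 5, 4), p = 0.4, seed = seed)
    g <- randomMask(c(6, 5, 4), p = 0.4, seed = seed + 100)
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(p)) {
      if (p[i] == 1 && g[i] == 1) tp <- tp + 1
      else if (p[i] == 1) fp <- fp + 1
      else if (g[i] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(counts(confusionCounts(p, g)),
                 c(tp = tp, fp = fp, fn = fn, tn = tn))
  }
})

test_that("the three metrics evaluate their formulas and conventions", {
  cc <- new("ConfusionCounts", tp = 3, fp = 1, fn = 1, tn = 95)
  expect_equal(diceCoefficient(cc), 0.75)
  cc2 <- new("ConfusionCounts", tp = 8, fp = 2, fn = 2, tn = 88)
  expect_equal(sensitivity(cc2), 0.8)
  expect_equal(precision(cc2), 0.8)
  # identity, disjoint, and degenerate conventions
  idc <- confusionCounts(randomMask(c(4, 4, 2), seed = 3),
                         randomMask(c(4, 4, 2), seed = 3))
  expect_equal(diceCoefficient(idc), 1)
  a <- array(0, c(2, 2, 2)); a[1, 1, 1] <- 1
  b <- array(0, c(2, 2, 2)); b[2, 2, 2] <- 1
  expect_equal(diceCoefficient(confusionCounts(a, b)), 0)
  emptyBoth <- confusionCounts(array(0, c(2, 2, 1)), array(0, c(2, 2, 1)))
  expect_message(val <- diceCoefficient(emptyBoth), "convention")
  expect_equal(val, 1)
  expect_true(is.na(sensitivity(emptyBoth)))
  expect_true(is.na(precision(emptyBoth)))
})

test_that("Dice is the harmonic mean of sensitivity and precision", {
  for (seed in 1:6) {
    p <- randomMask(c(8, 8, 4), p = 0.3, seed = seed)
    g <- randomMask(c(8, 8, 4), p = 0.3, seed = seed + 50)
    cc <- confusionCounts(p, g)
    s <- sensitivity(cc)
    pr <- precision(cc)
    if (!is.na(s) && !is.na(pr) && (s + pr) > 0) {
      expect_equal(diceCoefficient(cc), 2 * s * pr / (s + pr),
                   tolerance = 1e-12)
    }
  }
})

test_that("k-fold splits are balanced, disjoint and exhaustive", {
  ids <- sprintf("p%02d", 1:44)
  folds <- kfoldSplit(ids, 10, seed = 7)
  sizes <- sort(vapply(folds, function(f) length(f$test), 0L))
  expect_equal(sizes, c(rep(4L, 6), rep(5L, 4)))
  allTest <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(allTest, ids)
  expect_equal(anyDuplicated(allTest), 0L)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), ids)
  }
  # leave-one-out and determinism
  loo <- kfoldSplit(ids[1:5], 5, seed = 1)
  expect_true(all(vapply(loo, function(f) length(f$test), 0L) == 1L))
  expect_identical(kfoldSplit(ids, 10, seed = 7), folds)
  expect_error(kfoldSplit(ids[1:3], 5), "exceeds")
})

test_that("Mann-Whitney U follows the min convention and exact enumeration", {
  same <- c(0.5, 0.6, 0.7)
  expect_gt(mannWhitneyU(same, same)$p, 0.99)
  sep <- mannWhitneyU(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)
  set.seed(9)
  for (i in 1:5) {
    a <- runif(sample(4:7, 1))
    b <- runif(sample(4:7, 1))
    mw <- mannWhitneyU(a, b)
    expect_equal(mw$p, exactMannWhitneyP(a, b), tolerance = 1e-9)
  }
  expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})

test_that("the input comparison runs controlled folds across models", {
  cfg <- tinyPhantomConfig(gridShape = c(32L, 32L, 6L),
                           lesionRadiusRange = c(4, 5),
                           confuserCount = 1L, confuserRadiusRange = c(3, 4),
                           misregOffset = c(0, 0, 0))
  studies <- generateCohort(4, cfg, seed = 3L)
  pre <- lapply(studies, preprocessStudy, register = FALSE,
                targetSize = c(16L, 16L))
  res <- runInputComparison(
    pre, k = 2L, seed = 5L,
    netCfg = segNetConfig(inputSize = 16L, channelsPerStage = c(8L, 16L),
                          growthRate = 8L, denseMicroBlocks = 1L,
                          bottleneckFactor = 2L, gnGroups = 4L),
    trainCfg = trainConfig(epochs = 1L, seed = 2L))
  expect_setequal(unique(res$perPatient$model), c("dual", "t1", "t2"))
  # every patient evaluated once per model, same folds for all models
  expect_equal(nrow(res$perPatient), 12L)
  for (mo in c("t1", "t2")) {
    a <- res$perPatient[res$perPatient$model == mo, c("fold", "patient")]
    b <- res$perPatient[res$perPatient$model == "dual", c("fold", "patient")]
    expect_equal(a[order(a$patient), ], b[order(b$patient), ],
                 ignore_attr = TRUE)
  }
  expect_equal(nrow(res$table1), 3L)
  expect_equal(nrow(res$tests), 2L)
  expect_true(all(is.finite(res$table1$dsc_mean)))
})
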