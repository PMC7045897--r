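test_that("soft Dice loss takes its closed-form values", {
  g <- matrix(c(1, 0, 1, 1), 2)
  expect_equal(diceLoss(g, g, smooth = 1e-12), 0, tolerance = 1e-9)
  disj <- matrix(c(0, 1, 0, 0), 2)
  expect_equal(diceLoss(disj, g, smooth = 1e-12), 1, tolerance = 1e-9)
  # uniform 0.5 on a 2-pixel image with g = (1, 0): 1 - (2*0.5)/(1+1)
  expect_equal(diceLoss(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1),
                        smooth = 0), 0.5)
  expect_error(diceLoss(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
})

test_that("augmentation is an identity at neutral parameters and involutive", {
  set.seed(31)
  s <- list(x1 = matrix(runif(64), 8), x2 = matrix(runif(64), 8),
            y = matrix(rbinom(64, 1, 0.3), 8))
  expect_identical(augmentSample(s, flip = FALSE, scale = 1), s)
  flipped2 <- augmentSample(augmentSample(s, TRUE, 1), TRUE, 1)
  expect_equal(flipped2$x1, s$x1)
  expect_equal(flipped2$y, s$y)
  resc <- augmentSample(s, FALSE, 1.1)
  expect_true(all(resc$y %in% c(0, 1)))
  expect_equal(dim(resc$x1), dim(s$x1))
  down <- augmentSample(s, FALSE, 0.9)
  expect_true(all(down$y %in% c(0, 1)))
})

test_that("training enforces preconditions", {
  net <- buildDualNet(tinyNetConfig())
  expect_error(trainConfig(epochs = 0L))
  expect_error(trainConfig(learningRate = -1))
  expect_error(trainNetwork(net, list(), trainConfig(epochs = 1L)),
               "empty")
  bad <- list(list(x1 = matrix(0, 8, 8), x2 = matrix(0, 8, 8),
                   y = matrix(0, 8, 8)))
  expect_error(trainNetwork(net, bad, trainConfig(epochs = 1L)), "expects")
})

test_that("training is seed-reproducible and bounded, and loss decreases", {
  st <- generateStudy(tinyPhantomConfig(seed = 13L))
  pre <- preprocessStudy(st, register = FALSE, targetSize = c(32L, 32L))
  g <- volData(gold(pre))
  k <- which.max(apply(g, 3, sum))
  sm <- list(x1 = volData(t1w(pre))[, , k], x2 = volData(t2w(pre))[, , k],
             y = g[, , k])
  ds <- rep(list(sm), 4)
  cfg <- trainConfig(epochs = 10L, learningRate = 1e-3, augment = FALSE,
                     seed = 5L)
  r1 <- trainNetwork(buildDualNet(tinyNetConfig(initSeed = 3L)), ds, cfg)
  r2 <- trainNetwork(buildDualNet(tinyNetConfig(initSeed = 3L)), ds, cfg)
  expect_identical(r1$history$loss, r2$history$loss)
  expect_true(all(r1$history$loss >= 0 & r1$history$loss <= 1))
  # memorizing a single slice: clear decrease over the first 10 epochs
  expect_lt(tail(r1$history$loss, 1), r1$history$loss[1] - 0.1)
  expect_equal(nrow(r1$history), 10L)
})

test_that("augmented training streams are reproducible too", {
  st <- generateStudy(tinyPhantomConfig(seed = 14L))
  pre <- preprocessStudy(st, register = FALSE, targetSize = c(32L, 32L))
  ds <- buildSliceDataset(list(pre), input = "dual")[1:4]
  cfg <- trainConfig(epochs = 2L, learningRate = 5e-4, augment = TRUE,
                     seed = 11L)
  r1 <- trainNetwork(buildDualNet(tinyNetConfig(initSeed = 2L)), ds, cfg)
  r2 <- trainNetwork(buildDualNet(tinyNetConfig(initSeed = 2L)), ds, cfg)
  expect_identical(r1$history$loss, r2$history$loss)
})

test_that("single-sequence datasets drive single-path networks", {
  st <- generateStudy(tinyPhantomConfig(seed = 15L))
  pre <- preprocessStudy(st, register = FALSE, targetSize = c(32L, 32L))
  dsT2 <- buildSliceDataset(list(pre), input = "t2")
  expect_null(dsT2[[1]]$x2)
  net <- buildSingleNet(tinyNetConfig(dualInput = FALSE))
  r <- trainNetwork(net, dsT2[1:3], trainConfig(epochs = 1L, seed = 1L))
  expect_equal(nrow(r$history), 1L)
  prob <- predictStudy(net, pre, input = "t2")
  expect_equal(dim(volData(prob)), dim(volData(gold(pre))))
  # dual network refuses single-channel samples
  expect_error(
    trainNetwork(buildDualNet(tinyNetConfig()), dsT2,
                 trainConfig(epochs = 1L)),
    "dual")
})
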