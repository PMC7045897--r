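test_that("leaky ReLU follows its two-branch definition", {
  expect_equal(leakyRelu(5, 0.1), 5)
  expect_equal(leakyRelu(-10, 0.1), -1)
  expect_equal(leakyRelu(0, 0.1), 0)
  expect_equal(leakyRelu(c(-2, 3), 0.25), c(-0.5, 3))
  expect_error(leakyRelu(1, alpha = 0), "between 0 and 1")
  expect_error(leakyRelu(1, alpha = 1.2), "between 0 and 1")
})

test_that("group normalization matches direct mean/variance oracles", {
  set.seed(21)
  x <- array(rnorm(6 * 6 * 4, mean = 3, sd = 2), c(6, 6, 4))
  # constant input normalizes to zero through the epsilon convention
  expect_equal(groupNormalize(array(5, c(4, 4, 2)), 2L),
               array(0, c(4, 4, 2)))
  # groups = 1: layer-wide normalization
  o1 <- (x - mean(x)) / sqrt(mean((x - mean(x))^2) + 1e-5)
  expect_equal(groupNormalize(x, 1L), o1)
  # groups = channels: per-channel instance normalization
  oc <- x
  for (c in 1:4) {
    xc <- x[, , c]
    oc[, , c] <- (xc - mean(xc)) / sqrt(mean((xc - mean(xc))^2) + 1e-5)
  }
  expect_equal(groupNormalize(x, 4L), oc)
  expect_error(groupNormalize(x, 3L), "divisible")
})

test_that("config validity enforces slope, divisibility and input size", {
  expect_error(segNetConfig(lreluAlpha = 1.5), "between 0 and 1")
  expect_error(segNetConfig(channelsPerStage = c(12L, 24L)), "divisible")
  expect_error(segNetConfig(inputSize = 100L), "divisible by 2")
  expect_s4_class(tinyNetConfig(), "SegNetConfig")
})

test_that("forward pass restores the input size with outputs in (0,1)", {
  for (sz in c(32L, 64L)) {
    cfg <- tinyNetConfig(inputSize = sz)
    net <- buildDualNet(cfg)
    p <- predictSlice(net, matrix(runif(sz * sz), sz),
                      matrix(runif(sz * sz), sz))
    expect_equal(dim(p), c(sz, sz))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("inference and builds are deterministic", {
  cfg <- tinyNetConfig(initSeed = 5L)
  net <- buildDualNet(cfg)
  x1 <- matrix(runif(32 * 32), 32)
  x2 <- matrix(runif(32 * 32), 32)
  expect_identical(predictSlice(net, x1, x2), predictSlice(net, x1, x2))
  net2 <- buildDualNet(cfg)
  expect_identical(paramCount(net), paramCount(net2))
  expect_identical(net@params[["e1a.c1.w"]]$v, net2@params[["e1a.c1.w"]]$v)
})

test_that("dense block widths follow in_width + m K", {
  for (m in 0:4) {
    cfg <- tinyNetConfig(denseMicroBlocks = m, growthRate = 8L)
    net <- buildDualNet(cfg)
    dIn <- 2L * cfg@channelsPerStage[1]
    if (m > 0) {
      for (i in seq_len(m)) {
        # micro-block i's first group-norm sees dIn + (i-1) K channels
        expect_length(net@params[[sprintf("d%d.g1.g", i)]]$v,
                      dIn + (i - 1L) * cfg@growthRate)
      }
    }
    # transition compresses dIn + m K back to the dense input width
    expect_length(net@params[["t.g.g"]]$v, dIn + m * cfg@growthRate)
    expect_equal(dim(net@params[["t.c.w"]]$v),
                 c(dIn + m * cfg@growthRate, dIn))
    # and the network still closes shape-wise
    p <- predictSlice(net, matrix(0.5, 32, 32), matrix(0.5, 32, 32))
    expect_equal(dim(p), c(32L, 32L))
  }
})

test_that("encoder block parameter count matches the closed form", {
  cfg <- tinyNetConfig()
  net <- buildDualNet(cfg)
  cin <- 1L
  cout <- cfg@channelsPerStage[1]
  # three 3x3 convs (+bias) and two GN scale/shift pairs
  expected <- (9 * cin * cout + cout) + 2 * (9 * cout * cout + cout) +
    2 * (2 * cout)
  got <- sum(vapply(grep("^e1a\\.", names(net@params), value = TRUE),
                    function(nm) length(net@params[[nm]]$v), 0))
  expect_equal(got, expected)
})

test_that("the single-sequence variant is a strict submodel", {
  dual <- buildDualNet(tinyNetConfig())
  single <- buildSingleNet(tinyNetConfig(dualInput = FALSE))
  expect_lt(paramCount(single), paramCount(dual))
  # the first-stage output width equals the dense block's input width
  expect_equal(dim(single@params[["d1.c1.w"]]$v)[1],
               single@config@channelsPerStage[1])
  p <- predictSlice(single, matrix(runif(32 * 32), 32))
  expect_equal(dim(p), c(32L, 32L))
  expect_true(all(p > 0 & p < 1))
  expect_error(buildSingleNet(tinyNetConfig(dualInput = TRUE)), "dualInput")
  expect_error(buildDualNet(tinyNetConfig(dualInput = FALSE)), "dualInput")
})

test_that("network summary enumerates every parameter tensor", {
  net <- buildDualNet(tinyNetConfig())
  s <- networkSummary(net)
  expect_equal(sum(s$n), paramCount(net))
  expect_true(all(c("e1a.c1.w", "t.c.w", "f.c.w") %in% s$name))
})

test_that("checkpoints restore bit-identical networks", {
  net <- buildDualNet(tinyNetConfig(initSeed = 9L))
  path <- withr::local_tempfile(fileext = ".rds")
  saveNetwork(net, path)
  back <- loadNetwork(path)
  expect_identical(paramCount(back), paramCount(net))
  x1 <- matrix(runif(32 * 32), 32)
  x2 <- matrix(runif(32 * 32), 32)
  expect_identical(predictSlice(back, x1, x2), predictSlice(net, x1, x2))
})
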