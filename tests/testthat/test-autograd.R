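# analytic gradients of every layer against central differences

agNode <- ddunet:::agNode
agTape <- ddunet:::agTape

scalarThrough <- function(tape, out) {
  # reduce an output node to a scalar with a nonlinear weighting so the
  # backward path is exercised with a non-uniform gradient
  loss <- agNode(sum(sin(out$v)))
  ddunet:::agPush(tape, function() {
    ddunet:::agAccum(out, loss$g * cos(out$v))
  })
  loss
}

test_that("convolution gradients match numerical differentiation", {
  set.seed(11)
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  w <- matrix(rnorm(27 * 4) * 0.3, 27, 4)
  b <- rnorm(4)
  f <- function(xa, wa, ba, stride) {
    sum(sin(ddunet:::.cpp_conv2d_fwd(array(xa, dim(x)), matrix(wa, 27, 4),
                                     ba, 3L, 3L, stride, 1L)))
  }
  for (stride in c(1L, 2L)) {
    tape <- agTape()
    xn <- agNode(x); wn <- agNode(w); bn <- agNode(b)
    out <- ddunet:::agConv(tape, xn, wn, bn, 3L, 3L, stride, 1L)
    ddunet:::agBackward(tape, scalarThrough(tape, out))
    expect_equal(xn$g, numGrad(function(a) f(a, w, b, stride), x),
                 tolerance = 1e-6)
    expect_equal(wn$g, numGrad(function(a) f(x, a, b, stride), w),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(bn$g, numGrad(function(a) f(x, w, a, stride), b),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("transposed convolution doubles size and its gradients check out", {
  set.seed(12)
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  w <- matrix(rnorm(18 * 3) * 0.3, 18, 3)  # (9 * Cout=2) x Cin=3
  b <- rnorm(2)
  f <- function(xa, wa, ba) {
    y <- ddunet:::.cpp_conv2d_bwd_input(array(xa, dim(x)), matrix(wa, 18, 3),
                                        3L, 3L, 2L, 1L, 8L, 8L)
    sum(sin(sweep(y, 3, ba, `+`)))
  }
  tape <- agTape()
  xn <- agNode(x); wn <- agNode(w); bn <- agNode(b)
  out <- ddunet:::agConvT(tape, xn, wn, bn)
  expect_equal(dim(out$v), c(8L, 8L, 2L))
  ddunet:::agBackward(tape, scalarThrough(tape, out))
  expect_equal(xn$g, numGrad(function(a) f(a, w, b), x), tolerance = 1e-6)
  expect_equal(wn$g, numGrad(function(a) f(x, a, b), w), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(bn$g, numGrad(function(a) f(x, w, a), b), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("group-norm gradients match numerical differentiation", {
  set.seed(13)
  x <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  gam <- rnorm(4) * 0.5 + 1
  bet <- rnorm(4) * 0.2
  f <- function(xa, ga, ba) {
    sum(sin(groupNormalize(array(xa, dim(x)), 2L, ga, ba)))
  }
  tape <- agTape()
  xn <- agNode(x); gn <- agNode(gam); bn <- agNode(bet)
  out <- ddunet:::agGroupNorm(tape, xn, gn, bn, 2L, 1e-5)
  ddunet:::agBackward(tape, scalarThrough(tape, out))
  expect_equal(xn$g, numGrad(function(a) f(a, gam, bet), x),
               tolerance = 1e-5)
  expect_equal(gn$g, numGrad(function(a) f(x, a, bet), gam),
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(bn$g, numGrad(function(a) f(x, gam, a), bet),
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("pooling, activation and Dice-loss gradients check out", {
  set.seed(14)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  tape <- agTape()
  xn <- agNode(x)
  out <- ddunet:::agAvgPool2(tape, ddunet:::agLRelu(tape, xn, 0.1))
  ddunet:::agBackward(tape, scalarThrough(tape, out))
  f <- function(xa) {
    y <- leakyRelu(array(xa, dim(x)), 0.1)
    io <- c(1, 3); jo <- c(1, 3)
    p <- (y[io, jo, , drop = FALSE] + y[io + 1, jo, , drop = FALSE] +
          y[io, jo + 1, , drop = FALSE] + y[io + 1, jo + 1, , drop = FALSE]) / 4
    sum(sin(p))
  }
  expect_equal(xn$g, numGrad(f, x), tolerance = 1e-6)

  p <- matrix(runif(16), 4)
  g <- matrix(rbinom(16, 1, 0.4), 4)
  tape <- agTape()
  pn <- agNode(array(p, c(4, 4, 1)))
  ln <- ddunet:::agDiceLoss(tape, pn, g, smooth = 1)
  ddunet:::agBackward(tape, ln)
  expect_equal(pn$g[, , 1],
               numGrad(function(a) diceLoss(matrix(a, 4, 4), g, 1), p),
               tolerance = 1e-6)
})

test_that("sigmoid output node backpropagates through concatenation", {
  set.seed(15)
  a <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  b <- array(rnorm(3 * 3 * 1), c(3, 3, 1))
  f <- function(aa, bb) {
    y <- 1 / (1 + exp(-c(aa, bb)))
    sum(sin(y))
  }
  tape <- agTape()
  an <- agNode(a); bn <- agNode(b)
  out <- ddunet:::agSigmoid(tape, ddunet:::agConcat(tape, list(an, bn)))
  ddunet:::agBackward(tape, scalarThrough(tape, out))
  expect_equal(an$g, numGrad(function(z) f(array(z, dim(a)), b), a),
               tolerance = 1e-6)
  expect_equal(bn$g, numGrad(function(z) f(a, array(z, dim(b))), b),
               tolerance = 1e-6)
})
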