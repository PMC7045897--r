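# Reverse-mode autodiff tape for the segmentation network.
#
# A node is an environment with $v (value array) and $g (gradient, filled
# during the backward sweep). Operations compute the output value eagerly
# and, when a tape is supplied, push a closure that propagates the output
# gradient to the inputs. Inference passes use tape = NULL and skip all
# bookkeeping. Feature maps are H x W x C arrays; convolutions run through
# the compiled im2col kernels.

agNode <- function(v) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e
}

agTape <- function() {
  e <- new.env(parent = emptyenv())
  e$ops <- list()
  e
}

agPush <- function(tape, fn) {
  if (!is.null(tape)) tape$ops[[length(tape$ops) + 1L]] <- fn
  invisible(NULL)
}

agAccum <- function(node, g) {
  node$g <- if (is.null(node$g)) g else node$g + g
  invisible(NULL)
}

# run the backward sweep from a scalar output node
agBackward <- function(tape, out) {
  out$g <- 1
  for (i in rev(seq_along(tape$ops))) tape$ops[[i]]()
  invisible(NULL)
}

.as3d <- function(v) {
  if (is.matrix(v)) array(v, c(dim(v), 1L)) else v
}

# 2D convolution, zero padding, weight w: (kh*kw*Cin) x Cout
agConv <- function(tape, x, w, b, kh, kw, stride, pad) {
  xv <- .as3d(x$v)
  out <- agNode(.cpp_conv2d_fwd(xv, w$v, b$v, kh, kw, stride, pad))
  agPush(tape, function() {
    gy <- out$g
    agAccum(x, .cpp_conv2d_bwd_input(gy, w$v, kh, kw, stride, pad,
                                     dim(xv)[1], dim(xv)[2]))
    agAccum(w, .cpp_conv2d_bwd_weight(xv, gy, kh, kw, stride, pad))
    agAccum(b, apply(gy, 3, sum))
  })
  out
}

# 3x3 stride-2 transposed convolution doubling the spatial size;
# weight w: (3*3*Cout) x Cin, the transpose-pair of a stride-2 conv
agConvT <- function(tape, x, w, b) {
  xv <- .as3d(x$v)
  oh <- 2L * dim(xv)[1]
  ow <- 2L * dim(xv)[2]
  y <- .cpp_conv2d_bwd_input(xv, w$v, 3L, 3L, 2L, 1L, oh, ow)
  y <- sweep(y, 3, b$v, `+`)
  out <- agNode(y)
  agPush(tape, function() {
    gy <- out$g
    agAccum(x, .cpp_conv2d_fwd(gy, w$v, numeric(ncol(w$v)), 3L, 3L, 2L, 1L))
    agAccum(w, .cpp_conv2d_bwd_weight(gy, xv, 3L, 3L, 2L, 1L))
    agAccum(b, apply(gy, 3, sum))
  })
  out
}

# group normalization with learned per-channel scale/shift
agGroupNorm <- function(tape, x, gamma, beta, groups, eps) {
  v <- .as3d(x$v)
  d <- dim(v)
  C <- d[3]
  if (C %% groups != 0L) {
    stop(sprintf("channel count %d not divisible by %d groups", C, groups))
  }
  cg <- C %/% groups
  xhat <- array(0, d)
  mu <- numeric(groups)
  istd <- numeric(groups)
  for (g in seq_len(groups)) {
    idx <- ((g - 1L) * cg + 1L):(g * cg)
    xg <- v[, , idx, drop = FALSE]
    m <- mean(xg)
    va <- mean((xg - m)^2)
    mu[g] <- m
    istd[g] <- 1 / sqrt(va + eps)
    xhat[, , idx] <- (xg - m) * istd[g]
  }
  gam <- rep(gamma$v, each = d[1] * d[2])
  y <- xhat * array(gam, d) + array(rep(beta$v, each = d[1] * d[2]), d)
  out <- agNode(y)
  agPush(tape, function() {
    gy <- out$g
    agAccum(gamma, apply(gy * xhat, 3, sum))
    agAccum(beta, apply(gy, 3, sum))
    gx <- array(0, d)
    for (g in seq_len(groups)) {
      idx <- ((g - 1L) * cg + 1L):(g * cg)
      n <- d[1] * d[2] * cg
      dxh <- gy[, , idx, drop = FALSE] *
        array(rep(gamma$v[idx], each = d[1] * d[2]), c(d[1], d[2], cg))
      xh <- xhat[, , idx, drop = FALSE]
      s1 <- sum(dxh)
      s2 <- sum(dxh * xh)
      gx[, , idx] <- istd[g] * (dxh - s1 / n - xh * s2 / n)
    }
    agAccum(x, gx)
  })
  out
}

agLRelu <- function(tape, x, alpha) {
  v <- x$v
  neg <- v < 0
  y <- v
  y[neg] <- alpha * v[neg]
  out <- agNode(y)
  agPush(tape, function() {
    g <- out$g
    g[neg] <- alpha * g[neg]
    agAccum(x, g)
  })
  out
}

agSigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$v))
  out <- agNode(y)
  agPush(tape, function() agAccum(x, out$g * y * (1 - y)))
  out
}

# channel-wise concatenation of a list of nodes
agConcat <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) .as3d(n$v))
  chans <- vapply(vals, function(v) dim(v)[3], 0L)
  d1 <- dim(vals[[1L]])
  y <- array(0, c(d1[1], d1[2], sum(chans)))
  at <- 0L
  for (v in vals) {
    y[, , at + seq_len(dim(v)[3])] <- v
    at <- at + dim(v)[3]
  }
  out <- agNode(y)
  agPush(tape, function() {
    at <- 0L
    for (i in seq_along(nodes)) {
      agAccum(nodes[[i]], out$g[, , at + seq_len(chans[i]), drop = FALSE])
      at <- at + chans[i]
    }
  })
  out
}

# 2x2 average pooling, stride 2 (spatial dims must be even)
agAvgPool2 <- function(tape, x) {
  v <- .as3d(x$v)
  d <- dim(v)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
    stop("average pooling requires even spatial dimensions")
  }
  io <- seq(1L, d[1], 2L)
  jo <- seq(1L, d[2], 2L)
  y <- (v[io, jo, , drop = FALSE] + v[io + 1L, jo, , drop = FALSE] +
        v[io, jo + 1L, , drop = FALSE] + v[io + 1L, jo + 1L, , drop = FALSE]) / 4
  out <- agNode(y)
  agPush(tape, function() {
    g <- out$g / 4
    gx <- array(0, d)
    gx[io, jo, ] <- g
    gx[io + 1L, jo, ] <- g
    gx[io, jo + 1L, ] <- g
    gx[io + 1L, jo + 1L, ] <- g
    agAccum(x, gx)
  })
  out
}

# soft Dice loss between a probability node and a fixed binary mask:
# 1 - (2 sum(p g) + s) / (sum p + sum g + s)
agDiceLoss <- function(tape, p, goldMask, smooth) {
  pv <- p$v
  if (!isTRUE(all.equal(dim(.as3d(pv))[1:2], dim(goldMask)[1:2]))) {
    stop("probability map and gold mask shapes differ")
  }
  g <- as.numeric(goldMask)
  pvv <- as.numeric(pv)
  inter <- sum(pvv * g)
  denom <- sum(pvv) + sum(g) + smooth
  loss <- 1 - (2 * inter + smooth) / denom
  out <- agNode(loss)
  agPush(tape, function() {
    # d/dp of -(2 pg + s)/(sum p + sum g + s)
    gp <- -(2 * g * denom - (2 * inter + smooth)) / denom^2
    agAccum(p, array(out$g * gp, dim(pv)))
  })
  out
}
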