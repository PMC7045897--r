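#' Configure the dense dual-path segmentation network
#'
#' The architecture is an encoder-decoder with a dense connectivity block.
#' Each input sequence enters through its own first-stage encoder block;
#' the two paths are concatenated channel-wise and fused by a dense block
#' (each micro-block sees the concatenation of the block input and all
#' previous micro-block outputs and appends \code{growthRate} channels)
#' followed by a transition block (group norm, 1 x 1 convolution
#' compressing back to the dense input width, 2 x 2 average pooling). The
#' remaining encoder stages then downsample further, and one decoder block
#' per downsampling (transposed convolution, skip concatenation with the
#' matching encoder features, two 3 x 3 convolutions with group norm and
#' leaky ReLU) restores the input resolution; a 1 x 1 convolution with a
#' pixel-wise sigmoid emits the probability map.
#'
#' An encoder block is three 3 x 3 convolutions with group norm and leaky
#' ReLU after the first two; the third runs at stride 2 and halves the
#' spatial size. With \code{s = length(channelsPerStage)} encoder stages the
#' network downsamples \code{s + 1} times (the extra one from the
#' transition pooling) and therefore has \code{s + 1} decoder blocks; the
#' default four stages give five decoder blocks, and \code{inputSize} must
#' be divisible by \code{2^(s+1)}.
#'
#' @param inputSize integer pair, the in-plane slice shape (default
#'   256 x 256).
#' @param channelsPerStage output width of each encoder stage; the first
#'   entry is the per-path width of the two parallel input blocks.
#' @param growthRate dense-block growth rate K: channels appended by each
#'   micro-block.
#' @param denseMicroBlocks number of dense micro-blocks (pre-transition
#'   width is the dense input width plus \code{denseMicroBlocks * K}).
#' @param bottleneckFactor width multiplier of the 1 x 1 bottleneck
#'   convolution inside each micro-block (DenseNet convention, 4).
#' @param gnGroups group-normalization groups (default 8); every normalized
#'   width must be divisible by this.
#' @param lreluAlpha negative-part slope of the leaky ReLU, in (0, 1);
#'   default 0.1.
#' @param dualInput \code{TRUE} for the dual-sequence network, \code{FALSE}
#'   for the single-sequence variant (one input path, whose first-stage
#'   output feeds the dense block directly).
#' @param gnEps group-norm variance floor.
#' @param initSeed seed for He-uniform weight initialization.
#' @return A validated \linkS4class{SegNetConfig}.
#' @export
segNetConfig <- function(inputSize = c(256L, 256L),
                         channelsPerStage = c(32L, 64L, 128L, 256L),
                         growthRate = 32L,
                         denseMicroBlocks = 4L,
                         bottleneckFactor = 4L,
                         gnGroups = 8L,
                         lreluAlpha = 0.1,
                         dualInput = TRUE,
                         gnEps = 1e-5,
                         initSeed = 1L) {
  if (length(inputSize) == 1L) inputSize <- c(inputSize, inputSize)
  new("SegNetConfig",
      inputSize = as.integer(inputSize),
      channelsPerStage = as.integer(channelsPerStage),
      growthRate = as.integer(growthRate),
      denseMicroBlocks = as.integer(denseMicroBlocks),
      bottleneckFactor = as.integer(bottleneckFactor),
      gnGroups = as.integer(gnGroups),
      lreluAlpha = as.numeric(lreluAlpha),
      dualInput = isTRUE(dualInput),
      gnEps = as.numeric(gnEps),
      initSeed = as.integer(initSeed))
}

# every channel width that passes through a group-norm layer, used by the
# config validity check
.segnetGnWidths <- function(cfg) {
  cps <- cfg@channelsPerStage
  k <- cfg@growthRate
  m <- cfg@denseMicroBlocks
  dIn <- if (cfg@dualInput) 2L * cps[1] else cps[1]
  dense <- if (m > 0L) {
    c(dIn + (seq_len(m) - 1L) * k, cfg@bottleneckFactor * k)
  } else integer(0)
  skips <- c(rev(cps[-1]), dIn, dIn)
  c(cps, dense, dIn + m * k, skips)
}

#' Leaky rectified linear unit
#'
#' \code{y = x} for \code{x >= 0} and \code{y = alpha * x} otherwise,
#' elementwise.
#'
#' @param x numeric vector/array.
#' @param alpha negative-part slope, strictly inside (0, 1). Default 0.1.
#' @return Same shape as \code{x}.
#' @examples
#' leakyRelu(c(5, -10, 0))
#' @export
leakyRelu <- function(x, alpha = 0.1) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1")
  }
  ifelse(x >= 0, x, alpha * x) * 1
}

#' Group normalization (plain numeric version)
#'
#' Normalizes an H x W x C feature array to zero mean and unit variance
#' within each of \code{groups} contiguous channel groups, then applies the
#' per-channel scale and shift.
#'
#' @param x H x W x C array.
#' @param groups number of channel groups; must divide C.
#' @param gamma,beta per-channel scale and shift (defaults 1 and 0).
#' @param eps variance floor.
#' @return Array of the same shape.
#' @export
groupNormalize <- function(x, groups, gamma = NULL, beta = NULL,
                           eps = 1e-5) {
  x <- .as3d(x)
  C <- dim(x)[3]
  if (C %% groups != 0L) {
    stop(sprintf("channel count %d not divisible by %d groups", C, groups))
  }
  if (is.null(gamma)) gamma <- rep(1, C)
  if (is.null(beta)) beta <- rep(0, C)
  n <- agGroupNorm(NULL, agNode(x), agNode(gamma), agNode(beta), groups, eps)
  n$v
}

# ---- parameter construction -------------------------------------------

.heUniform <- function(n, fanIn) {
  lim <- sqrt(6 / fanIn)
  stats::runif(n, -lim, lim)
}

.mkConv <- function(params, name, kh, kw, cin, cout) {
  w <- matrix(.heUniform(kh * kw * cin * cout, kh * kw * cin),
              kh * kw * cin, cout)
  params[[paste0(name, ".w")]] <- agNode(w)
  params[[paste0(name, ".b")]] <- agNode(numeric(cout))
  params
}

.mkConvT <- function(params, name, cin, cout) {
  w <- matrix(.heUniform(9L * cout * cin, 9L * cin), 9L * cout, cin)
  params[[paste0(name, ".w")]] <- agNode(w)
  params[[paste0(name, ".b")]] <- agNode(numeric(cout))
  params
}

.mkGN <- function(params, name, ch) {
  params[[paste0(name, ".g")]] <- agNode(rep(1, ch))
  params[[paste0(name, ".s")]] <- agNode(numeric(ch))
  params
}

# parameter list for the full network; layout mirrors .segnetForward
.segnetParams <- function(cfg, arch) {
  cps <- cfg@channelsPerStage
  nS <- length(cps)
  k <- cfg@growthRate
  m <- cfg@denseMicroBlocks
  bf <- cfg@bottleneckFactor
  dual <- arch == "dual"
  dIn <- if (dual) 2L * cps[1] else cps[1]

  p <- list()
  encBlock <- function(p, pfx, cin, cout) {
    p <- .mkConv(p, paste0(pfx, ".c1"), 3L, 3L, cin, cout)
    p <- .mkGN(p, paste0(pfx, ".g1"), cout)
    p <- .mkConv(p, paste0(pfx, ".c2"), 3L, 3L, cout, cout)
    p <- .mkGN(p, paste0(pfx, ".g2"), cout)
    .mkConv(p, paste0(pfx, ".c3"), 3L, 3L, cout, cout)
  }

  p <- encBlock(p, "e1a", 1L, cps[1])
  if (dual) p <- encBlock(p, "e1b", 1L, cps[1])

  for (i in seq_len(m)) {
    wIn <- dIn + (i - 1L) * k
    pfx <- sprintf("d%d", i)
    p <- .mkGN(p, paste0(pfx, ".g1"), wIn)
    p <- .mkConv(p, paste0(pfx, ".c1"), 1L, 1L, wIn, bf * k)
    p <- .mkGN(p, paste0(pfx, ".g2"), bf * k)
    p <- .mkConv(p, paste0(pfx, ".c2"), 3L, 3L, bf * k, k)
  }
  p <- .mkGN(p, "t.g", dIn + m * k)
  p <- .mkConv(p, "t.c", 1L, 1L, dIn + m * k, dIn)

  wPrev <- dIn
  for (i in seq_len(nS - 1L)) {
    p <- encBlock(p, sprintf("e%d", i + 1L), wPrev, cps[i + 1L])
    wPrev <- cps[i + 1L]
  }

  skips <- c(rev(cps[-1]), dIn, dIn)
  for (j in seq_along(skips)) {
    s <- skips[j]
    pfx <- sprintf("u%d", j)
    p <- .mkConvT(p, paste0(pfx, ".up"), wPrev, s)
    p <- .mkConv(p, paste0(pfx, ".c1"), 3L, 3L, 2L * s, s)
    p <- .mkGN(p, paste0(pfx, ".g1"), s)
    p <- .mkConv(p, paste0(pfx, ".c2"), 3L, 3L, s, s)
    p <- .mkGN(p, paste0(pfx, ".g2"), s)
    wPrev <- s
  }
  p <- .mkConv(p, "f.c", 1L, 1L, wPrev, 1L)
  # start the classifier biased toward foreground: with a pure Dice
  # objective and many empty-mask slices, a net initialized near p = 0.5
  # can saturate into the all-background attractor before the lesion
  # gradient takes hold; a positive prior bias avoids that
  p[["f.c.b"]]$v <- 1
  p
}

#' Build the dual-sequence segmentation network
#'
#' Instantiates the network weights (He-uniform, seeded by
#' \code{initSeed}) for the dual-path architecture described in
#' \code{\link{segNetConfig}}. Builds from the same config are
#' bit-identical.
#'
#' @param cfg a \linkS4class{SegNetConfig} with \code{dualInput = TRUE}.
#' @return A \linkS4class{SegNet} handle.
#' @export
buildDualNet <- function(cfg = segNetConfig()) {
  stopifnot(is(cfg, "SegNetConfig"))
  if (!cfg@dualInput) stop("cfg must have dualInput = TRUE for buildDualNet")
  validObject(cfg)
  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  })
  set.seed(cfg@initSeed)
  new("SegNet", config = cfg, params = .segnetParams(cfg, "dual"),
      arch = "dual")
}

#' Build the single-sequence ablation network
#'
#' Identical to the dual network except that there is a single first-stage
#' path whose output feeds the dense connectivity block directly (no
#' pre-dense concatenation); strictly fewer parameters than the dual
#' network at equal widths.
#'
#' @param cfg a \linkS4class{SegNetConfig} with \code{dualInput = FALSE}.
#' @return A \linkS4class{SegNet} handle.
#' @export
buildSingleNet <- function(cfg = segNetConfig(dualInput = FALSE)) {
  stopifnot(is(cfg, "SegNetConfig"))
  if (cfg@dualInput) stop("cfg must have dualInput = FALSE for buildSingleNet")
  validObject(cfg)
  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  })
  set.seed(cfg@initSeed)
  new("SegNet", config = cfg, params = .segnetParams(cfg, "single"),
      arch = "single")
}

#' @describeIn buildDualNet total number of trainable scalars
#' @param x a SegNet.
#' @export
setMethod("paramCount", "SegNet", function(x) {
  sum(vapply(x@params, function(p) length(p$v), 0))
})

setMethod("show", "SegNet", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SegNet (%s input), %d encoder stages + dense block (K=%d, m=%d), %s parameters\n",
    object@arch, length(cfg@channelsPerStage), cfg@growthRate,
    cfg@denseMicroBlocks, format(paramCount(object), big.mark = ",")))
})

#' Save / load network weights
#'
#' Checkpoints carry the weight arrays, the full configuration, the
#' architecture label and the config hash, so a reloaded network is
#' bit-identical to the saved one.
#'
#' @param net a \linkS4class{SegNet}.
#' @param path checkpoint file (RDS).
#' @return \code{saveNetwork} returns \code{path} invisibly;
#'   \code{loadNetwork} returns the reconstructed \linkS4class{SegNet}.
#' @export
saveNetwork <- function(net, path) {
  stopifnot(is(net, "SegNet"))
  saveRDS(list(arch = net@arch, config = net@config,
               weights = lapply(net@params, function(p) p$v),
               configHash = configHash(net@config)), path)
  invisible(path)
}

#' @rdname saveNetwork
#' @export
loadNetwork <- function(path) {
  ck <- readRDS(path)
  params <- lapply(ck$weights, agNode)
  new("SegNet", config = ck$config, params = params, arch = ck$arch)
}

#' Per-layer summary of a network
#' @param net a \linkS4class{SegNet}.
#' @return data.frame with one row per parameter tensor (name, shape, size).
#' @export
networkSummary <- function(net) {
  data.frame(
    name = names(net@params),
    shape = vapply(net@params, function(p) {
      paste(if (is.null(dim(p$v))) length(p$v) else dim(p$v), collapse = "x")
    }, ""),
    n = vapply(net@params, function(p) length(p$v), 0),
    row.names = NULL
  )
}

# ---- forward pass -----------------------------------------------------

# full forward pass; x1/x2 are H x W matrices in [0,1]; returns the sigmoid
# output node (H x W x 1). tape = NULL for inference.
.segnetForward <- function(net, x1, x2 = NULL, tape = NULL) {
  p <- net@params
  cfg <- net@config
  al <- cfg@lreluAlpha
  gg <- cfg@gnGroups
  eps <- cfg@gnEps
  cps <- cfg@channelsPerStage
  nS <- length(cps)
  m <- cfg@denseMicroBlocks
  dual <- net@arch == "dual"

  conv <- function(x, nm, stride = 1L, k = 3L) {
    agConv(tape, x, p[[paste0(nm, ".w")]], p[[paste0(nm, ".b")]],
           k, k, stride, if (k == 3L) 1L else 0L)
  }
  gn <- function(x, nm) {
    agGroupNorm(tape, x, p[[paste0(nm, ".g")]], p[[paste0(nm, ".s")]],
                gg, eps)
  }
  lr <- function(x) agLRelu(tape, x, al)

  encBlock <- function(x, pfx) {
    h <- lr(gn(conv(x, paste0(pfx, ".c1")), paste0(pfx, ".g1")))
    h <- lr(gn(conv(h, paste0(pfx, ".c2")), paste0(pfx, ".g2")))
    list(out = conv(h, paste0(pfx, ".c3"), stride = 2L), tap = h)
  }

  if (dual) {
    if (is.null(x2)) stop("dual-input network needs both channels")
    ea <- encBlock(agNode(.as3d(x1)), "e1a")
    eb <- encBlock(agNode(.as3d(x2)), "e1b")
    inputTap <- agConcat(tape, list(ea$tap, eb$tap))
    h <- agConcat(tape, list(ea$out, eb$out))
  } else {
    e1 <- encBlock(agNode(.as3d(x1)), "e1a")
    inputTap <- e1$tap
    h <- e1$out
  }

  # dense connectivity: micro-block i sees the concatenation of the block
  # input and all previous micro-block outputs, appends K channels
  for (i in seq_len(m)) {
    pfx <- sprintf("d%d", i)
    z <- lr(gn(h, paste0(pfx, ".g1")))
    z <- conv(z, paste0(pfx, ".c1"), k = 1L)
    z <- lr(gn(z, paste0(pfx, ".g2")))
    z <- conv(z, paste0(pfx, ".c2"))
    h <- agConcat(tape, list(h, z))
  }
  z <- gn(h, "t.g")
  z <- conv(z, "t.c", k = 1L)
  denseTap <- z
  h <- agAvgPool2(tape, z)

  taps <- vector("list", nS - 1L)
  for (i in seq_len(nS - 1L)) {
    e <- encBlock(h, sprintf("e%d", i + 1L))
    taps[[i]] <- e$tap
    h <- e$out
  }

  skips <- c(rev(taps), list(denseTap), list(inputTap))
  for (j in seq_along(skips)) {
    pfx <- sprintf("u%d", j)
    up <- agConvT(tape, h, p[[paste0(pfx, ".up.w")]],
                  p[[paste0(pfx, ".up.b")]])
    sk <- skips[[j]]
    du <- dim(.as3d(up$v))[1:2]
    ds <- dim(.as3d(sk$v))[1:2]
    if (!all(du == ds)) {
      stop(sprintf(
        "skip shape mismatch at decoder %d: upsampled %s vs encoder %s",
        j, paste(du, collapse = "x"), paste(ds, collapse = "x")))
    }
    h <- agConcat(tape, list(up, sk))
    h <- lr(gn(conv(h, paste0(pfx, ".c1")), paste0(pfx, ".g1")))
    h <- lr(gn(conv(h, paste0(pfx, ".c2")), paste0(pfx, ".g2")))
  }
  agSigmoid(tape, conv(h, "f.c", k = 1L))
}

#' Run inference on one slice
#'
#' @param net a \linkS4class{SegNet}.
#' @param x1 channel-1 slice (H x W matrix); for single-sequence networks
#'   the only input.
#' @param x2 channel-2 slice, required for dual-input networks.
#' @return H x W matrix of probabilities in (0, 1).
#' @export
predictSlice <- function(net, x1, x2 = NULL) {
  out <- .segnetForward(net, x1, x2, tape = NULL)
  out$v[, , 1L]
}
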