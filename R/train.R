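#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-4,
#' 200 epochs, batch size 1, per-epoch flip/rescale augmentation, and a
#' soft Dice objective. The Dice smoothing constant avoids 0/0 on slices
#' with empty masks.
#'
#' @param learningRate Adam step size (> 0).
#' @param epochs number of passes over the training slices (>= 1).
#' @param batchSize gradients are accumulated over this many slices per
#'   update (default 1).
#' @param augment enable per-sample flip/rescale augmentation.
#' @param rescaleRange interval from which the rescale factor is drawn.
#' @param rescaleMode \code{"spatial"} (zoom, the default reading of
#'   "re-scaling") or \code{"intensity"} (multiplicative intensity scale).
#' @param flipProb probability of a horizontal (left-right) flip.
#' @param seed drives shuffling, augmentation draws and anything else
#'   stochastic inside \code{\link{trainNetwork}}.
#' @param binarizeThreshold probability threshold used downstream when
#'   binarizing predictions, in (0, 1).
#' @param diceSmooth smoothing constant s of the soft Dice loss.
#' @param beta1,beta2,adamEps Adam moment decay rates and epsilon.
#' @param clipNorm global gradient-norm ceiling applied before each update
#'   (gradients are rescaled when their joint L2 norm exceeds it); guards
#'   small group-normalized networks against variance-spike gradient
#'   explosions. \code{Inf} disables clipping.
#' @return A validated \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 1e-4, epochs = 200L, batchSize = 1L,
                        augment = TRUE, rescaleRange = c(0.9, 1.1),
                        rescaleMode = "spatial", flipProb = 0.5, seed = 1L,
                        binarizeThreshold = 0.5, diceSmooth = 1,
                        beta1 = 0.9, beta2 = 0.999, adamEps = 1e-8,
                        clipNorm = 1) {
  new("TrainConfig",
      learningRate = learningRate, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), augment = isTRUE(augment),
      rescaleRange = as.numeric(rescaleRange), rescaleMode = rescaleMode,
      flipProb = flipProb, seed = as.integer(seed),
      binarizeThreshold = binarizeThreshold, diceSmooth = diceSmooth,
      beta1 = beta1, beta2 = beta2, adamEps = adamEps,
      clipNorm = clipNorm)
}

#' Soft Dice loss
#'
#' \code{1 - (2 sum(p g) + s) / (sum p + sum g + s)}: 0 at perfect overlap
#' (in the limit s -> 0), 1 at disjoint supports.
#'
#' @param p probability image (values in [0, 1]).
#' @param g binary gold mask of the same shape.
#' @param smooth smoothing constant s.
#' @return Scalar in [0, 1].
#' @examples
#' diceLoss(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1), smooth = 0)
#' @export
diceLoss <- function(p, g, smooth = 1) {
  if (!isTRUE(all.equal(dim(p), dim(g)))) {
    stop("probability map and gold mask shapes differ")
  }
  if (!all(g %in% c(0, 1))) stop("gold mask must be binary")
  inter <- sum(p * g)
  1 - (2 * inter + smooth) / (sum(p) + sum(g) + smooth)
}

# resize a slice by factor f (bilinear for images, nearest for masks) and
# pad/crop back to the original shape
.rescaleSlice <- function(img, f, nearest) {
  d <- dim(img)
  nn <- pmax(2L, as.integer(round(d * f)))
  sc <- d / nn
  res <- .cpp_resample2d(img, nn[1], nn[2], sc[1], sc[2],
                         (sc[1] - 1) / 2, (sc[2] - 1) / 2, nearest)
  out <- padCrop(res, d)
  attr(out, "shift") <- NULL
  out
}

#' Apply one augmentation draw to a training sample
#'
#' The geometric parameters are drawn once per sample and applied
#' identically to both channels and the mask; the mask goes through
#' nearest-neighbour resampling and stays binary.
#'
#' @param sample list with \code{x1}, optional \code{x2}, and mask \code{y}
#'   (H x W matrices).
#' @param flip logical: mirror left-right.
#' @param scale rescale factor.
#' @param mode \code{"spatial"} or \code{"intensity"}.
#' @return The augmented sample.
#' @export
augmentSample <- function(sample, flip, scale, mode = "spatial") {
  fl <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (flip) {
    sample$x1 <- fl(sample$x1)
    if (!is.null(sample$x2)) sample$x2 <- fl(sample$x2)
    sample$y <- fl(sample$y)
  }
  if (scale != 1) {
    if (mode == "spatial") {
      sample$x1 <- .rescaleSlice(sample$x1, scale, FALSE)
      if (!is.null(sample$x2)) {
        sample$x2 <- .rescaleSlice(sample$x2, scale, FALSE)
      }
      sample$y <- .rescaleSlice(sample$y, scale, TRUE)
    } else {
      sample$x1 <- sample$x1 * scale
      if (!is.null(sample$x2)) sample$x2 <- sample$x2 * scale
    }
  }
  sample
}

#' Flatten preprocessed studies into per-slice training samples
#'
#' @param studies list of preprocessed \linkS4class{PairedStudy} objects
#'   (shared grid across the three volumes).
#' @param input \code{"dual"}, \code{"t1"} or \code{"t2"}: which channels
#'   the samples carry. Single-sequence samples put the chosen channel in
#'   \code{x1} and leave \code{x2} NULL.
#' @return List of samples (\code{x1}, \code{x2}, \code{y}, \code{patient},
#'   \code{slice}); slices with empty masks are kept.
#' @export
buildSliceDataset <- function(studies, input = c("dual", "t1", "t2")) {
  input <- match.arg(input)
  out <- list()
  for (st in studies) {
    a1 <- volData(t1w(st))
    a2 <- volData(t2w(st))
    g <- volData(gold(st))
    for (k in seq_len(dim(g)[3])) {
      s <- switch(input,
        dual = list(x1 = a1[, , k], x2 = a2[, , k]),
        t1 = list(x1 = a1[, , k], x2 = NULL),
        t2 = list(x1 = a2[, , k], x2 = NULL))
      s$y <- g[, , k]
      s$patient <- patientId(st)
      s$slice <- k
      out[[length(out) + 1L]] <- s
    }
  }
  out
}

#' Train a segmentation network with Adam and the soft Dice loss
#'
#' Runs \code{epochs} passes over the slice dataset with per-sample
#' augmentation, batch-size-1 Adam updates (or gradient accumulation for
#' larger batches) and records the mean loss per epoch. All randomness
#' (shuffling, augmentation) flows from \code{cfg@seed}. The weights of
#' \code{net} are updated in place (parameter nodes are reference objects)
#' and the handle is also returned.
#'
#' @param net a \linkS4class{SegNet}.
#' @param samples slice dataset from \code{\link{buildSliceDataset}}; every
#'   slice must match the network's configured input size.
#' @param cfg a \linkS4class{TrainConfig}.
#' @return List with \code{net} and \code{history} (data.frame of epoch,
#'   mean loss, wall seconds; the seed as an attribute).
#' @export
trainNetwork <- function(net, samples, cfg = trainConfig()) {
  stopifnot(is(net, "SegNet"), is(cfg, "TrainConfig"))
  validObject(cfg)
  if (length(samples) == 0L) stop("training dataset is empty")
  insz <- net@config@inputSize
  for (s in samples) {
    if (!all(dim(s$x1) == insz)) {
      stop(sprintf("sample slice is %s but the network expects %s",
                   paste(dim(s$x1), collapse = "x"),
                   paste(insz, collapse = "x")))
    }
  }
  dual <- net@arch == "dual"
  if (dual && is.null(samples[[1L]]$x2)) {
    stop("dual-input network needs dual-channel samples")
  }

  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  })
  set.seed(cfg@seed)

  pnames <- names(net@params)
  adamM <- lapply(net@params, function(p) p$v * 0)
  adamV <- lapply(net@params, function(p) p$v * 0)
  tStep <- 0L

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        seconds = numeric(0))
  n <- length(samples)
  for (epoch in seq_len(cfg@epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample.int(n)
    epochLoss <- 0
    sinceStep <- 0L
    for (ii in seq_along(ord)) {
      s <- samples[[ord[ii]]]
      if (cfg@augment) {
        s <- augmentSample(
          s, flip = stats::runif(1) < cfg@flipProb,
          scale = stats::runif(1, cfg@rescaleRange[1], cfg@rescaleRange[2]),
          mode = cfg@rescaleMode)
      }
      tape <- agTape()
      out <- .segnetForward(net, s$x1, if (dual) s$x2 else NULL, tape)
      loss <- agDiceLoss(tape, out, s$y, cfg@diceSmooth)
      if (!is.finite(loss$v)) {
        stop(sprintf("non-finite loss at epoch %d", epoch))
      }
      epochLoss <- epochLoss + loss$v
      agBackward(tape, loss)
      sinceStep <- sinceStep + 1L
      if (sinceStep >= cfg@batchSize || ii == n) {
        tStep <- tStep + 1L
        corr1 <- 1 - cfg@beta1^tStep
        corr2 <- 1 - cfg@beta2^tStep
        scale <- if (sinceStep > 1L) 1 / sinceStep else 1
        if (is.finite(cfg@clipNorm)) {
          gnorm <- sqrt(sum(vapply(net@params, function(p) {
            if (is.null(p$g)) 0 else sum(p$g^2)
          }, 0))) * scale
          if (gnorm > cfg@clipNorm) scale <- scale * cfg@clipNorm / gnorm
        }
        for (nm in pnames) {
          p <- net@params[[nm]]
          g <- if (is.null(p$g)) p$v * 0 else p$g * scale
          adamM[[nm]] <- cfg@beta1 * adamM[[nm]] + (1 - cfg@beta1) * g
          adamV[[nm]] <- cfg@beta2 * adamV[[nm]] + (1 - cfg@beta2) * g^2
          p$v <- p$v - cfg@learningRate * (adamM[[nm]] / corr1) /
            (sqrt(adamV[[nm]] / corr2) + cfg@adamEps)
          p$g <- NULL
        }
        sinceStep <- 0L
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = epochLoss / n,
      seconds = proc.time()[["elapsed"]] - t0))
  }
  attr(history, "seed") <- cfg@seed
  list(net = net, history = history)
}

#' Predict the probability volume of one preprocessed study
#'
#' @param net trained \linkS4class{SegNet}.
#' @param study preprocessed \linkS4class{PairedStudy}.
#' @param input which channels the network was trained on.
#' @return A \linkS4class{Volume} of per-voxel probabilities.
#' @export
predictStudy <- function(net, study, input = c("dual", "t1", "t2")) {
  input <- match.arg(input)
  a1 <- volData(t1w(study))
  a2 <- volData(t2w(study))
  d <- dim(a1)
  out <- array(0, d)
  for (k in seq_len(d[3])) {
    out[, , k] <- switch(input,
      dual = predictSlice(net, a1[, , k], a2[, , k]),
      t1 = predictSlice(net, a1[, , k]),
      t2 = predictSlice(net, a2[, , k]))
  }
  volume(out, spacing = spacing(t1w(study)), origin = origin(t1w(study)))
}
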