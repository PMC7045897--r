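#' Min-max normalize a volume to [0, 1]
#'
#' Applies \code{(v - min) / (max - min)} over the whole volume. A constant
#' volume maps to all zeros (declared convention for the degenerate case).
#'
#' @param vol a \linkS4class{Volume}.
#' @return A \linkS4class{Volume} with values in [0, 1].
#' @export
minmaxNormalize <- function(vol) {
  v <- volData(vol)
  rng <- range(v)
  v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else
    array(0, dim(v))
  volume(v, spacing = spacing(vol), origin = origin(vol))
}

#' Halve the in-plane resolution of a volume
#'
#' Reduces rows and columns by 50% (floor division for odd sizes), leaving
#' the slice count unchanged and doubling the in-plane spacing. Images are
#' resampled with linear interpolation; masks must use
#' \code{method = "nearest"} so binarity is preserved. Each output voxel is
#' sampled at the centre of the 2 x 2 input block it replaces.
#'
#' @param vol a \linkS4class{Volume} with in-plane dimensions >= 2.
#' @param method \code{"linear"} (images) or \code{"nearest"} (masks).
#' @return The downsampled \linkS4class{Volume}.
#' @export
downsampleInPlane <- function(vol, method = c("linear", "nearest")) {
  method <- match.arg(method)
  v <- volData(vol)
  d <- dim(v)
  if (d[1] < 2L || d[2] < 2L) {
    stop("in-plane dimensions must be >= 2 to downsample")
  }
  or <- d[1] %/% 2L
  oc <- d[2] %/% 2L
  out <- array(0, c(or, oc, d[3]))
  for (k in seq_len(d[3])) {
    out[, , k] <- .cpp_resample2d(v[, , k], or, oc, 2, 2, 0.5, 0.5,
                                  method == "nearest")
  }
  sp <- spacing(vol)
  volume(out, spacing = c(sp[1] * 2, sp[2] * 2, sp[3]),
         origin = origin(vol) + c(0.5 * sp[1], 0.5 * sp[2], 0))
}

#' Pad and crop a slice image to a target shape
#'
#' Pads with zeros symmetrically where the input is smaller than the target
#' and crops a centered window where it is larger, so that the output is
#' exactly \code{target}. The content shift (output index minus input index)
#' is attached as attribute \code{"shift"} so that masks and images passed
#' through the same call displace identically.
#'
#' @param img a matrix (one slice).
#' @param target integer pair (rows, cols), strictly positive.
#' @return Matrix of dimension \code{target} with a \code{"shift"} attribute.
#' @examples
#' x <- matrix(1, 200, 240)
#' dim(padCrop(x, c(256, 256)))
#' @export
padCrop <- function(img, target) {
  stopifnot(is.matrix(img), length(target) == 2L, all(target >= 1))
  out <- img
  shift <- c(0L, 0L)
  for (axis in 1:2) {
    n <- dim(out)[axis]
    t <- as.integer(target[axis])
    if (n < t) {
      before <- (t - n) %/% 2L
      blk <- dim(out)
      blk[axis] <- t
      res <- matrix(0, blk[1], blk[2])
      if (axis == 1L) res[before + seq_len(n), ] <- out
      else res[, before + seq_len(n)] <- out
      out <- res
      shift[axis] <- before
    } else if (n > t) {
      start <- (n - t) %/% 2L + 1L
      out <- if (axis == 1L) out[start + seq_len(t) - 1L, , drop = FALSE]
             else out[, start + seq_len(t) - 1L, drop = FALSE]
      shift[axis] <- -(start - 1L)
    }
  }
  attr(out, "shift") <- shift
  out
}

# pad/crop every slice of a volume to the target in-plane shape
padCropVolume <- function(vol, target) {
  v <- volData(vol)
  d <- dim(v)
  out <- array(0, c(target[1], target[2], d[3]))
  sh <- c(0L, 0L)
  for (k in seq_len(d[3])) {
    s <- padCrop(v[, , k], target)
    sh <- attr(s, "shift")
    out[, , k] <- s
  }
  sp <- spacing(vol)
  volume(out, spacing = sp,
         origin = origin(vol) - c(sh[1] * sp[1], sh[2] * sp[2], 0))
}

#' Preprocess a dual-sequence study
#'
#' Runs the fixed preprocessing chain: (1) rigid co-registration of channel
#' 1 onto the channel-2 grid by mutual information (see
#' \code{\link{registerVolumes}}); (2) 50% in-plane downsampling of the
#' registered channel 1, channel 2 and gold mask to channel-1-like
#' resolution (linear interpolation for images, nearest-neighbour for the
#' mask); (3) per-volume min-max normalization of the two image channels;
#' (4) zero-padding / centered cropping of every slice to
#' \code{targetSize}. The mask travels through the identical geometric
#' operations as the images, so voxel correspondence is exact and the mask
#' stays binary.
#'
#' @param study a \linkS4class{PairedStudy}.
#' @param regOpts \code{\link{registrationOptions}}.
#' @param targetSize in-plane output shape; 256 x 256 by default.
#' @param register set \code{FALSE} to skip registration (already aligned
#'   inputs); channel 1 is then resampled onto the channel-2 grid under the
#'   identity transform.
#' @param strictMaskInterp if \code{TRUE}, resample the mask linearly and
#'   re-binarize at 0.5 instead of nearest-neighbour.
#' @return A \linkS4class{PairedStudy} on a single shared grid, with the
#'   registration transform attached as attribute \code{"transform"}.
#' @export
preprocessStudy <- function(study, regOpts = registrationOptions(),
                            targetSize = c(256L, 256L), register = TRUE,
                            strictMaskInterp = FALSE) {
  stopifnot(is(study, "PairedStudy"))
  if (register) {
    reg <- registerVolumes(t1w(study), t2w(study), regOpts)
    t1r <- reg$volume
    transform <- reg$transform
  } else {
    t1r <- resampleToGrid(t1w(study), t2w(study))
    transform <- list(model = "identity", translation = c(0, 0, 0))
  }
  t1d <- downsampleInPlane(t1r, "linear")
  t2d <- downsampleInPlane(t2w(study), "linear")
  gd <- if (strictMaskInterp) {
    g <- downsampleInPlane(gold(study), "linear")
    volume(array(as.numeric(volData(g) >= 0.5), dim(volData(g))),
           spacing = spacing(g), origin = origin(g))
  } else {
    downsampleInPlane(gold(study), "nearest")
  }
  t1n <- minmaxNormalize(t1d)
  t2n <- minmaxNormalize(t2d)
  out <- pairedStudy(
    t1w = padCropVolume(t1n, targetSize),
    t2w = padCropVolume(t2n, targetSize),
    gold = padCropVolume(gd, targetSize),
    patientId = patientId(study)
  )
  attr(out, "transform") <- transform
  out
}

#' Resample a volume onto the grid of another under the identity transform
#' @param vol volume to resample.
#' @param ref volume whose grid to adopt.
#' @param method interpolation, linear or nearest.
#' @return A \linkS4class{Volume} on \code{ref}'s grid.
#' @export
resampleToGrid <- function(vol, ref, method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(volData(ref))
  arr <- .cpp_resample3d_affine(
    volData(vol), spacing(vol), origin(vol), d[1], d[2], d[3],
    spacing(ref), origin(ref), diag(3), c(0, 0, 0), volCenter(ref),
    0, method == "nearest")
  volume(arr, spacing = spacing(ref), origin = origin(ref))
}
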