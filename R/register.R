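#' Options for mutual-information registration
#'
#' The inter-sequence alignment is driven by a histogram-based mutual
#' information metric optimized with a (1+1) evolutionary strategy: at each
#' iteration a Gaussian perturbation of the current transform parameters is
#' accepted if it improves the metric, and the search radius grows on
#' success and shrinks on failure.
#'
#' @param initialRadius initial relative search radius of the evolutionary
#'   optimizer (default 0.004).
#' @param maxIterations iteration budget (default 300).
#' @param transformModel \code{"rigid"} (translation + rotation, the
#'   default, appropriate for intra-patient same-session sequences),
#'   \code{"translation"}, or \code{"affine"}.
#' @param interpolation resampling interpolation for the moving image.
#' @param bins histogram bins per intensity axis for the metric.
#' @param growthFactor search-radius growth on an accepted step; the radius
#'   shrinks by \code{growthFactor^-0.25} on rejection.
#' @param epsilon radius below which the search stops early.
#' @param momentsInit initialize the translation from the intensity
#'   centre-of-mass difference of the two volumes (the standard moments
#'   initializer) before the evolutionary search.
#' @param seed seed for the optimizer's perturbations.
#' @return A validated \linkS4class{RegistrationOptions}.
#' @export
registrationOptions <- function(initialRadius = 0.004,
                                maxIterations = 300L,
                                transformModel = "rigid",
                                interpolation = "linear",
                                bins = 32L,
                                growthFactor = 1.05,
                                epsilon = 1.5e-6,
                                momentsInit = TRUE,
                                seed = 1L) {
  new("RegistrationOptions",
      initialRadius = initialRadius, maxIterations = as.integer(maxIterations),
      transformModel = transformModel, interpolation = interpolation,
      bins = as.integer(bins), growthFactor = growthFactor,
      epsilon = epsilon, momentsInit = momentsInit, seed = as.integer(seed))
}

# rotation matrix from extrinsic angles (radians) about the three axes
.rotationMatrix <- function(a) {
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

# parameter vector -> (A, t) for the chosen model
.thetaToTransform <- function(theta, model) {
  if (model == "translation") {
    list(A = diag(3), t = theta)
  } else if (model == "rigid") {
    list(A = .rotationMatrix(theta[4:6]), t = theta[1:3])
  } else {
    list(A = diag(3) + matrix(theta[4:12], 3, 3), t = theta[1:3])
  }
}

.comPhysical <- function(vol) {
  v <- volData(vol)
  v <- v - min(v)
  s <- sum(v)
  if (s <= 0) return(volCenter(vol))
  d <- dim(v)
  w1 <- apply(v, 1, sum); w2 <- apply(v, 2, sum); w3 <- apply(v, 3, sum)
  idx <- c(sum(w1 * (seq_len(d[1]) - 1)), sum(w2 * (seq_len(d[2]) - 1)),
           sum(w3 * (seq_len(d[3]) - 1))) / s
  origin(vol) + idx * spacing(vol)
}

#' Register one volume onto another by mutual information
#'
#' Resamples \code{moving} into \code{fixed}'s grid under the transform
#' that maximizes the mutual information between the two intensity
#' distributions, found by a (1+1) evolutionary strategy (optionally
#' initialized at the centre-of-mass alignment). The transform maps fixed
#' physical positions \code{p} to moving positions
#' \code{q = A (p - c) + c + t} about the fixed volume centre \code{c}; the
#' reported \code{translation} is the content displacement correction
#' \code{-t}, i.e. a moving image whose content was shifted by \code{+d}
#' millimetres yields \code{translation} close to \code{-d}.
#'
#' @param moving,fixed \linkS4class{Volume} objects with overlapping
#'   physical extents.
#' @param opts \code{\link{registrationOptions}}.
#' @return List with \code{volume} (moving resampled on the fixed grid),
#'   \code{transform} (model, parameter vector, matrix \code{A}, pull-back
#'   \code{t}, content \code{translation}), and the negated mutual
#'   information \code{metricInitial} / \code{metricFinal} (lower is
#'   better; the final value never exceeds the identity-transform value).
#' @export
registerVolumes <- function(moving, fixed, opts = registrationOptions()) {
  stopifnot(is(moving, "Volume"), is(fixed, "Volume"))
  validObject(opts)
  loM <- origin(moving); hiM <- loM + (dim(volData(moving)) - 1) * spacing(moving)
  loF <- origin(fixed); hiF <- loF + (dim(volData(fixed)) - 1) * spacing(fixed)
  if (any(hiM < loF) || any(hiF < loM)) {
    stop("volumes have non-overlapping physical extents; cannot register")
  }

  d <- dim(volData(fixed))
  cen <- volCenter(fixed)
  fv <- volData(fixed)
  nearest <- opts@interpolation == "nearest"

  # negated mutual information over the voxels where the transformed moving
  # image is defined; transforms that leave less than half of the fixed
  # grid covered are rejected outright, otherwise shrinking the overlap
  # would be rewarded with spuriously high information
  metric <- function(theta) {
    tr <- .thetaToTransform(theta, opts@transformModel)
    mv <- .cpp_resample3d_affine(
      volData(moving), spacing(moving), origin(moving), d[1], d[2], d[3],
      spacing(fixed), origin(fixed), tr$A, tr$t, cen, NaN, nearest)
    frac <- 1 - mean(is.nan(mv))
    if (frac < 0.5) return(1 + (0.5 - frac))
    -.cpp_mutual_information(fv, mv, opts@bins)
  }

  nPar <- switch(opts@transformModel, translation = 3L, rigid = 6L,
                 affine = 12L)
  theta0 <- numeric(nPar)
  if (opts@momentsInit) {
    theta0[1:3] <- .comPhysical(moving) - .comPhysical(fixed)
  }

  # parameter scales: search radius is relative; translations move on the
  # scale of tens of mm, rotations / affine terms on ~0.1 rad or 10%
  scales <- c(rep(100, 3), rep(5, nPar - 3L))[seq_len(nPar)]

  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  })
  set.seed(opts@seed)

  mIdentity <- metric(numeric(nPar))
  best <- theta0
  mBest <- metric(theta0)
  radius <- opts@initialRadius
  shrink <- opts@growthFactor^(-0.25)
  for (i in seq_len(opts@maxIterations)) {
    if (radius < opts@epsilon) break
    cand <- best + stats::rnorm(nPar, 0, radius * scales)
    mc <- metric(cand)
    if (mc < mBest) {
      best <- cand
      mBest <- mc
      radius <- radius * opts@growthFactor
    } else {
      radius <- radius * shrink
    }
  }
  if (!is.finite(mBest) || mBest > mIdentity) {
    # never return a transform worse than doing nothing
    best <- numeric(nPar)
    mBest <- mIdentity
  }

  tr <- .thetaToTransform(best, opts@transformModel)
  arr <- .cpp_resample3d_affine(
    volData(moving), spacing(moving), origin(moving), d[1], d[2], d[3],
    spacing(fixed), origin(fixed), tr$A, tr$t, cen, 0, nearest)
  list(
    volume = volume(arr, spacing = spacing(fixed), origin = origin(fixed)),
    transform = list(model = opts@transformModel, parameters = best,
                     A = tr$A, t = tr$t, translation = -tr$t[1:3]),
    metricInitial = mIdentity,
    metricFinal = mBest
  )
}
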