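#' Volume: a 3D scalar image with physical geometry
#'
#' The carrier of all image data through the pipeline. Voxel values live in
#' a 3D array indexed (row, column, slice); \code{spacing} gives the voxel
#' edge lengths in millimetres along those axes and \code{origin} the
#' physical position of the centre of voxel (1, 1, 1).
#'
#' @slot values 3D numeric array.
#' @slot spacing numeric triple, mm, strictly positive.
#' @slot origin numeric triple, mm.
#' @export
setClass("Volume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("Volume", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array")
  if (any(dim(v) < 1L)) return("grid must be non-empty")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
    return("spacing must be three strictly positive finite numbers")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin))) {
    return("origin must be three finite numbers")
  }
  TRUE
})

#' PairedStudy: one patient's dual-sequence study
#'
#' Holds the two MRI sequences of one patient (channel 1, T1-weighted;
#' channel 2, T2-weighted) and the binary gold-standard lesion mask drawn
#' on the channel-2 geometry (value 1 inside the lesion, 0 elsewhere).
#' Before preprocessing the three volumes may sit on different grids; after
#' \code{\link{preprocessStudy}} they share shape and spacing.
#'
#' @slot t1w,t2w,gold \linkS4class{Volume} objects.
#' @slot patientId character scalar.
#' @aliases t1w t2w gold patientId
#' @export
setClass("PairedStudy",
  representation(t1w = "Volume", t2w = "Volume", gold = "Volume",
                 patientId = "character")
)

setValidity("PairedStudy", function(object) {
  g <- object@gold@values
  if (!all(g %in% c(0, 1))) {
    return("gold mask must contain only values 0 and 1")
  }
  if (length(object@patientId) != 1L || is.na(object@patientId)) {
    return("patientId must be a single non-missing string")
  }
  TRUE
})

#' PhantomConfig: parameters of the synthetic dual-sequence phantom
#'
#' See \code{\link{phantomConfig}} for the constructor and the meaning and
#' defaults of each field.
#'
#' @export
setClass("PhantomConfig",
  representation(
    gridShape = "integer", spacingCh1 = "numeric", spacingCh2 = "numeric",
    nLesions = "integer", lesionRadiusRange = "numeric",
    t1HypoFraction = "numeric", confuserCount = "integer",
    confuserRadiusRange = "numeric", misregOffset = "numeric",
    noiseSd = "numeric", backgroundLevel = "numeric",
    lesionLevelCh1 = "numeric", lesionLevelCh2 = "numeric",
    confuserLevel = "numeric", airLevel = "numeric",
    headRadiusFrac = "numeric", seed = "integer"
  )
)

setValidity("PhantomConfig", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L)) {
    return("gridShape must be three positive integers (rows, cols, slices)")
  }
  for (nm in c("spacingCh1", "spacingCh2")) {
    sp <- slot(object, nm)
    if (length(sp) != 3L || any(sp <= 0)) {
      return(sprintf("%s entries must be strictly positive", nm))
    }
  }
  rr <- object@lesionRadiusRange
  if (length(rr) != 2L || any(rr <= 0) || rr[1] > rr[2]) {
    return("lesionRadiusRange must be 0 < lower <= upper")
  }
  cr <- object@confuserRadiusRange
  if (length(cr) != 2L || any(cr <= 0) || cr[1] > cr[2]) {
    return("confuserRadiusRange must be 0 < lower <= upper")
  }
  if (object@t1HypoFraction < 0 || object@t1HypoFraction > 1) {
    return("t1HypoFraction must lie in [0, 1]")
  }
  if (object@nLesions < 0L) return("nLesions must be >= 0")
  if (object@confuserCount < 0L) return("confuserCount must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (length(object@misregOffset) != 3L) {
    return("misregOffset must be a mm triple")
  }
  hf <- object@headRadiusFrac
  if (length(hf) != 3L || any(hf <= 0) || any(hf > 0.5)) {
    return("headRadiusFrac must be three fractions in (0, 0.5]")
  }
  TRUE
})

#' RegistrationOptions: settings of the mutual-information registration
#'
#' See \code{\link{registrationOptions}}.
#' @export
setClass("RegistrationOptions",
  representation(
    initialRadius = "numeric", maxIterations = "integer",
    transformModel = "character", interpolation = "character",
    bins = "integer", growthFactor = "numeric", epsilon = "numeric",
    momentsInit = "logical", seed = "integer"
  )
)

setValidity("RegistrationOptions", function(object) {
  if (object@initialRadius <= 0) return("initialRadius must be > 0")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (!object@transformModel %in% c("rigid", "affine", "translation")) {
    return("transformModel must be 'rigid', 'affine' or 'translation'")
  }
  if (!object@interpolation %in% c("linear", "nearest")) {
    return("interpolation must be 'linear' or 'nearest'")
  }
  if (object@bins < 4L) return("bins must be >= 4")
  TRUE
})

#' SegNetConfig: architectural hyperparameters of the segmentation network
#'
#' See \code{\link{segNetConfig}} for field semantics and defaults.
#' @export
setClass("SegNetConfig",
  representation(
    inputSize = "integer", channelsPerStage = "integer",
    growthRate = "integer", denseMicroBlocks = "integer",
    bottleneckFactor = "integer", gnGroups = "integer",
    lreluAlpha = "numeric", dualInput = "logical", gnEps = "numeric",
    initSeed = "integer"
  )
)

setValidity("SegNetConfig", function(object) {
  a <- object@lreluAlpha
  if (length(a) != 1L || a <= 0 || a >= 1) {
    return("lreluAlpha must lie strictly between 0 and 1")
  }
  if (length(object@channelsPerStage) < 1L ||
      any(object@channelsPerStage < 1L)) {
    return("channelsPerStage must be a non-empty positive integer vector")
  }
  g <- object@gnGroups
  if (g < 1L) return("gnGroups must be >= 1")
  widths <- .segnetGnWidths(object)
  bad <- widths[widths %% g != 0L]
  if (length(bad)) {
    return(sprintf(
      "all normalized channel widths must be divisible by gnGroups=%d (got %s)",
      g, paste(unique(bad), collapse = ", ")))
  }
  nDown <- length(object@channelsPerStage) + 1L
  if (any(object@inputSize %% (2L^nDown) != 0L)) {
    return(sprintf("inputSize must be divisible by 2^%d", nDown))
  }
  if (object@denseMicroBlocks < 0L) return("denseMicroBlocks must be >= 0")
  TRUE
})

#' SegNet: an instantiated segmentation network
#'
#' Opaque handle produced by \code{\link{buildDualNet}} or
#' \code{\link{buildSingleNet}}: the weight tensors, the configuration they
#' were built from, and the architecture label.
#'
#' @slot config the \linkS4class{SegNetConfig} used to build the network.
#' @slot params named list of parameter nodes (weights, biases, norm scales).
#' @slot arch \code{"dual"} or \code{"single"}.
#' @export
setClass("SegNet",
  representation(config = "SegNetConfig", params = "list", arch = "character")
)

#' TrainConfig: optimization settings
#'
#' See \code{\link{trainConfig}}.
#' @export
setClass("TrainConfig",
  representation(
    learningRate = "numeric", epochs = "integer", batchSize = "integer",
    augment = "logical", rescaleRange = "numeric", rescaleMode = "character",
    flipProb = "numeric", seed = "integer", binarizeThreshold = "numeric",
    diceSmooth = "numeric", beta1 = "numeric", beta2 = "numeric",
    adamEps = "numeric", clipNorm = "numeric"
  )
)

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  rr <- object@rescaleRange
  if (length(rr) != 2L || any(rr <= 0) || rr[1] > rr[2]) {
    return("rescaleRange must be 0 < lower <= upper")
  }
  bt <- object@binarizeThreshold
  if (bt <= 0 || bt >= 1) return("binarizeThreshold must lie in (0, 1)")
  if (!object@rescaleMode %in% c("spatial", "intensity")) {
    return("rescaleMode must be 'spatial' or 'intensity'")
  }
  if (object@diceSmooth < 0) return("diceSmooth must be >= 0")
  if (length(object@clipNorm) != 1L || object@clipNorm <= 0) {
    return("clipNorm must be a positive scalar (Inf disables clipping)")
  }
  TRUE
})

#' LabeledComponents: a 3D connected-component labeling
#'
#' @slot labels integer 3D array; 0 background, k for component k.
#' @slot count number of components (labels are contiguous 1..count).
#' @slot sliceExtent for each component, the number of distinct axial slice
#'   indices its voxels occupy.
#' @aliases componentCount sliceExtent
#' @export
setClass("LabeledComponents",
  representation(labels = "array", count = "integer", sliceExtent = "integer")
)

setValidity("LabeledComponents", function(object) {
  if (object@count != length(object@sliceExtent)) {
    return("sliceExtent must have one entry per component")
  }
  if (object@count > 0L && any(object@sliceExtent < 1L)) {
    return("every component must occupy at least one slice")
  }
  TRUE
})

#' ConfusionCounts: voxelwise segmentation tallies
#'
#' True positive, false positive, false negative and true negative voxel
#' counts from comparing a binary prediction to a binary gold mask; all
#' three evaluation metrics derive from these.
#'
#' @slot tp,fp,fn,tn non-negative voxel counts.
#' @aliases counts
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", fn = "numeric",
                 tn = "numeric")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(v < 0) || any(v != round(v))) {
    return("tp/fp/fn/tn must be non-negative integers")
  }
  TRUE
})
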