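#' Binarize a probability volume
#'
#' Voxels with probability greater than or equal to the threshold map to 1
#' (ties are foreground by convention), all others to 0.
#'
#' @param vol probability \linkS4class{Volume} (or array).
#' @param threshold in (0, 1); default 0.5.
#' @return Binary \linkS4class{Volume} (or array, matching the input type).
#' @export
binarize <- function(vol, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  if (is(vol, "Volume")) {
    volume(array(as.numeric(volData(vol) >= threshold), dim(volData(vol))),
           spacing = spacing(vol), origin = origin(vol))
  } else {
    array(as.numeric(vol >= threshold), dim(vol))
  }
}

#' Label the 3D connected components of a binary mask
#'
#' Voxels belong to the same component iff they are mutually reachable
#' under the chosen 3D adjacency (6: faces; 18: faces + edges; 26: full
#' neighbourhood, the default).
#'
#' @param mask binary \linkS4class{Volume} or 3D array.
#' @param connectivity 6, 18 or 26.
#' @return A \linkS4class{LabeledComponents}: the integer label volume
#'   (0 = background, k = component k, labels contiguous), the component
#'   count, and each component's axial slice extent.
#' @export
labelComponents3D <- function(mask, connectivity = 26L) {
  arr <- if (is(mask, "Volume")) volData(mask) else mask
  if (!all(arr %in% c(0, 1))) stop("mask must be binary")
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26")
  }
  d <- dim(arr)
  lab <- .cpp_label_components_3d(as.integer(arr), d[1], d[2], d[3],
                                  as.integer(connectivity))
  cnt <- max(lab)
  ext <- integer(cnt)
  if (cnt > 0L) {
    sliceOf <- rep(seq_len(d[3]), each = d[1] * d[2])
    fg <- lab > 0L
    ext <- vapply(split(sliceOf[fg], lab[fg]),
                  function(s) length(unique(s)), 0L)
    ext <- as.integer(ext[order(as.integer(names(ext)))])
  }
  new("LabeledComponents", labels = array(lab, d), count = as.integer(cnt),
      sliceExtent = ext)
}

#' @describeIn labelComponents3D number of components
#' @export
setMethod("componentCount", "LabeledComponents", function(x) x@count)

#' @describeIn labelComponents3D per-component axial slice extent
#' @export
setMethod("sliceExtent", "LabeledComponents", function(x) x@sliceExtent)

setMethod("show", "LabeledComponents", function(object) {
  cat(sprintf("LabeledComponents: %d components; slice extents: %s\n",
              object@count,
              paste(object@sliceExtent, collapse = ", ")))
})

#' Remove components confined to a single axial slice
#'
#' Deletes every connected component whose voxels all lie within one axial
#' slice index (isolated in-plane false positives of a 2D network);
#' components spanning two or more slices are retained voxel-identically.
#'
#' @param labeled a \linkS4class{LabeledComponents}.
#' @return Binary 3D array of the surviving voxels.
#' @export
removeSingleSliceComponents <- function(labeled) {
  stopifnot(is(labeled, "LabeledComponents"))
  keep <- which(labeled@sliceExtent >= 2L)
  out <- array(0, dim(labeled@labels))
  if (length(keep)) out[labeled@labels %in% keep] <- 1
  out
}

#' Full post-processing of a probability volume
#'
#' Binarize at \code{threshold}, label the 3D connected components, and
#' drop single-slice components. Never adds voxels and is idempotent.
#'
#' @param probVol probability \linkS4class{Volume}.
#' @param threshold binarization threshold.
#' @param connectivity component adjacency (default 26).
#' @return Binary \linkS4class{Volume}.
#' @export
postprocessPrediction <- function(probVol, threshold = 0.5,
                                  connectivity = 26L) {
  b <- binarize(probVol, threshold)
  lab <- labelComponents3D(b, connectivity)
  arr <- removeSingleSliceComponents(lab)
  volume(arr, spacing = spacing(b), origin = origin(b))
}
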