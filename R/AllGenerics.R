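#' @import methods
NULL

#' Voxel spacing of an image object
#'
#' @param x a \linkS4class{Volume} or other spatially referenced object.
#' @return Numeric triple of voxel edge lengths in millimetres, ordered as
#'   the array dimensions (rows, columns, slices).
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Physical origin (mm position of the first voxel centre)
#' @param x a \linkS4class{Volume}.
#' @return Numeric triple in millimetres.
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Raw voxel array of an image object
#' @param x a \linkS4class{Volume}.
#' @return The 3D numeric array.
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname PairedStudy-class
#' @param x a \linkS4class{PairedStudy}.
#' @export
setGeneric("t1w", function(x) standardGeneric("t1w"))

#' @rdname PairedStudy-class
#' @export
setGeneric("t2w", function(x) standardGeneric("t2w"))

#' @rdname PairedStudy-class
#' @export
setGeneric("gold", function(x) standardGeneric("gold"))

#' @rdname PairedStudy-class
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' Number of trainable parameters of a network handle
#' @param x a \linkS4class{SegNet}.
#' @return Integer-valued scalar.
#' @export
setGeneric("paramCount", function(x) standardGeneric("paramCount"))

#' @rdname LabeledComponents-class
#' @param x a \linkS4class{LabeledComponents}.
#' @export
setGeneric("componentCount", function(x) standardGeneric("componentCount"))

#' @rdname LabeledComponents-class
#' @export
setGeneric("sliceExtent", function(x) standardGeneric("sliceExtent"))

#' @rdname ConfusionCounts-class
#' @param x a \linkS4class{ConfusionCounts}.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
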