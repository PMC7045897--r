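#' Create a Volume
#'
#' @param values 3D numeric array (rows, columns, slices).
#' @param spacing voxel size in mm along the three array axes.
#' @param origin physical position (mm) of the centre of voxel (1, 1, 1).
#' @return A \linkS4class{Volume}.
#' @examples
#' v <- volume(array(0, c(4, 4, 2)), spacing = c(1, 1, 4))
#' dim(volData(v))
#' @export
volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  new("Volume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @describeIn volume voxel array accessor
#' @param x a Volume.
#' @export
setMethod("volData", "Volume", function(x) x@values)

#' @describeIn volume spacing accessor
#' @export
setMethod("spacing", "Volume", function(x) x@spacing)

#' @describeIn volume origin accessor
#' @export
setMethod("origin", "Volume", function(x) x@origin)

setMethod("show", "Volume", function(object) {
  d <- dim(object@values)
  cat(sprintf("Volume %d x %d x %d, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              min(object@values), max(object@values)))
})

#' Physical centre of a volume (mm)
#' @param vol a Volume.
#' @return mm triple at the geometric centre of the voxel grid.
#' @keywords internal
volCenter <- function(vol) {
  origin(vol) + spacing(vol) * (dim(volData(vol)) - 1) / 2
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} that keep the \linkS4class{Volume}
#' spacing in the NIfTI pixdim fields.
#'
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @return \code{readVolume} returns a \linkS4class{Volume};
#'   \code{writeVolume} returns \code{path} invisibly.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L) sp <- c(sp, rep(1, 3 - length(sp)))
  volume(arr, spacing = abs(sp[1:3]))
}

#' @rdname readVolume
#' @param vol a Volume to write.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(volData(vol))
  RNifti::pixdim(img) <- spacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# assemble a PairedStudy, used by phantom and IO code
pairedStudy <- function(t1w, t2w, gold, patientId) {
  new("PairedStudy", t1w = t1w, t2w = t2w, gold = gold,
      patientId = patientId)
}

#' @describeIn PairedStudy-class channel-1 (T1-weighted) volume
#' @export
setMethod("t1w", "PairedStudy", function(x) x@t1w)

#' @describeIn PairedStudy-class channel-2 (T2-weighted) volume
#' @export
setMethod("t2w", "PairedStudy", function(x) x@t2w)

#' @describeIn PairedStudy-class binary gold-standard mask
#' @export
setMethod("gold", "PairedStudy", function(x) x@gold)

#' @describeIn PairedStudy-class patient identifier
#' @export
setMethod("patientId", "PairedStudy", function(x) x@patientId)

setMethod("show", "PairedStudy", function(object) {
  cat(sprintf("PairedStudy '%s'\n", object@patientId))
  cat("  t1w:  "); show(object@t1w)
  cat("  t2w:  "); show(object@t2w)
  cat(sprintf("  gold: %d lesion voxels\n", sum(object@gold@values)))
})

#' Write a study to disk as NIfTI files
#'
#' Writes \code{<id>_t1w.nii.gz}, \code{<id>_t2w.nii.gz} and
#' \code{<id>_gold.nii.gz} into \code{dir} and returns the file paths.
#'
#' @param study a \linkS4class{PairedStudy}.
#' @param dir output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
writeStudy <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- patientId(study)
  paths <- c(
    t1w = file.path(dir, paste0(id, "_t1w.nii.gz")),
    t2w = file.path(dir, paste0(id, "_t2w.nii.gz")),
    gold = file.path(dir, paste0(id, "_gold.nii.gz"))
  )
  writeVolume(t1w(study), paths[["t1w"]])
  writeVolume(t2w(study), paths[["t2w"]])
  writeVolume(gold(study), paths[["gold"]])
  invisible(paths)
}

#' Read a study written by \code{\link{writeStudy}}
#' @param dir directory containing the three NIfTI files.
#' @param id patient identifier (file prefix).
#' @return A \linkS4class{PairedStudy}.
#' @export
readStudy <- function(dir, id) {
  pairedStudy(
    t1w = readVolume(file.path(dir, paste0(id, "_t1w.nii.gz"))),
    t2w = readVolume(file.path(dir, paste0(id, "_t2w.nii.gz"))),
    gold = readVolume(file.path(dir, paste0(id, "_gold.nii.gz"))),
    patientId = id
  )
}
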