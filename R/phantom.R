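#' Configure the synthetic dual-sequence phantom
#'
#' The phantom emulates the statistical structure the segmentation pipeline
#' assumes about a dual-sequence head MRI study: a channel-2 (T2-weighted)
#' acquisition at fine in-plane resolution, a channel-1 (T1-weighted)
#' acquisition of the same anatomy at coarser in-plane resolution with a
#' small residual misalignment, 4 mm slices, ellipsoidal lesions that are
#' hyperintense on channel 2 but partially hypointense on channel 1, bright
#' non-lesion confuser blobs on channel 2 only, and additive Gaussian noise.
#' The gold-standard mask marks exactly the lesion voxels on the channel-2
#' grid, mirroring masks drawn on the T2-weighted series.
#'
#' @param gridShape integer triple (rows, cols, slices) of the channel-2
#'   grid. Default \code{c(128, 128, 32)}, a testing-scale grid; full
#'   256 x 256 acquisitions are supported by passing larger values.
#' @param spacingCh1,spacingCh2 voxel spacing in mm. Defaults mirror typical
#'   clinical head protocols: 0.93 x 0.93 x 4 mm for channel 1 and
#'   0.48 x 0.48 x 4 mm for channel 2.
#' @param nLesions number of lesions (>= 0).
#' @param lesionRadiusRange mm interval from which each per-axis ellipsoid
#'   radius is drawn uniformly.
#' @param t1HypoFraction fraction in [0, 1] of each lesion's volume rendered
#'   at background intensity on channel 1 (the part of the lesion that a
#'   T1-weighted image fails to show).
#' @param confuserCount number of bright non-lesion blobs added to channel 2
#'   (normal tissue that looks lesion-like on T2 only).
#' @param confuserRadiusRange mm interval for confuser radii.
#' @param misregOffset mm triple by which channel-1 content is displaced
#'   relative to channel 2 (the residual inter-sequence misalignment that
#'   registration must undo).
#' @param noiseSd standard deviation of the additive Gaussian noise, in the
#'   same arbitrary intensity units as the level parameters.
#' @param backgroundLevel,lesionLevelCh1,lesionLevelCh2,confuserLevel tissue
#'   intensity levels (arbitrary units); \code{backgroundLevel} is the
#'   normal head tissue the lesion sits in.
#' @param airLevel intensity of the air outside the head.
#' @param headRadiusFrac per-axis radii of the head ellipsoid as fractions
#'   of the field of view (in (0, 0.5]); lesions and confusers are placed
#'   inside the head.
#' @param seed integer driving all randomness; identical seeds give
#'   bit-identical studies.
#' @return A validated \linkS4class{PhantomConfig}.
#' @export
phantomConfig <- function(gridShape = c(128L, 128L, 32L),
                          spacingCh1 = c(0.93, 0.93, 4),
                          spacingCh2 = c(0.48, 0.48, 4),
                          nLesions = 1L,
                          lesionRadiusRange = c(6, 12),
                          t1HypoFraction = 0.4,
                          confuserCount = 3L,
                          confuserRadiusRange = c(4, 8),
                          misregOffset = c(2, 1, 0),
                          noiseSd = 0.05,
                          backgroundLevel = 0.35,
                          lesionLevelCh1 = 0.6,
                          lesionLevelCh2 = 0.85,
                          confuserLevel = 0.85,
                          airLevel = 0.02,
                          headRadiusFrac = c(0.42, 0.42, 0.46),
                          seed = 1L) {
  new("PhantomConfig",
      gridShape = as.integer(gridShape), spacingCh1 = as.numeric(spacingCh1),
      spacingCh2 = as.numeric(spacingCh2), nLesions = as.integer(nLesions),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      t1HypoFraction = as.numeric(t1HypoFraction),
      confuserCount = as.integer(confuserCount),
      confuserRadiusRange = as.numeric(confuserRadiusRange),
      misregOffset = as.numeric(misregOffset),
      noiseSd = as.numeric(noiseSd),
      backgroundLevel = as.numeric(backgroundLevel),
      lesionLevelCh1 = as.numeric(lesionLevelCh1),
      lesionLevelCh2 = as.numeric(lesionLevelCh2),
      confuserLevel = as.numeric(confuserLevel),
      airLevel = as.numeric(airLevel),
      headRadiusFrac = as.numeric(headRadiusFrac), seed = as.integer(seed))
}

# voxel-centre coordinates (mm) along one axis of a grid
.axisCoords <- function(n, sp) (seq_len(n) - 1) * sp

# binary array: voxel centre inside the axis-aligned ellipsoid
# centre `cen`, per-axis radii `rad` (both mm), on the grid given by
# dims/spacing, with grid content displaced by `shift` mm.
.ellipsoidMask <- function(dims, sp, cen, rad, shift = c(0, 0, 0)) {
  cx <- .axisCoords(dims[1], sp[1]) - shift[1]
  cy <- .axisCoords(dims[2], sp[2]) - shift[2]
  cz <- .axisCoords(dims[3], sp[3]) - shift[3]
  dx2 <- ((cx - cen[1]) / rad[1])^2
  dy2 <- ((cy - cen[2]) / rad[2])^2
  dz2 <- ((cz - cen[3]) / rad[3])^2
  q <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(q <= 1, dims)
}

# half-space mask u . (x - cen) >= tau on a (possibly shifted) grid
.halfSpaceMask <- function(dims, sp, cen, u, tau, shift = c(0, 0, 0)) {
  cx <- .axisCoords(dims[1], sp[1]) - shift[1] - cen[1]
  cy <- .axisCoords(dims[2], sp[2]) - shift[2] - cen[2]
  cz <- .axisCoords(dims[3], sp[3]) - shift[3] - cen[3]
  s <- outer(outer(u[1] * cx, u[2] * cy, `+`), u[3] * cz, `+`)
  array(s >= tau, dims)
}

# plane offset tau (mm, along unit direction u) cutting the requested
# volume fraction off an ellipsoid with radii `rad`; binary search on the
# unit-ball cap fraction f(t) = (2 - 3t + t^3) / 4 after the affine map
# that sends the ellipsoid to the unit ball.
.hypoCutOffset <- function(u, rad, fraction) {
  v <- u * rad
  s <- sqrt(sum(v^2))
  capFrac <- function(t) (2 - 3 * t + t^3) / 4
  lo <- -1; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (capFrac(mid) > fraction) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) * s
}

#' Generate one synthetic dual-sequence study
#'
#' Places \code{nLesions} axis-aligned ellipsoidal lesions fully inside the
#' field of view, renders them on both channels (channel 1 with a connected
#' hypointense sub-region covering \code{t1HypoFraction} of each lesion's
#' volume), adds confuser blobs to channel 2 only, samples channel 1 on its
#' own coarser grid displaced by \code{misregOffset}, and adds independent
#' Gaussian noise (clipped to non-negative) to each channel. The gold mask
#' marks exactly the lesion voxels of the channel-2 grid.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param id patient identifier string.
#' @return A \linkS4class{PairedStudy}.
#' @examples
#' st <- generateStudy(phantomConfig(gridShape = c(64, 64, 8), seed = 7))
#' sum(volData(gold(st)))
#' @export
generateStudy <- function(config, id = "phantom001") {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  })
  set.seed(config@seed)

  d2 <- config@gridShape
  sp2 <- config@spacingCh2
  ext <- (d2 - 1) * sp2                       # physical extent, mm
  sp1 <- config@spacingCh1
  d1 <- pmax(2L, as.integer(floor(ext / sp1)) + 1L)
  off <- config@misregOffset

  # feasibility: the largest admissible lesion plus the misregistration
  # margin must fit between the volume boundaries
  pad <- sp2  # one voxel of clearance per axis
  if (config@nLesions > 0L) {
    need <- 2 * (config@lesionRadiusRange[2] + abs(off) + pad)
    bad <- which(need > ext)
    if (length(bad)) {
      stop(sprintf(
        "lesion of radius %.3g mm cannot fit along axis %d (extent %.3g mm)",
        config@lesionRadiusRange[2], bad[1], ext[bad[1]]))
    }
  }

  # head: a large tissue ellipsoid centred in the field of view; everything
  # outside it is air
  headCen <- ext / 2
  headRad <- config@headRadiusFrac * ext

  # sample a blob centre so the blob sits inside the head ellipsoid and
  # clear of the volume boundary (with the misregistration margin)
  sampleCentre <- function(rad, margin) {
    for (i in 1:400) {
      cen <- stats::runif(3, headCen - 0.6 * headRad, headCen + 0.6 * headRad)
      if (any(cen < margin) || any(cen > ext - margin)) next
      if (sum(((cen - headCen) / pmax(headRad - rad, 1e-6))^2) <= 0.8) {
        return(cen)
      }
    }
    NULL
  }

  lesions <- vector("list", config@nLesions)
  for (i in seq_len(config@nLesions)) {
    rad <- stats::runif(3, config@lesionRadiusRange[1],
                        config@lesionRadiusRange[2])
    cen <- sampleCentre(rad, rad + abs(off) + pad)
    if (is.null(cen)) {
      stop("could not place a lesion inside the head ellipsoid")
    }
    lesions[[i]] <- list(cen = cen, rad = rad)
  }

  goldArr <- array(FALSE, d2)
  for (les in lesions) {
    goldArr <- goldArr | .ellipsoidMask(d2, sp2, les$cen, les$rad)
  }

  # channel 2: head tissue, lesions, confusers (disjoint from gold)
  head2 <- .ellipsoidMask(d2, sp2, headCen, headRad)
  ch2 <- array(config@airLevel, d2)
  ch2[head2] <- config@backgroundLevel
  ch2[goldArr] <- config@lesionLevelCh2
  conf <- 0L
  tries <- 0L
  while (conf < config@confuserCount && tries < 400L) {
    tries <- tries + 1L
    rad <- stats::runif(3, config@confuserRadiusRange[1],
                        config@confuserRadiusRange[2])
    cen <- sampleCentre(rad, rad + pad)
    if (is.null(cen)) next
    clear <- all(vapply(lesions, function(les) {
      sum(((cen - les$cen) / (rad + les$rad))^2) > 1.4
    }, TRUE))
    if (!clear) next
    m <- .ellipsoidMask(d2, sp2, cen, rad)
    if (any(m & goldArr)) next
    ch2[m] <- config@confuserLevel
    conf <- conf + 1L
  }
  if (conf < config@confuserCount) {
    stop("could not place the requested confusers disjoint from the lesions")
  }

  # channel 1 on its own grid, content displaced by misregOffset: head and
  # lesion at their channel-1 levels, a hypointense cut through each
  # lesion, no confusers
  head1 <- .ellipsoidMask(d1, sp1, headCen, headRad, shift = off)
  ch1 <- array(config@airLevel, d1)
  ch1[head1] <- config@backgroundLevel
  for (les in lesions) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    lm1 <- .ellipsoidMask(d1, sp1, les$cen, les$rad, shift = off)
    ch1[lm1] <- config@lesionLevelCh1
    if (config@t1HypoFraction > 0) {
      tau <- .hypoCutOffset(u, les$rad, config@t1HypoFraction)
      hm <- .halfSpaceMask(d1, sp1, les$cen, u, tau, shift = off)
      ch1[lm1 & hm] <- config@backgroundLevel
    }
  }

  if (config@noiseSd > 0) {
    ch1 <- pmax(ch1 + stats::rnorm(length(ch1), 0, config@noiseSd), 0)
    ch2 <- pmax(ch2 + stats::rnorm(length(ch2), 0, config@noiseSd), 0)
    dim(ch1) <- d1
    dim(ch2) <- d2
  }

  out <- pairedStudy(
    t1w = volume(ch1, spacing = sp1),
    t2w = volume(ch2, spacing = sp2),
    gold = volume(array(as.numeric(goldArr), d2), spacing = sp2),
    patientId = id
  )
  # ground-truth scene parameters, for geometry oracles and debugging
  attr(out, "lesions") <- lesions
  attr(out, "head") <- list(cen = headCen, rad = headRad)
  out
}

#' Generate a cohort of phantom studies
#'
#' @param n number of patients.
#' @param config base \linkS4class{PhantomConfig}; each patient reuses it
#'   with a per-patient seed derived from \code{seed}.
#' @param seed cohort seed.
#' @return List of \linkS4class{PairedStudy} objects named by patient id.
#' @export
generateCohort <- function(n, config = phantomConfig(), seed = 1L) {
  stopifnot(n >= 1)
  studies <- vector("list", n)
  ids <- sprintf("p%03d", seq_len(n))
  for (i in seq_len(n)) {
    cfg <- config
    cfg@seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    studies[[i]] <- generateStudy(cfg, id = ids[i])
  }
  names(studies) <- ids
  studies
}

#' Write a cohort to disk with a manifest
#'
#' Writes per-patient NIfTI triplets via \code{\link{writeStudy}} plus a
#' \code{manifest.csv} (patient_id, file paths, config hash).
#'
#' @param studies list of \linkS4class{PairedStudy}.
#' @param dir output directory.
#' @param config the generating \linkS4class{PhantomConfig} (hashed into the
#'   manifest for traceability); optional.
#' @return Path of the manifest, invisibly.
#' @export
writeCohort <- function(studies, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(studies, function(st) {
    p <- writeStudy(st, dir)
    data.frame(patient_id = patientId(st), t1w = p[["t1w"]],
               t2w = p[["t2w"]], gold = p[["gold"]],
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest$config_hash <- if (is.null(config)) NA_character_ else
    configHash(config)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
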