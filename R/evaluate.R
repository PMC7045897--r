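#' Voxelwise confusion counts between prediction and gold standard
#'
#' TP = predicted-and-gold, FP = predicted-not-gold, FN = gold-not-
#' predicted, TN = the remainder; the four always sum to the voxel count.
#'
#' @param pred,gold binary \linkS4class{Volume}s or arrays of equal shape.
#' @return A \linkS4class{ConfusionCounts}.
#' @examples
#' p <- array(c(1, 1, 0, 0), c(2, 2, 1))
#' g <- array(c(1, 0, 1, 0), c(2, 2, 1))
#' counts(confusionCounts(p, g))
#' @export
confusionCounts <- function(pred, gold) {
  p <- if (is(pred, "Volume")) volData(pred) else pred
  g <- if (is(gold, "Volume")) volData(gold) else gold
  if (!isTRUE(all.equal(dim(p), dim(g)))) {
    stop("prediction and gold shapes differ")
  }
  if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1))) {
    stop("both masks must be binary")
  }
  tp <- as.numeric(sum(p == 1 & g == 1))
  fp <- as.numeric(sum(p == 1 & g == 0))
  fn <- as.numeric(sum(p == 0 & g == 1))
  new("ConfusionCounts", tp = tp, fp = fp, fn = fn,
      tn = length(p) - tp - fp - fn)
}

#' @describeIn confusionCounts named vector (tp, fp, fn, tn)
#' @param x a ConfusionCounts.
#' @export
setMethod("counts", "ConfusionCounts", function(x) {
  c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn)
})

setMethod("show", "ConfusionCounts", function(object) {
  print(counts(object))
})

#' Dice similarity coefficient
#'
#' \code{2 TP / (FP + 2 TP + FN)}, the overlap between segmentation and
#' gold standard. When both masks are empty (2TP + FP + FN = 0) the
#' convention is perfect agreement on absence: 1, with a message.
#'
#' @param c a \linkS4class{ConfusionCounts}.
#' @return Scalar in [0, 1].
#' @export
diceCoefficient <- function(c) {
  stopifnot(is(c, "ConfusionCounts"))
  den <- 2 * c@tp + c@fp + c@fn
  if (den == 0) {
    message("both masks empty; Dice = 1 by convention")
    return(1)
  }
  2 * c@tp / den
}

#' Sensitivity (recall over the gold standard)
#'
#' \code{TP / (TP + FN)}; undefined (NA) when the gold mask is empty.
#' @param c a \linkS4class{ConfusionCounts}.
#' @return Scalar in [0, 1], or NA for an empty gold mask.
#' @export
sensitivity <- function(c) {
  stopifnot(is(c, "ConfusionCounts"))
  if (c@tp + c@fn == 0) return(NA_real_)
  c@tp / (c@tp + c@fn)
}

#' Precision (positive predictive value)
#'
#' \code{TP / (TP + FP)}; undefined (NA) when the prediction is empty.
#' @param c a \linkS4class{ConfusionCounts}.
#' @return Scalar in [0, 1], or NA for an empty prediction.
#' @export
precision <- function(c) {
  stopifnot(is(c, "ConfusionCounts"))
  if (c@tp + c@fp == 0) return(NA_real_)
  c@tp / (c@tp + c@fp)
}

#' All three metrics of one prediction
#' @param pred,gold binary volumes/arrays of equal shape.
#' @return Named list: counts, dsc, sensitivity, precision.
#' @export
evaluatePrediction <- function(pred, gold) {
  cc <- confusionCounts(pred, gold)
  list(counts = cc, dsc = diceCoefficient(cc), sensitivity = sensitivity(cc),
       precision = precision(cc))
}

#' Patient-level k-fold cross-validation split
#'
#' Shuffles the patient ids with \code{seed} and deals them into k folds
#' whose test sizes differ by at most one; every patient appears in exactly
#' one test fold and never in both train and test of the same fold.
#'
#' @param ids character vector of patient ids (unique).
#' @param k number of folds, \code{2 <= k <= length(ids)}.
#' @param seed shuffle seed.
#' @return List of k elements, each \code{list(train =, test =)}.
#' @export
kfoldSplit <- function(ids, k, seed = 1L) {
  stopifnot(!anyDuplicated(ids))
  n <- length(ids)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of patients")
  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  })
  set.seed(seed)
  ids <- sample(ids)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  at <- 0L
  lapply(seq_len(k), function(i) {
    test <- ids[at + seq_len(sizes[i])]
    at <<- at + sizes[i]
    list(train = setdiff(ids, test), test = test)
  })
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test comparing two independent samples; exact for small
#' untied samples, tie-corrected normal approximation otherwise (via
#' \code{stats::wilcox.test}). The reported U is the smaller of the two
#' one-sided U statistics (min convention).
#'
#' @param a,b numeric samples (non-empty).
#' @return List with \code{U} and the two-sided \code{p}.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(10, 11, 12))$U  # 0: complete separation
#' @export
mannWhitneyU <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("samples must be non-empty")
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  ua <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ub <- n1 * n2 - ua
  p <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
  list(U = min(ua, ub), p = p)
}

#' Dual- versus single-sequence cross-validated comparison
#'
#' Trains and evaluates the three input variants (channel 1 only, channel 2
#' only, dual) under identical patient-level folds and seeds, computes
#' per-patient 3D Dice/sensitivity/precision on the post-processed
#' predictions, and compares the per-fold mean Dice of the dual model
#' against each single-sequence model with a two-sided Mann-Whitney U test.
#'
#' @param studies list of preprocessed \linkS4class{PairedStudy} objects.
#' @param k number of cross-validation folds.
#' @param seed drives the fold split, weight initialization and training
#'   streams, shared across the three models so the comparison is
#'   controlled.
#' @param netCfg base \linkS4class{SegNetConfig}; the dual flag is set per
#'   model internally.
#' @param trainCfg a \linkS4class{TrainConfig}.
#' @param models subset of \code{c("dual", "t1", "t2")} to run.
#' @param connectivity,threshold post-processing settings.
#' @return List: \code{perPatient} (model, fold, patient, dsc, sensitivity,
#'   precision), \code{perFold} (per-fold means), \code{table1} (mean and
#'   sd per model, over folds and over patients), \code{tests} (Mann-
#'   Whitney comparisons of per-fold Dice against the dual model), and
#'   \code{folds}.
#' @export
runInputComparison <- function(studies, k = 10L, seed = 1L,
                               netCfg = segNetConfig(),
                               trainCfg = trainConfig(),
                               models = c("dual", "t1", "t2"),
                               connectivity = 26L, threshold = NULL) {
  ids <- vapply(studies, patientId, "")
  names(studies) <- ids
  folds <- kfoldSplit(ids, k, seed)
  if (is.null(threshold)) threshold <- trainCfg@binarizeThreshold

  perPatient <- list()
  for (model in models) {
    cfg <- netCfg
    cfg@dualInput <- model == "dual"
    for (f in seq_along(folds)) {
      cfg@initSeed <- as.integer((seed * 131L + f) %% .Machine$integer.max)
      tc <- trainCfg
      tc@seed <- as.integer((seed * 977L + f) %% .Machine$integer.max)
      net <- if (model == "dual") buildDualNet(cfg) else buildSingleNet(cfg)
      trainSet <- buildSliceDataset(studies[folds[[f]]$train], input = model)
      trainNetwork(net, trainSet, tc)
      for (pid in folds[[f]]$test) {
        prob <- predictStudy(net, studies[[pid]], input = model)
        seg <- postprocessPrediction(prob, threshold, connectivity)
        ev <- evaluatePrediction(seg, gold(studies[[pid]]))
        perPatient[[length(perPatient) + 1L]] <- data.frame(
          model = model, fold = f, patient = pid, dsc = ev$dsc,
          sensitivity = ev$sensitivity, precision = ev$precision,
          stringsAsFactors = FALSE)
      }
    }
  }
  perPatient <- do.call(rbind, perPatient)

  aggFold <- stats::aggregate(
    perPatient[c("dsc", "sensitivity", "precision")],
    by = perPatient[c("model", "fold")], FUN = mean, na.rm = TRUE)

  tab <- do.call(rbind, lapply(unique(perPatient$model), function(mo) {
    pf <- aggFold[aggFold$model == mo, ]
    pp <- perPatient[perPatient$model == mo, ]
    data.frame(
      input = mo,
      dsc_mean = mean(pf$dsc), dsc_sd_folds = stats::sd(pf$dsc),
      dsc_sd_patients = stats::sd(pp$dsc),
      dsc_median_patients = stats::median(pp$dsc),
      sensitivity_mean = mean(pf$sensitivity, na.rm = TRUE),
      sensitivity_sd_folds = stats::sd(pf$sensitivity),
      precision_mean = mean(pf$precision, na.rm = TRUE),
      precision_sd_folds = stats::sd(pf$precision),
      stringsAsFactors = FALSE)
  }))

  tests <- NULL
  if ("dual" %in% models && length(models) > 1L) {
    dualFold <- aggFold$dsc[aggFold$model == "dual"]
    tests <- do.call(rbind, lapply(setdiff(models, "dual"), function(mo) {
      mw <- mannWhitneyU(aggFold$dsc[aggFold$model == mo], dualFold)
      data.frame(comparison = paste0(mo, " vs dual"), U = mw$U, p = mw$p,
                 stringsAsFactors = FALSE)
    }))
  }

  list(perPatient = perPatient, perFold = aggFold, table1 = tab,
       tests = tests, folds = folds)
}
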