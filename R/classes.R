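# Central S4 containers: the three-level resolution pyramid, the phantom
# generator's spec and cases, Grad-CAM localization maps, and confusion
# counts. Validity methods encode the invariants the rest of the package
# relies on.

#' PyramidImage: one case at three co-registered resolutions
#'
#' Holds the low / mid / high levels of the sagittal resolution pyramid
#' (nominal 640x320, 1280x640, 2560x1280 pixels). The mid level is exactly
#' twice and the high level exactly four times the low level in each
#' dimension; pixel values live in [0, 1].
#'
#' @slot low,mid,high grayscale matrices (rows x cols = H x W).
#' @slot caseId character identifier.
#' @export
setClass("PyramidImage",
         representation(low = "matrix", mid = "matrix", high = "matrix",
                        caseId = "character"))

setValidity("PyramidImage", function(object) {
  dl <- dim(object@low)
  if (!identical(dim(object@mid), 2L * dl))
    return("mid level must be exactly 2x the low level in each dimension")
  if (!identical(dim(object@high), 4L * dl))
    return("high level must be exactly 4x the low level in each dimension")
  rng <- range(object@low, object@mid, object@high)
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
    return("pixel values must be normalized to [0, 1]")
  TRUE
})

#' @describeIn PyramidImage construct from three level matrices.
#' @param low,mid,high,caseId see slots.
#' @export
pyramidImage <- function(low, mid, high, caseId = "case") {
  new("PyramidImage", low = low, mid = mid, high = high, caseId = caseId)
}

#' @export lowRes midRes highRes caseId
setGeneric("lowRes", function(x) standardGeneric("lowRes"))
setGeneric("midRes", function(x) standardGeneric("midRes"))
setGeneric("highRes", function(x) standardGeneric("highRes"))
setGeneric("caseId", function(x) standardGeneric("caseId"))

#' @rdname PyramidImage-class
#' @param x a `PyramidImage` (or `PhantomCase` where documented).
#' @aliases lowRes midRes highRes caseId
setMethod("lowRes", "PyramidImage", function(x) x@low)
setMethod("midRes", "PyramidImage", function(x) x@mid)
setMethod("highRes", "PyramidImage", function(x) x@high)
setMethod("caseId", "PyramidImage", function(x) x@caseId)

setMethod("show", "PyramidImage", function(object) {
  d <- dim(object@low)
  cat(sprintf("PyramidImage '%s': %dx%d / %dx%d / %dx%d (WxH)\n",
              object@caseId, d[2], d[1], 2 * d[2], 2 * d[1], 4 * d[2], 4 * d[1]))
})

#' PhantomSpec: parameters of the synthetic knee phantom
#'
#' The phantom emulates the sagittal appearance the classifier is trained on:
#' a noisy bright background, one or two dark triangular meniscus horns
#' (bow-tie when both), and for injured cases a thin bright streak inside a
#' horn, with a known pixel mask. Intensities must satisfy
#' `wedgeIntensity < backgroundMean < lesionIntensity`.
#'
#' @slot baseResolution integer `c(W, H)` of the lowest pyramid level; W = 2H.
#' @slot backgroundMean,backgroundSd background intensity mean / texture sd.
#' @slot wedgeCount 1 (single horn) or 2 (anterior + posterior).
#' @slot wedgeIntensity mean intensity of the meniscus (dark).
#' @slot lesionProbability fraction of injured cases.
#' @slot lesionIntensity mean intensity of the lesion streak (bright).
#' @slot lesionThicknessPx streak thickness at base resolution, pixels.
#' @slot seed integer RNG seed; each case draws from its own stream derived
#'   from `(seed, caseIndex)`.
#' @export
setClass("PhantomSpec",
         representation(baseResolution = "integer", backgroundMean = "numeric",
                        backgroundSd = "numeric", wedgeCount = "integer",
                        wedgeIntensity = "numeric", lesionProbability = "numeric",
                        lesionIntensity = "numeric", lesionThicknessPx = "numeric",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@baseResolution) != 2L ||
      object@baseResolution[1] != 2L * object@baseResolution[2])
    return("baseResolution must be c(W, H) with W = 2*H")
  ints <- c(object@wedgeIntensity, object@backgroundMean, object@lesionIntensity)
  if (any(ints < 0 | ints > 1))
    return("intensities must lie in [0, 1]")
  if (!(object@wedgeIntensity < object@backgroundMean &&
        object@backgroundMean < object@lesionIntensity))
    return("need wedgeIntensity < backgroundMean < lesionIntensity (dark meniscus, bright lesion)")
  if (!object@wedgeCount %in% c(1L, 2L)) return("wedgeCount must be 1 or 2")
  if (object@lesionProbability < 0 || object@lesionProbability > 1)
    return("lesionProbability must be in [0, 1]")
  if (object@lesionThicknessPx <= 0) return("lesionThicknessPx must be positive")
  TRUE
})

#' @describeIn PhantomSpec constructor with the package's default study
#'   conditions.
#' @param baseResolution,backgroundMean,backgroundSd,wedgeCount see slots.
#' @param wedgeIntensity,lesionProbability,lesionIntensity see slots.
#' @param lesionThicknessPx,seed see slots.
#' @export
phantomSpec <- function(baseResolution = c(640L, 320L), backgroundMean = 0.5,
                        backgroundSd = 0.06, wedgeCount = 2L,
                        wedgeIntensity = 0.18, lesionProbability = 0.5,
                        lesionIntensity = 0.85, lesionThicknessPx = 2,
                        seed = 1L) {
  new("PhantomSpec", baseResolution = as.integer(baseResolution),
      backgroundMean = backgroundMean, backgroundSd = backgroundSd,
      wedgeCount = as.integer(wedgeCount), wedgeIntensity = wedgeIntensity,
      lesionProbability = lesionProbability, lesionIntensity = lesionIntensity,
      lesionThicknessPx = lesionThicknessPx, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: base %dx%d, %d wedge(s), bg %.2f+-%.2f, ",
                     "wedge %.2f, lesion %.2f (p=%.2f, %.3gpx), seed %d\n"),
              object@baseResolution[1], object@baseResolution[2],
              object@wedgeCount, object@backgroundMean, object@backgroundSd,
              object@wedgeIntensity, object@lesionIntensity,
              object@lesionProbability, object@lesionThicknessPx, object@seed))
})

#' PhantomCase: a generated phantom with label, mask and horn tag
#'
#' @slot pyramid the [PyramidImage-class] for the case.
#' @slot label 0 = normal, 1 = meniscus injury.
#' @slot lesionMask binary matrix at base resolution; all-zero when normal.
#'   Nonempty if and only if `label == 1`, and its foreground lies inside a
#'   wedge.
#' @slot horn `"anterior"` or `"posterior"` for the wedge carrying the
#'   lesion; `"none"` for normal cases.
#' @export
setClass("PhantomCase",
         representation(pyramid = "PyramidImage", label = "integer",
                        lesionMask = "matrix", horn = "character"))

setValidity("PhantomCase", function(object) {
  if (!object@label %in% c(0L, 1L)) return("label must be 0 or 1")
  if (!identical(dim(object@lesionMask), dim(object@pyramid@low)))
    return("lesionMask must be at base resolution")
  has <- any(object@lesionMask > 0)
  if (has != (object@label == 1L))
    return("label = 1 must hold exactly when the lesion mask is nonempty")
  if (object@label == 1L && !object@horn %in% c("anterior", "posterior"))
    return("injured case must carry a horn tag")
  TRUE
})

#' @export caseLabel lesionMask lesionHorn
setGeneric("caseLabel", function(x) standardGeneric("caseLabel"))
setGeneric("lesionMask", function(x) standardGeneric("lesionMask"))
setGeneric("lesionHorn", function(x) standardGeneric("lesionHorn"))

#' @rdname PhantomCase-class
#' @param x a `PhantomCase`.
#' @aliases caseLabel lesionMask lesionHorn
setMethod("caseLabel", "PhantomCase", function(x) x@label)
setMethod("lesionMask", "PhantomCase", function(x) x@lesionMask)
setMethod("lesionHorn", "PhantomCase", function(x) x@horn)
setMethod("caseId", "PhantomCase", function(x) x@pyramid@caseId)
setMethod("lowRes", "PhantomCase", function(x) x@pyramid@low)
setMethod("midRes", "PhantomCase", function(x) x@pyramid@mid)
setMethod("highRes", "PhantomCase", function(x) x@pyramid@high)

setMethod("show", "PhantomCase", function(object) {
  cat(sprintf("PhantomCase '%s': label %d (%s), %d lesion px\n",
              object@pyramid@caseId, object@label, object@horn,
              sum(object@lesionMask > 0)))
})

#' LocalizationMap: non-negative Grad-CAM lesion heat map
#'
#' @slot values map upsampled to the low pyramid level and normalized to
#'   [0, 1] (all-zero maps stay zero).
#' @slot native map at the hooked tap's own spatial resolution (non-negative,
#'   unnormalized).
#' @slot classIndex class the map explains (1 = injury).
#' @export
setClass("LocalizationMap",
         representation(values = "matrix", native = "matrix",
                        classIndex = "integer"))

setValidity("LocalizationMap", function(object) {
  if (any(!is.finite(object@values)) || any(!is.finite(object@native)))
    return("map values must be finite")
  if (any(object@values < 0) || any(object@native < 0))
    return("map values must be non-negative (ReLU)")
  if (any(object@values > 0) && abs(max(object@values) - 1) > 1e-8)
    return("nonzero normalized map must have max 1")
  TRUE
})

#' @export mapValues
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname LocalizationMap-class
#' @param x a `LocalizationMap`.
#' @aliases mapValues
setMethod("mapValues", "LocalizationMap", function(x) x@values)

setMethod("show", "LocalizationMap", function(object) {
  cat(sprintf("LocalizationMap: native %dx%d -> %dx%d, class %d, peak %.3g\n",
              nrow(object@native), ncol(object@native),
              nrow(object@values), ncol(object@values),
              object@classIndex, max(object@values)))
})

#' ConfusionCounts: tp / tn / fp / fn tallies
#'
#' @slot tp,tn,fp,fn non-negative integer counts; their total must be
#'   positive for metric computation.
#' @export
setClass("ConfusionCounts",
         representation(tp = "integer", tn = "integer",
                        fp = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0)) return("counts must be non-negative")
  if (sum(v) == 0) return("total count must be positive")
  TRUE
})

#' @describeIn ConfusionCounts construct from the four counts.
#' @param tp,tn,fp,fn counts.
#' @export
confusionCounts <- function(tp, tn, fp, fn) {
  new("ConfusionCounts", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn))
}

#' @describeIn ConfusionCounts tally counts from 0/1 labels and predictions.
#' @param labels,predicted 0/1 vectors of equal length.
#' @export
countsFromPredictions <- function(labels, predicted) {
  stopifnot(length(labels) == length(predicted))
  confusionCounts(tp = sum(labels == 1 & predicted == 1),
                  tn = sum(labels == 0 & predicted == 0),
                  fp = sum(labels == 0 & predicted == 1),
                  fn = sum(labels == 1 & predicted == 0))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: tp %d, tn %d, fp %d, fn %d (n = %d)\n",
              object@tp, object@tn, object@fp, object@fn,
              object@tp + object@tn + object@fp + object@fn))
})
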