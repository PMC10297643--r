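# Weakly supervised lesion localization by Grad-CAM on the primary tier.
# The hook is the output of the third convolution of a configurable residual
# unit of block_3 (default: unit 1). Channel weights are the spatial mean
# (GAP) of the class-score gradient at the hook; the map is the ReLU of the
# weighted channel sum, upsampled to the low pyramid level and normalized to
# [0, 1] by its maximum (all-zero maps stay zero).

#' Grad-CAM map from a hooked feature map and its gradient
#'
#' Computes `ReLU(sum_i alpha_i * f_i)` with `alpha_i` the spatial mean of
#' the gradient of the selected class score with respect to feature channel
#' `i`.
#'
#' @param features `(H, W, C)` or `(H, W, C, 1)` array: the hooked feature
#'   map of one case.
#' @param gradient array of the same shape: gradient of the class logit with
#'   respect to `features`.
#' @param classIndex class the gradient was taken for (stored, default 1 =
#'   injury).
#' @return a [LocalizationMap-class] at the hook's native resolution (the
#'   `values` slot holds the normalized map, here also native size; use
#'   [localize()] for the upsampled map of a full tier).
#' @export
computeGradCam <- function(features, gradient, classIndex = 1L) {
  features <- asTensor(features); gradient <- asTensor(gradient)
  if (!identical(dim(features), dim(gradient)))
    stop("features and gradient must have identical shape; got ",
         paste(dim(features), collapse = "x"), " vs ",
         paste(dim(gradient), collapse = "x"))
  if (dim(features)[4] != 1L) stop("one case at a time")
  d <- dim(features)
  alpha <- .colSums(gradient, d[1] * d[2], d[3]) / (d[1] * d[2])
  m <- matrix(features, d[1] * d[2], d[3]) %*% alpha
  m <- matrix(pmax(m, 0), d[1], d[2])
  new("LocalizationMap", values = normalizeMap(m), native = m,
      classIndex = as.integer(classIndex))
}

normalizeMap <- function(m) {
  mx <- max(m)
  if (mx > 0) m / mx else m
}

# Gradient of one class logit with respect to the primary tier's hook tap,
# from a cached eval-mode forward pass.
hookGradient <- function(tier, fw, classIndex) {
  dlogits <- matrix(0, 2, 1)
  dlogits[classIndex + 1L, 1] <- 1
  hb <- headBackward(tier, fw$caches$head, dlogits, evalMode = TRUE)
  dy <- hb$dx
  nb <- length(tier$blocks)
  if (nb > tier$hookBlock) {
    r <- blocksBackward(tier, fw$caches$blocks, dy, from = nb,
                        to = tier$hookBlock + 1L, needDx = TRUE,
                        evalMode = TRUE)
    dy <- r$dx
  }
  r <- blocksBackward(tier, fw$caches$blocks, dy, from = tier$hookBlock,
                      to = tier$hookBlock, evalMode = TRUE, stopAtHook = TRUE)
  r$dhook
}

# Recompute the class logits from substituted hook-tap values (eval mode),
# holding everything below the hook fixed. The independent path used by the
# finite-difference validation of the Grad-CAM hook gradient.
forwardFromHook <- function(tier, fw, hookValues) {
  k0 <- tier$hookBlock; u0 <- tier$hookUnit
  unit <- tier$blocks[[k0]][[u0]]
  cache <- fw$caches$blocks[[k0]][[u0]]
  if (is.null(unit$down)) sc <- cache$x
  else {
    z <- convForward(unit$down$conv, cache$x)
    sc <- bnForward(unit$down$bn, z, train = FALSE)$y
  }
  y <- reluForward(hookValues + sc)
  units <- tier$blocks[[k0]]
  for (u in seq_along(units))
    if (u > u0) y <- bottleneckForward(units[[u]], y, train = FALSE)$y
  for (k in seq_along(tier$blocks))
    if (k > k0) y <- blockForward(tier, k, y, train = FALSE)$y
  headForward(tier, y)$logits
}

#' Localize a lesion with Grad-CAM on the primary tier
#'
#' Runs a forward pass, backpropagates the selected class logit to the hook
#' tap, and returns the normalized localization map upsampled to the input
#' image size together with the class scores.
#'
#' @param tier the primary tier (built with an fc head).
#' @param imageLow grayscale matrix at the tier's input size (the low
#'   pyramid level).
#' @param classIndex class to explain; default `NULL` uses the predicted
#'   class (the injury class is used during training-time map generation).
#' @return list with `map` (a [LocalizationMap-class], `values` at image
#'   resolution) and `scores` (logits and probabilities).
#' @export
localize <- function(tier, imageLow, classIndex = NULL) {
  if (is.null(tier$fc)) stop("localize needs a tier with an fc head")
  fw <- tierForward(tier, imageLow, train = FALSE, cache = TRUE)
  if (is.null(fw$hook))
    stop("hook tap not found: block_", tier$hookBlock, " unit ", tier$hookUnit)
  if (is.null(classIndex))
    classIndex <- which.max(fw$scores$probs[, 1]) - 1L
  dhook <- hookGradient(tier, fw, classIndex)
  m <- computeGradCam(fw$hook, dhook, classIndex)
  up <- resizeBilinear(m@native, tier$inH, tier$inW)
  up <- pmax(up, 0)  # guard against tiny negative interpolation overshoot
  list(map = new("LocalizationMap", values = normalizeMap(up),
                 native = m@native, classIndex = as.integer(classIndex)),
       scores = fw$scores)
}
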