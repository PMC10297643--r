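# Lesion attention module (LAM). Fuses the lower-tier feature map, the
# higher-tier feature map and the Grad-CAM localization map into re-weighted
# high-resolution features:
#   feature attention  A = HW * softmax_positions(conv1x1(T_l(low) + T_h(high)))
#   location attention L = 1 + resize(loc)        (identity off-lesion, up to
#                                                  2x on the lesion)
#   weighted high      = T_out(high) * A * L      (broadcast over channels)
# The softmax is taken over all spatial positions of the 1-channel fused map
# and rescaled by HW so the mean weight is 1; without the rescale the product
# would shrink as maps grow and the identity limit would be lost. Location
# attention uses 1 + loc rather than loc alone so that non-lesion features
# are never suppressed below identity.

bcastHW <- function(a, C) a[, , rep(1L, C), , drop = FALSE]

channelSum4 <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1], d[2], 1L, d[4]))
  for (n in seq_len(d[4]))
    y[, , 1L, n] <- rowSums(matrix(x[, , , n], d[1] * d[2], d[3]))
  y
}

#' Initialize a lesion attention module
#'
#' @param lowC,highC channel counts of the lower/higher tier taps at the
#'   fusion point. All transforms map to `highC` channels; the output
#'   transform starts at identity so an untrained LAM passes the high
#'   features through.
#' @return LAM parameter list.
#' @export
lamInit <- function(lowC, highC) {
  tOut <- convInit(1L, 1L, highC, highC, pad = 0L, zero = TRUE)
  for (c in seq_len(highC)) tOut$w[1, 1, c, c] <- 1
  list(tLow = convInit(1L, 1L, lowC, highC, pad = 0L),
       tHigh = convInit(1L, 1L, highC, highC, pad = 0L),
       att = convInit(1L, 1L, highC, 1L, pad = 0L),
       tOut = tOut)
}

spatialSoftmax <- function(z) {
  d <- dim(z)
  hw <- d[1] * d[2]
  a <- z
  for (n in seq_len(d[4])) {
    zz <- z[, , 1L, n]
    e <- exp(zz - max(zz))
    a[, , 1L, n] <- e / sum(e) * hw
  }
  a
}

featureAttentionForward <- function(lam, low, high) {
  low <- asTensor(low); high <- asTensor(high)
  dh <- dim(high)
  lowUp <- if (dim(low)[1] != dh[1] || dim(low)[2] != dh[2])
    .resizeBilinear(low, dh[1], dh[2]) else low
  lT <- convForward(lam$tLow, lowUp)
  hT <- convForward(lam$tHigh, high)
  s <- lT + hT
  z <- convForward(lam$att, s)
  A <- spatialSoftmax(z)
  list(A = A, cache = list(lowUp = lowUp, high = high, s = s, A = A,
                           lowDim = dim(low), resized = !identical(dim(low), dh)))
}

featureAttentionBackward <- function(lam, cache, dA) {
  d <- dim(dA)
  hw <- d[1] * d[2]
  p <- cache$A / hw
  dz <- dA
  for (n in seq_len(d[4])) {
    pp <- p[, , 1L, n]
    dd <- dA[, , 1L, n] * hw
    dz[, , 1L, n] <- pp * (dd - sum(pp * dd))
  }
  ca <- convBackward(lam$att, cache$s, dz, TRUE)
  cl <- convBackward(lam$tLow, cache$lowUp, ca$dx, TRUE)
  ch <- convBackward(lam$tHigh, cache$high, ca$dx, TRUE)
  dlow <- if (cache$resized)
    .resizeBilinearBackward(cl$dx, cache$lowDim[1], cache$lowDim[2]) else cl$dx
  list(dlow = dlow, dhigh = ch$dx,
       grads = list(att = ca$grads, tLow = cl$grads, tHigh = ch$grads))
}

#' Feature-weighted attention map
#'
#' @param lam LAM parameters from [lamInit()].
#' @param low,high feature maps (`(H, W, C, N)` arrays or `(H, W, C)`); `low`
#'   is bilinearly upsampled to `high`'s spatial size when smaller.
#' @return attention array `(H, W, 1, N)`; each sample's values sum to H*W
#'   (mean weight 1).
#' @export
featureAttention <- function(lam, low, high) {
  featureAttentionForward(lam, low, high)$A
}

#' Positioning-weighted attention map
#'
#' Resizes the normalized localization map to the target feature size and
#' shifts it by one, so non-lesion positions keep weight 1 and the lesion
#' peak is amplified up to 2x.
#'
#' @param loc a [LocalizationMap-class] or a matrix in [0, 1].
#' @param targetSize integer `c(H, W)`.
#' @return matrix of weights in [1, 2].
#' @export
locationAttention <- function(loc, targetSize) {
  if (is(loc, "LocalizationMap")) loc <- loc@values
  if (length(targetSize) != 2L || any(targetSize < 1))
    stop("targetSize must be positive c(H, W)")
  1 + resizeBilinear(loc, targetSize[1], targetSize[2])
}

#' Apply the lesion attention module
#'
#' @param lam LAM parameters from [lamInit()].
#' @param low,high feature maps at the fusion point.
#' @param loc localization map(s): a [LocalizationMap-class], a matrix, or a
#'   list with one entry per sample in the batch.
#' @param train keep caches for backpropagation.
#' @return an `AttentionBundle` list: `featureAttention` (H, W, 1, N),
#'   `locationAttention` (H, W, 1, N), `weightedHigh` (same shape as `high`),
#'   and `cache` when `train = TRUE`.
#' @export
applyLam <- function(lam, low, high, loc, train = FALSE) {
  low <- asTensor(low); high <- asTensor(high)
  dh <- dim(high)
  fa <- featureAttentionForward(lam, low, high)
  if (!is.list(loc)) loc <- list(loc)
  if (length(loc) != dh[4])
    stop("need one localization map per sample: got ", length(loc),
         " for batch of ", dh[4])
  L <- array(0, c(dh[1], dh[2], 1L, dh[4]))
  for (n in seq_len(dh[4]))
    L[, , 1L, n] <- locationAttention(loc[[n]], c(dh[1], dh[2]))
  hT <- convForward(lam$tOut, high)
  AB <- bcastHW(fa$A, dh[3])
  LB <- bcastHW(L, dh[3])
  wh <- hT * AB * LB
  bundle <- list(featureAttention = fa$A, locationAttention = L,
                 weightedHigh = wh,
                 cache = if (train) list(fa = fa$cache, hT = hT, L = L,
                                         high = high))
  class(bundle) <- "AttentionBundle"
  bundle
}

lamBackward <- function(lam, bundle, dwh) {
  cache <- bundle$cache
  dh <- dim(dwh)
  AB <- bcastHW(bundle$featureAttention, dh[3])
  LB <- bcastHW(cache$L, dh[3])
  dhT <- dwh * AB * LB
  dA <- channelSum4(dwh * cache$hT * LB)
  co <- convBackward(lam$tOut, cache$high, dhT, TRUE)
  fb <- featureAttentionBackward(lam, cache$fa, dA)
  list(dlow = fb$dlow, dhigh = co$dx + fb$dhigh,
       grads = c(fb$grads, list(tOut = co$grads)))
}

#' @export
print.AttentionBundle <- function(x, ...) {
  d <- dim(x$weightedHigh)
  cat(sprintf("AttentionBundle: weighted high %dx%dx%d (batch %d), attention mean %.3f, location range [%.2f, %.2f]\n",
              d[1], d[2], d[3], d[4], mean(x$featureAttention),
              min(x$locationAttention), max(x$locationAttention)))
  invisible(x)
}
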