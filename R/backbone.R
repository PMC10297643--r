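# Residual-network tiers. Three tiers share the ResNet50 vocabulary:
#   conv_1: 7x7, 64, stride 2, followed by 3x3 max-pool stride 2
#   conv_2: 3x3, 64, stride 2 (tertiary tier only; halves the map so that the
#           secondary and tertiary block_2 taps coincide)
#   block_k: bottleneck residual units with channel triplets
#            (64,64,256), (128,128,512), (256,256,1024), (512,512,2048)
#   fc:     global average pool -> 2-unit linear -> softmax
# The primary tier runs {conv_1, block_1..4, fc} on the low-resolution image,
# the secondary {conv_1, block_1, block_2} on the mid level, the tertiary
# {conv_1, conv_2, block_1..4, fc} on the high level. A width multiplier and
# per-block repeat counts define the "tiny" preset used for desk-scale runs.

BLOCK_MID <- c(64L, 128L, 256L, 512L)
BLOCK_OUT <- c(256L, 512L, 1024L, 2048L)

scaleChannels <- function(c, wm) pmax(1L, as.integer(round(c * wm)))

halveDim <- function(n) as.integer(ceiling(n / 2))

bottleneckInit <- function(cin, mid, cout, stride) {
  down <- if (stride != 1L || cin != cout)
    list(conv = convInit(1L, 1L, cin, cout, stride = stride, pad = 0L),
         bn = bnInit(cout))
  list(conv1 = convInit(1L, 1L, cin, mid, pad = 0L), bn1 = bnInit(mid),
       conv2 = convInit(3L, 3L, mid, mid, stride = stride), bn2 = bnInit(mid),
       conv3 = convInit(1L, 1L, mid, cout, pad = 0L), bn3 = bnInit(cout),
       down = down)
}

bottleneckForward <- function(unit, x, train, keepHook = FALSE) {
  z <- convForward(unit$conv1, x)
  f1 <- bnForward(unit$bn1, z, train); unit$bn1 <- f1$layer
  a1 <- reluForward(f1$y)
  z <- convForward(unit$conv2, a1)
  f2 <- bnForward(unit$bn2, z, train); unit$bn2 <- f2$layer
  a2 <- reluForward(f2$y)
  z <- convForward(unit$conv3, a2)
  f3 <- bnForward(unit$bn3, z, train); unit$bn3 <- f3$layer
  if (is.null(unit$down)) {
    sc <- x
    bnDc <- NULL
  } else {
    sc <- convForward(unit$down$conv, x)
    fd <- bnForward(unit$down$bn, sc, train); unit$down$bn <- fd$layer
    sc <- fd$y
    bnDc <- fd$cache
  }
  y <- reluForward(f3$y + sc)
  cache <- list(x = x, a1 = a1, a2 = a2, y = y,
                bn1c = f1$cache, bn2c = f2$cache, bn3c = f3$cache, bnDc = bnDc,
                hook = if (keepHook) f3$y)
  list(y = y, cache = cache, unit = unit)
}

bnBack <- function(layer, cache, dy, evalMode, needGrads = TRUE) {
  if (evalMode || is.null(cache)) {
    istd <- 1 / sqrt(layer$rvar + layer$eps)
    return(list(dx = channelScale(dy, layer$gamma * istd), grads = NULL))
  }
  bnBackward(layer, cache, dy)
}

# Backward through one bottleneck unit. When `toHook` is TRUE the walk stops
# at the output of the third convolution's batch norm and returns that
# gradient (used by Grad-CAM); parameter gradients are skipped in eval mode.
bottleneckBackward <- function(unit, cache, dy, needDx = TRUE,
                               evalMode = FALSE, toHook = FALSE) {
  dpre <- reluBackward(cache$y, dy)
  if (toHook) return(list(dhook = dpre))
  b3 <- bnBack(unit$bn3, cache$bn3c, dpre, evalMode)
  c3 <- convBackward(unit$conv3, cache$a2, b3$dx, TRUE)
  da2 <- reluBackward(cache$a2, c3$dx)
  b2 <- bnBack(unit$bn2, cache$bn2c, da2, evalMode)
  c2 <- convBackward(unit$conv2, cache$a1, b2$dx, TRUE)
  da1 <- reluBackward(cache$a1, c2$dx)
  b1 <- bnBack(unit$bn1, cache$bn1c, da1, evalMode)
  needMain <- needDx || !is.null(unit$down)
  c1 <- convBackward(unit$conv1, cache$x, b1$dx, needDx)
  grads <- NULL
  dGrads <- NULL
  dx <- NULL
  if (is.null(unit$down)) {
    if (needDx) dx <- c1$dx + dpre
  } else {
    bd <- bnBack(unit$down$bn, cache$bnDc, dpre, evalMode)
    cd <- convBackward(unit$down$conv, cache$x, bd$dx, needDx)
    if (needDx) dx <- c1$dx + cd$dx
    if (!evalMode) dGrads <- list(conv = cd$grads, bn = bd$grads)
  }
  if (!evalMode)
    grads <- list(conv1 = c1$grads, bn1 = b1$grads, conv2 = c2$grads,
                  bn2 = b2$grads, conv3 = c3$grads, bn3 = b3$grads,
                  down = dGrads)
  list(dx = dx, grads = grads)
}

#' Build one residual tier of the cascade
#'
#' @param tier `"primary"`, `"secondary"` or `"tertiary"`.
#' @param baseSize `c(W, H)` pixel size of the *low* pyramid level; the tier's
#'   own input is this size for primary, 2x for secondary, 4x for tertiary.
#'   Width must be twice height (2:1 sagittal crop).
#' @param widthMultiplier scales every channel count (1 = full ResNet50
#'   widths; the tiny preset uses 0.25).
#' @param repeats bottleneck unit counts for block_1..block_4
#'   (full scale: 3, 4, 6, 3).
#' @param hookBlock,hookUnit location of the Grad-CAM hook (primary tier):
#'   the output of the third convolution of that unit.
#' @return a tier object (list) with named layers; pass to [tierForward()].
#' @examples
#' tier <- withSeed(1, buildTier("primary", baseSize = c(160, 80),
#'                               widthMultiplier = 0.25, repeats = c(1, 1, 1, 1)))
#' tierTapShapes(tier)
#' @export
buildTier <- function(tier = c("primary", "secondary", "tertiary"),
                      baseSize = c(640L, 320L), widthMultiplier = 1,
                      repeats = c(3L, 4L, 6L, 3L),
                      hookBlock = 3L, hookUnit = 1L) {
  tier <- match.arg(tier)
  if (length(baseSize) != 2L || baseSize[1] != 2L * baseSize[2])
    stop("baseSize must be c(W, H) with W = 2*H, got (",
         paste(baseSize, collapse = ", "), ")")
  if (length(repeats) != 4L || any(repeats < 1L))
    stop("repeats must be four counts >= 1")
  mult <- switch(tier, primary = 1L, secondary = 2L, tertiary = 4L)
  inW <- as.integer(baseSize[1]) * mult
  inH <- as.integer(baseSize[2]) * mult
  stemC <- scaleChannels(64L, widthMultiplier)
  mids <- scaleChannels(BLOCK_MID, widthMultiplier)
  outs <- scaleChannels(BLOCK_OUT, widthMultiplier)
  nBlocks <- if (tier == "secondary") 2L else 4L
  blocks <- vector("list", nBlocks)
  cin <- stemC
  for (k in seq_len(nBlocks)) {
    units <- vector("list", repeats[k])
    for (u in seq_len(repeats[k])) {
      stride <- if (k > 1L && u == 1L) 2L else 1L
      units[[u]] <- bottleneckInit(cin, mids[k], outs[k], stride)
      cin <- outs[k]
    }
    blocks[[k]] <- units
  }
  names(blocks) <- paste0("block_", seq_len(nBlocks))
  obj <- list(tier = tier, inH = inH, inW = inW,
              widthMultiplier = widthMultiplier, repeats = repeats[seq_len(nBlocks)],
              channels = list(stem = stemC, mid = mids, out = outs),
              conv1 = convInit(7L, 7L, 1L, stemC, stride = 2L),
              bn1 = bnInit(stemC),
              conv2 = if (tier == "tertiary") convInit(3L, 3L, stemC, stemC, stride = 2L),
              bn2s = if (tier == "tertiary") bnInit(stemC),
              blocks = blocks,
              fc = if (tier != "secondary") linearInit(outs[nBlocks], 2L, sd = 0.01),
              hookBlock = as.integer(hookBlock), hookUnit = as.integer(hookUnit))
  class(obj) <- "cpcnnTier"
  obj
}

#' Closed-form tap shapes for a tier
#'
#' Computes the `(H, W, C)` shape of every block tap from the stride
#' arithmetic alone (every downsampling stage maps H to ceiling(H/2)).
#'
#' @param tier a tier object from [buildTier()].
#' @return named list of integer `c(H, W, C)` per tap.
#' @export
tierTapShapes <- function(tier) {
  h <- halveDim(halveDim(tier$inH))  # conv_1 + max-pool
  w <- halveDim(halveDim(tier$inW))
  if (tier$tier == "tertiary") { h <- halveDim(h); w <- halveDim(w) }  # conv_2
  shapes <- list()
  for (k in seq_along(tier$blocks)) {
    if (k > 1L) { h <- halveDim(h); w <- halveDim(w) }
    shapes[[paste0("block_", k)]] <- c(H = h, W = w, C = tier$channels$out[k])
  }
  shapes
}

stemForward <- function(tier, x, train) {
  z <- convForward(tier$conv1, x)
  f1 <- bnForward(tier$bn1, z, train); tier$bn1 <- f1$layer
  a1 <- reluForward(f1$y)
  pl <- poolForward(a1)
  y <- pl$y
  cache <- list(x = x, a1 = a1, poolIdx = pl$idx, bn1c = f1$cache,
                poolDim = dim(a1))
  if (!is.null(tier$conv2)) {
    z <- convForward(tier$conv2, y)
    f2 <- bnForward(tier$bn2s, z, train); tier$bn2s <- f2$layer
    cache$p <- y
    cache$a2 <- reluForward(f2$y)
    cache$bn2c <- f2$cache
    y <- cache$a2
  }
  list(y = y, cache = cache, tier = tier)
}

stemBackward <- function(tier, cache, dy, evalMode = FALSE) {
  grads <- list()
  if (!is.null(tier$conv2)) {
    dy <- reluBackward(cache$a2, dy)
    b2 <- bnBack(tier$bn2s, cache$bn2c, dy, evalMode)
    c2 <- convBackward(tier$conv2, cache$p, b2$dx, TRUE)
    if (!evalMode) { grads$conv2 <- c2$grads; grads$bn2s <- b2$grads }
    dy <- c2$dx
  }
  d <- cache$poolDim
  dy <- poolBackward(dy, cache$poolIdx, d[1], d[2])
  dy <- reluBackward(cache$a1, dy)
  b1 <- bnBack(tier$bn1, cache$bn1c, dy, evalMode)
  c1 <- convBackward(tier$conv1, cache$x, b1$dx, FALSE)
  if (!evalMode) { grads$conv1 <- c1$grads; grads$bn1 <- b1$grads }
  list(grads = grads)
}

blockForward <- function(tier, k, x, train, keepHookUnit = NA_integer_) {
  units <- tier$blocks[[k]]
  caches <- vector("list", length(units))
  for (u in seq_along(units)) {
    r <- bottleneckForward(units[[u]], x, train,
                           keepHook = identical(u, keepHookUnit))
    x <- r$y
    caches[[u]] <- r$cache
    units[[u]] <- r$unit
  }
  tier$blocks[[k]] <- units
  list(y = x, caches = caches, tier = tier)
}

# Backward through blocks `from` down to `to` (inclusive). `stopAtHook` makes
# the walk terminate at the tier's Grad-CAM hook and return the gradient
# there instead of descending further.
blocksBackward <- function(tier, blockCaches, dy, from, to = 1L,
                           needDx = FALSE, evalMode = FALSE,
                           stopAtHook = FALSE) {
  grads <- list(blocks = stats::setNames(vector("list", length(tier$blocks)),
                                         names(tier$blocks)))
  for (k in seq(from, to)) {
    units <- tier$blocks[[k]]
    ug <- vector("list", length(units))
    for (u in rev(seq_along(units))) {
      atHook <- stopAtHook && k == tier$hookBlock && u == tier$hookUnit
      need <- needDx || k > to || u > 1L
      r <- bottleneckBackward(units[[u]], blockCaches[[k]][[u]], dy,
                              needDx = need, evalMode = evalMode,
                              toHook = atHook)
      if (atHook) return(list(dhook = r$dhook))
      dy <- r$dx
      ug[[u]] <- r$grads
    }
    grads$blocks[[k]] <- ug
  }
  list(dx = dy, grads = grads)
}

headForward <- function(tier, x) {
  g <- gapForward(x)
  logits <- linearForward(tier$fc, g)
  list(logits = logits, probs = softmaxCols(logits),
       cache = list(g = g, xdim = dim(x)))
}

headBackward <- function(tier, cache, dlogits, evalMode = FALSE) {
  lb <- linearBackward(tier$fc, cache$g, dlogits)
  d <- cache$xdim
  list(dx = gapBackward(lb$dx, d[1], d[2], d[3], d[4]),
       grads = if (!evalMode) list(fc = lb$grads))
}

#' Run one tier forward
#'
#' @param tier a tier object from [buildTier()].
#' @param x a grayscale image matrix at the tier's expected input size, or an
#'   `(H, W, 1, N)` batch tensor.
#' @param train logical; batch-norm uses batch statistics and caches are kept
#'   for backpropagation when `TRUE`.
#' @param cache keep activation caches (implied by `train`; set `TRUE` in
#'   eval mode when a Grad-CAM backward pass will follow).
#' @return list with `taps` (named feature maps after every block), `scores`
#'   (`logits` and `probs`, tiers with an fc head only), `hook` (the Grad-CAM
#'   hook tensor, primary tier), `caches`, and the updated `tier`.
#' @export
tierForward <- function(tier, x, train = FALSE, cache = train) {
  x <- asTensor(x)
  d <- dim(x)
  if (d[1] != tier$inH || d[2] != tier$inW)
    stop(sprintf("%s tier expects %dx%d input (HxW), got %dx%d",
                 tier$tier, tier$inH, tier$inW, d[1], d[2]))
  keep <- cache || train
  st <- stemForward(tier, x, train); tier <- st$tier
  y <- st$y
  taps <- list()
  blockCaches <- vector("list", length(tier$blocks))
  for (k in seq_along(tier$blocks)) {
    hu <- if (tier$tier == "primary" && k == tier$hookBlock) tier$hookUnit
          else NA_integer_
    bf <- blockForward(tier, k, y, train, keepHookUnit = hu)
    y <- bf$y
    tier <- bf$tier
    taps[[names(tier$blocks)[k]]] <- y
    if (keep) blockCaches[[k]] <- bf$caches
  }
  hook <- if (keep && tier$tier == "primary")
    blockCaches[[tier$hookBlock]][[tier$hookUnit]]$hook
  scores <- NULL
  headCache <- NULL
  if (!is.null(tier$fc)) {
    hf <- headForward(tier, y)
    scores <- list(logits = hf$logits, probs = hf$probs)
    headCache <- hf$cache
  }
  list(taps = taps, scores = scores, hook = hook,
       caches = if (keep) list(stem = st$cache, blocks = blockCaches,
                               head = headCache),
       tier = tier)
}

#' @export
print.cpcnnTier <- function(x, ...) {
  shp <- tierTapShapes(x)
  cat(sprintf("C-PCNN %s tier: input %dx%d, width x%g, repeats (%s)\n",
              x$tier, x$inH, x$inW, x$widthMultiplier,
              paste(x$repeats, collapse = ",")))
  for (nm in names(shp))
    cat(sprintf("  %s tap: %d x %d x %d\n", nm, shp[[nm]][1], shp[[nm]][2],
                shp[[nm]][3]))
  if (!is.null(x$fc)) cat("  fc head: global average pool -> 2 classes\n")
  invisible(x)
}
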