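# Primitive layers of the CNN engine: convolution (im2col + BLAS gemm in C++),
# batch normalization, ReLU, max-pooling, global average pooling and the linear
# head. Each layer is a plain list of parameters; forward functions return the
# output plus a cache, backward functions consume the cache and return the
# input gradient plus parameter gradients in the same nested shape as the
# parameters, so the SGD update can walk the two trees in parallel.

convInit <- function(kh, kw, cin, cout, stride = 1L, pad = NULL, zero = FALSE) {
  pad <- pad %||% (kh %/% 2L)
  sd <- sqrt(2 / (kh * kw * cin))
  w <- if (zero) array(0, c(kh, kw, cin, cout))
       else array(stats::rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout))
  list(kind = "conv", w = w, b = numeric(cout),
       stride = as.integer(stride), pad = as.integer(pad))
}

convForward <- function(layer, x) {
  .conv2dForward(x, layer$w, layer$b, layer$stride, layer$pad)
}

convBackward <- function(layer, x, dy, needDx = TRUE) {
  g <- .conv2dBackward(x, layer$w, dy, layer$stride, layer$pad, needDx)
  list(dx = if (needDx) g$dx else NULL, grads = list(w = g$dw, b = g$db))
}

bnInit <- function(c, momentum = 0.1) {
  list(kind = "bn", gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c), momentum = momentum, eps = 1e-5)
}

# Per-channel reduction of an (H, W, C, N) tensor to a length-C vector of sums.
channelSums <- function(x) .channelDot(x, numeric(0))

# Broadcast per-channel vectors over an (H, W, C, N) tensor: x * s[c] + t[c].
channelScale <- function(x, s, t = NULL) .channelAffine(x, s, t %||% numeric(0))

bnForward <- function(layer, x, train) {
  d <- dim(x)
  nred <- d[1] * d[2] * d[4]
  if (train) {
    mu <- channelSums(x) / nred
    v <- .channelDot(x, x) / nred - mu^2
    v <- pmax(v, 0)
    layer$rmean <- (1 - layer$momentum) * layer$rmean + layer$momentum * mu
    layer$rvar <- (1 - layer$momentum) * layer$rvar + layer$momentum * v
  } else {
    mu <- layer$rmean
    v <- layer$rvar
  }
  istd <- 1 / sqrt(v + layer$eps)
  xhat <- channelScale(x, istd, -mu * istd)
  y <- channelScale(xhat, layer$gamma, layer$beta)
  list(y = y, cache = if (train) list(xhat = xhat, istd = istd) else NULL,
       layer = layer)
}

bnBackward <- function(layer, cache, dy) {
  d <- dim(dy)
  nred <- d[1] * d[2] * d[4]
  xhat <- cache$xhat
  dgamma <- .channelDot(dy, xhat)
  dbeta <- channelSums(dy)
  # dx = gamma * istd * (dy - mean(dy) - xhat * mean(dy * xhat))
  dx <- .bnBackwardKernel(dy, xhat, dbeta / nred, dgamma / nred,
                          layer$gamma * cache$istd)
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

reluForward <- function(x) .reluFwd(x)

reluBackward <- function(y, dy) .reluBwd(y, dy)

poolForward <- function(x) .maxpoolForward(x, 3L, 2L, 1L)

poolBackward <- function(dy, idx, H, W) .maxpoolBackward(dy, idx, H, W)

gapForward <- function(x) {
  d <- dim(x)
  matrix(.colSums(x, d[1] * d[2], d[3] * d[4]) / (d[1] * d[2]), d[3], d[4])
}

gapBackward <- function(dg, H, W, C, N) {
  dx <- rep(as.vector(dg), each = H * W) / (H * W)
  dim(dx) <- c(H, W, C, N)
  dx
}

linearInit <- function(cin, cout, sd = NULL) {
  sd <- sd %||% sqrt(2 / cin)
  list(kind = "linear", w = matrix(stats::rnorm(cin * cout, sd = sd), cin, cout),
       b = numeric(cout))
}

linearForward <- function(layer, g) crossprod(layer$w, g) + layer$b

linearBackward <- function(layer, g, dz) {
  list(dx = layer$w %*% dz,
       grads = list(w = g %*% t(dz), b = rowSums(dz)))
}

# Softmax cross-entropy over a (2, N) logit matrix with 0/1 labels.
# Returns the mean loss, the class probabilities and dloss/dlogits.
softmaxCELoss <- function(logits, labels) {
  p <- softmaxCols(logits)
  n <- ncol(logits)
  idx <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}

# --- SGD with momentum over nested parameter/gradient trees ----------------

TRAINABLE <- c("w", "b", "gamma", "beta")

sgdUpdate <- function(params, grads, vel, lr, momentum) {
  if (is.null(grads)) return(list(params = params, vel = vel))
  if (length(vel) == 0) vel <- vector("list", length(grads))
  keys <- if (is.null(names(grads))) seq_along(grads) else names(grads)
  for (nm in keys) {
    g <- grads[[nm]]
    if (is.list(g)) {
      r <- sgdUpdate(params[[nm]], g, vel[[nm]], lr, momentum)
      params[[nm]] <- r$params
      vel[[nm]] <- r$vel
    } else if (is.numeric(g) && is.character(nm) && nm %in% TRAINABLE) {
      v <- if (is.null(vel[[nm]])) 0 * g else vel[[nm]]
      v <- momentum * v + g
      vel[[nm]] <- v
      params[[nm]] <- params[[nm]] - lr * v
    }
  }
  list(params = params, vel = vel)
}

gradSqNorm <- function(grads) {
  if (is.null(grads)) return(0)
  if (is.numeric(grads)) return(sum(grads^2))
  sum(vapply(grads, gradSqNorm, numeric(1)))
}

scaleGrads <- function(grads, s) {
  if (is.null(grads)) return(NULL)
  if (is.numeric(grads)) return(grads * s)
  lapply(grads, scaleGrads, s = s)
}

# Global L2 gradient-norm clipping (a standard stabilizer for the cascade
# stage, where spiky attention maps can produce outsized gradients).
clipGrads <- function(grads, maxNorm) {
  if (is.null(maxNorm) || !is.finite(maxNorm)) return(grads)
  nrm <- sqrt(gradSqNorm(grads))
  if (nrm > maxNorm) scaleGrads(grads, maxNorm / nrm) else grads
}

# Elementwise sum of two gradient trees (used where a tensor feeds two paths).
addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    keys <- if (is.null(names(a))) seq_along(a) else names(a)
    for (nm in keys) a[[nm]] <- addGrads(a[[nm]], b[[nm]])
    a
  } else a + b
}
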