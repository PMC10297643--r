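#' @useDynLib cpcnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Evaluate code under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards; all randomness in the package flows through this.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive an independent stream seed
#'
#' Maps `(seed, index)` to a 31-bit seed by a mixed linear-congruential step.
#' Phantom cases, batch shuffles and sub-runs each draw from their own stream
#' so any one of them is reproducible in isolation.
#'
#' @param seed base integer seed.
#' @param index stream index (e.g. a case number).
#' @return integer seed below 2^31.
#' @export
streamSeed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807 + 12345) %% 2147483647
  as.integer(s)
}

# Ensure an (H, W, C, N) tensor; matrices become (H, W, 1, 1).
asTensor <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array, got a vector")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected 2-4 dimensions, got ", length(d))
  x
}

#' Bilinear resampling of a matrix or tensor
#'
#' Resizes with half-pixel-centre coordinates and edge clamping; constants are
#' preserved exactly and the map is linear, which the attention module relies
#' on for its backward pass.
#'
#' @param x matrix or (H, W, C, N) array.
#' @param height,width target spatial size in pixels.
#' @return object of the same dimensionality as `x`, resized.
#' @export
resizeBilinear <- function(x, height, width) {
  d <- dim(x)
  y <- .resizeBilinear(asTensor(x), as.integer(height), as.integer(width))
  if (length(d) == 2L) dim(y) <- c(height, width)
  else if (length(d) == 3L) dim(y) <- c(height, width, d[3])
  y
}

softmaxCols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# Round half away from zero (the convention of the reported tables).
roundHalfUp <- function(x, digits = 4L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Clamp to [0, 1] preserving dimensions.
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
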