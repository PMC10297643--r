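# Shared fixtures: micro-scale specs and configs sized for fast unit tests.
# The 64x32 base keeps every tier forward under a second; the tiny preset
# (160x80) is reserved for the acceptance checks.

microSpec <- function(seed = 7L, ...) {
  phantomSpec(baseResolution = c(64L, 32L), seed = seed, ...)
}

microConfig <- function(seed = 5L, ...) {
  tinyCascadeConfig(baseSize = c(64L, 32L), seed = seed, ...)
}

microTier <- function(tier = "primary", seed = 1L, baseSize = c(64L, 32L)) {
  withSeed(seed, buildTier(tier, baseSize = baseSize, widthMultiplier = 0.25,
                           repeats = c(1L, 1L, 1L, 1L)))
}

# Independent stride-arithmetic oracle: walks the layer list and halves
# spatial dims with floor((n - 1) / 2) + 1 at every stride-2 stage.
shapeOracle <- function(role, inW, inH, widthMultiplier, repeats) {
  halve <- function(n) (n - 1L) %/% 2L + 1L
  ch <- function(c) max(1L, as.integer(round(c * widthMultiplier)))
  h <- halve(halve(inH)); w <- halve(halve(inW))       # conv_1 + max-pool
  if (role == "tertiary") { h <- halve(h); w <- halve(w) }  # conv_2
  outs <- c(256L, 512L, 1024L, 2048L)
  nb <- if (role == "secondary") 2L else 4L
  res <- list()
  for (k in seq_len(nb)) {
    if (k > 1L) { h <- halve(h); w <- halve(w) }
    res[[paste0("block_", k)]] <- c(H = h, W = w, C = ch(outs[k]))
  }
  res
}
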