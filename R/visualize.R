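# Heat-map visualization: jet-colormap overlays of localization maps on the
# source image, and the three-panel layout (original / heat map / weighted
# feature magnitude) used to inspect the attention module.

jetColor <- function(v) {
  v <- pmin(1, pmax(0, v))
  r <- pmin(1, pmax(0, 1.5 - abs(4 * v - 3)))
  g <- pmin(1, pmax(0, 1.5 - abs(4 * v - 2)))
  b <- pmin(1, pmax(0, 1.5 - abs(4 * v - 1)))
  list(r = r, g = g, b = b)
}

overlayRGB <- function(image, map, alpha = 0.4) {
  if (!identical(dim(map), dim(image)))
    map <- resizeBilinear(map, nrow(image), ncol(image))
  col <- jetColor(map)
  arr <- array(0, c(nrow(image), ncol(image), 3))
  arr[, , 1] <- (1 - alpha) * image + alpha * col$r
  arr[, , 2] <- (1 - alpha) * image + alpha * col$g
  arr[, , 3] <- (1 - alpha) * image + alpha * col$b
  clamp01(arr)
}

#' Write a heat-map overlay PNG
#'
#' Blends the localization map (jet colormap) over the grayscale image.
#'
#' @param image grayscale matrix in [0, 1].
#' @param map a [LocalizationMap-class] or matrix in [0, 1].
#' @param path output PNG path.
#' @param alpha overlay opacity (default 0.4).
#' @export
writeHeatmapOverlay <- function(image, map, path, alpha = 0.4) {
  if (is(map, "LocalizationMap")) map <- map@values
  png::writePNG(overlayRGB(image, map, alpha), path)
  invisible(path)
}

#' Write the three-panel inspection figure
#'
#' Panels left to right: the original image, the heat-map overlay, and the
#' channel-wise magnitude of the weighted high-resolution features.
#'
#' @param image grayscale matrix.
#' @param map localization map.
#' @param weightedHigh `(H, W, C)` or `(H, W, C, 1)` feature array from the
#'   attention bundle.
#' @param path output PNG path.
#' @param alpha overlay opacity.
#' @export
writeTriptych <- function(image, map, weightedHigh, path, alpha = 0.4) {
  if (is(map, "LocalizationMap")) map <- map@values
  wh <- asTensor(weightedHigh)
  d <- dim(wh)
  mag <- matrix(sqrt(rowSums(matrix(wh[, , , 1], d[1] * d[2], d[3])^2)),
                d[1], d[2])
  if (max(mag) > 0) mag <- mag / max(mag)
  mag <- resizeBilinear(mag, nrow(image), ncol(image))
  ov <- overlayRGB(image, map, alpha)
  panel <- array(0, c(nrow(image), 3 * ncol(image), 3))
  for (ch in 1:3) {
    panel[, seq_len(ncol(image)), ch] <- image
    panel[, ncol(image) + seq_len(ncol(image)), ch] <- ov[, , ch]
    panel[, 2 * ncol(image) + seq_len(ncol(image)), ch] <- mag
  }
  png::writePNG(clamp01(panel), path)
  invisible(path)
}

#' Write raw map values as a plain-text array file
#'
#' @param map a [LocalizationMap-class] or matrix.
#' @param path output path (CSV, no header).
#' @export
writeMapValues <- function(map, path) {
  if (is(map, "LocalizationMap")) map <- map@values
  utils::write.table(map, path, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  invisible(path)
}
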