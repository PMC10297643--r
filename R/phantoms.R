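# Synthetic knee phantom generator. Each case renders, on a bright noisy
# background, one or two dark triangular meniscus horns (a bow tie when both
# are present) and, for injured cases, a thin bright streak strictly inside
# one horn. Geometry lives in base-resolution pixel coordinates and is
# re-rasterized analytically at every pyramid level, so the levels depict the
# same scene rather than being resampled copies; the Gaussian background
# texture is drawn once at base resolution and upsampled so it, too, is part
# of the scene.

# Signed distances of points to the three edges of a triangle, positive
# inside. `px`, `py` vectors; vertices counter-clockwise 3x2 matrix.
triangleSignedDist <- function(px, py, v) {
  d <- rep(Inf, length(px))
  for (e in 1:3) {
    a <- v[e, ]; b <- v[e %% 3 + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    len <- sqrt(ex^2 + ey^2)
    # inward normal for CCW ordering
    d <- pmin(d, ((px - a[1]) * -ey + (py - a[2]) * ex) / len)
  }
  d
}

ccw <- function(v) {
  if ((v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
      (v[3, 1] - v[1, 1]) * (v[2, 2] - v[1, 2]) < 0) v[c(1, 3, 2), ] else v
}

# Horn triangles in base-pixel coordinates with per-vertex jitter.
hornTriangle <- function(side, W, H, jitter) {
  v <- if (side == "anterior")
    rbind(c(0.14, 0.32), c(0.14, 0.74), c(0.44, 0.53))
  else
    rbind(c(0.86, 0.32), c(0.86, 0.74), c(0.56, 0.53))
  v <- v + matrix(jitter, 3, 2)
  ccw(cbind(v[, 1] * W, v[, 2] * H))
}

# Longest chord through point P in direction d that keeps a margin from every
# edge: each edge contributes a linear constraint in t.
chordInTriangle <- function(v, p, dir, margin) {
  tlo <- -Inf; thi <- Inf
  for (e in 1:3) {
    a <- v[e, ]; b <- v[e %% 3 + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    len <- sqrt(ex^2 + ey^2)
    s0 <- ((p[1] - a[1]) * -ey + (p[2] - a[2]) * ex) / len
    sd <- (dir[1] * -ey + dir[2] * ex) / len
    if (abs(sd) < 1e-12) {
      if (s0 < margin) return(NULL)
    } else {
      tEdge <- (margin - s0) / sd
      if (sd > 0) tlo <- max(tlo, tEdge) else thi <- min(thi, tEdge)
    }
  }
  if (!is.finite(tlo) || !is.finite(thi) || thi <= tlo) return(NULL)
  c(tlo, thi)
}

# Distance of grid points to a segment (vectorized).
segmentDist <- function(px, py, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  l2 <- vx^2 + vy^2
  t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((px - p1[1]) * vx + (py - p1[2]) * vy) / l2))
  sqrt((px - (p1[1] + t * vx))^2 + (py - (p1[2] + t * vy))^2)
}

# Rasterize the scene at scale m (1, 2, 4): grid of pixel centres in base
# coordinates; returns the noiseless structure image and the lesion alpha.
renderLevel <- function(geom, spec, m) {
  W <- spec@baseResolution[1]; H <- spec@baseResolution[2]
  h <- H * m; w <- W * m
  px <- matrix(rep((seq_len(w) - 0.5) / m, each = h), h, w)
  py <- matrix(rep((seq_len(h) - 0.5) / m, times = w), h, w)
  img <- matrix(spec@backgroundMean, h, w)
  soft <- 0.5 / m  # anti-alias width: half a pixel at this level
  for (tri in geom$wedges) {
    a <- pmin(1, pmax(0, triangleSignedDist(px, py, tri) / soft + 0.5))
    img <- img * (1 - a) + spec@wedgeIntensity * a
  }
  if (!is.null(geom$lesion)) {
    d <- segmentDist(px, py, geom$lesion$p1, geom$lesion$p2)
    a <- pmin(1, pmax(0, (geom$lesion$halfWidth - d) / soft + 0.5))
    img <- img * (1 - a) + spec@lesionIntensity * a
  }
  img
}

drawGeometry <- function(spec) {
  W <- spec@baseResolution[1]; H <- spec@baseResolution[2]
  injured <- stats::runif(1) < spec@lesionProbability
  sides <- if (spec@wedgeCount == 2L) c("anterior", "posterior")
           else sample(c("anterior", "posterior"), 1L)
  wedges <- lapply(sides, function(s)
    hornTriangle(s, W, H, stats::runif(6, -0.03, 0.03)))
  names(wedges) <- sides
  lesion <- NULL
  horn <- "none"
  if (injured) {
    horn <- sample(sides, 1L)
    tri <- wedges[[horn]]
    halfWidth <- spec@lesionThicknessPx / 2
    margin <- halfWidth + 1.5  # streak plus a guard ring stays inside the horn
    for (attempt in 1:20) {
      cen <- colMeans(tri)
      p <- cen + stats::runif(2, -0.1, 0.1) * c(W, H) * 0.1
      th <- stats::runif(1, 0, pi)
      dir <- c(cos(th), sin(th))
      rng <- chordInTriangle(tri, p, dir, margin)
      if (is.null(rng)) next
      len <- rng[2] - rng[1]
      if (len < 3) next
      keep <- stats::runif(1, 0.55, 0.9)
      mid <- (rng[1] + rng[2]) / 2
      lesion <- list(p1 = p + dir * (mid - len * keep / 2),
                     p2 = p + dir * (mid + len * keep / 2),
                     halfWidth = halfWidth)
      break
    }
    if (is.null(lesion)) {  # degenerate tiny horn: centre dot fallback
      cen <- colMeans(tri)
      lesion <- list(p1 = cen - c(1, 0), p2 = cen + c(1, 0),
                     halfWidth = halfWidth)
    }
  }
  list(wedges = wedges, lesion = lesion, horn = horn, injured = injured)
}

#' Generate one synthetic phantom case
#'
#' Deterministic in `(spec@seed, caseIndex)`: every case draws from its own
#' RNG stream, so any single case can be regenerated without generating the
#' ones before it.
#'
#' @param spec a [PhantomSpec-class].
#' @param caseIndex non-negative integer index of the case.
#' @return a [PhantomCase-class] with a three-level pyramid, 0/1 label,
#'   base-resolution lesion mask and horn tag.
#' @examples
#' case <- generateCase(phantomSpec(baseResolution = c(64, 32)), 1)
#' caseLabel(case)
#' @export
generateCase <- function(spec, caseIndex) {
  validObject(spec)
  withSeed(streamSeed(spec@seed, caseIndex), {
    geom <- drawGeometry(spec)
    W <- spec@baseResolution[1]; H <- spec@baseResolution[2]
    noise <- matrix(stats::rnorm(H * W, sd = spec@backgroundSd), H, W)
    levels <- lapply(c(1L, 2L, 4L), function(m) {
      img <- renderLevel(geom, spec, m)
      nz <- if (m == 1L) noise else resizeBilinear(noise, H * m, W * m)
      clamp01(img + nz)
    })
    mask <- matrix(0L, H, W)
    if (geom$injured) {
      px <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
      py <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
      d <- segmentDist(px, py, geom$lesion$p1, geom$lesion$p2)
      a <- pmin(1, pmax(0, (geom$lesion$halfWidth - d) / 0.5 + 0.5))
      mask[a > 0.5] <- 1L
      if (!any(mask > 0))  # guard: at least the pixel under the streak centre
        mask[ceiling(pmin(pmax(geom$lesion$p1[2], 0.5), H - 0.5)),
             ceiling(pmin(pmax(geom$lesion$p1[1], 0.5), W - 0.5))] <- 1L
    }
    new("PhantomCase",
        pyramid = pyramidImage(levels[[1]], levels[[2]], levels[[3]],
                               caseId = sprintf("case_%05d", caseIndex)),
        label = as.integer(geom$injured), lesionMask = mask,
        horn = geom$horn)
  })
}

#' Generate a phantom dataset
#'
#' @param spec a [PhantomSpec-class].
#' @param nCases number of cases (indices `0 .. nCases-1`).
#' @return list of [PhantomCase-class] objects.
#' @export
generateDataset <- function(spec, nCases) {
  if (nCases < 1) stop("nCases must be >= 1")
  lapply(seq_len(nCases) - 1L, function(i) generateCase(spec, i))
}

#' Write a phantom dataset as PNG files plus a manifest
#'
#' Writes one PNG per pyramid level, the lesion mask PNG for injured cases,
#' and `manifest.csv` with columns `case_id, label, horn` and the file paths.
#'
#' @param cases list of [PhantomCase-class].
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
writeDataset <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cases, function(cs) {
    id <- caseId(cs)
    paths <- file.path(dir, paste0(id, c("_low.png", "_mid.png", "_high.png")))
    png::writePNG(lowRes(cs), paths[1])
    png::writePNG(midRes(cs), paths[2])
    png::writePNG(highRes(cs), paths[3])
    maskPath <- ""
    if (caseLabel(cs) == 1L) {
      maskPath <- file.path(dir, paste0(id, "_mask.png"))
      png::writePNG(lesionMask(cs) * 1.0, maskPath)
    }
    data.frame(case_id = id, label = caseLabel(cs), horn = lesionHorn(cs),
               low = paths[1], mid = paths[2], high = paths[3],
               mask = maskPath, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
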