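# Explicit-loop reference: alpha_i = spatial mean of gradient channel i,
# map = ReLU(sum_i alpha_i * f_i), element by element.
gradcamOracle <- function(features, gradient) {
  d <- dim(features)
  m <- matrix(0, d[1], d[2])
  for (i in seq_len(d[3])) {
    alpha <- mean(gradient[, , i])
    m <- m + alpha * features[, , i]
  }
  m[m < 0] <- 0
  m
}

test_that("computeGradCam matches the explicit-loop oracle on 100 random instances", {
  withSeed(101, {
    for (trial in 1:100) {
      h <- sample(2:8, 1); w <- sample(2:8, 1); c <- sample(1:8, 1)
      f <- array(rnorm(h * w * c), c(h, w, c))
      g <- array(rnorm(h * w * c), c(h, w, c))
      m <- computeGradCam(f, g)
      expect_lt(max(abs(m@native - gradcamOracle(f, g))), 1e-5)
    }
  })
})

test_that("worked two-channel example reproduces the hand computation", {
  f <- array(0, c(2, 2, 2))
  f[, , 1] <- rbind(c(1, 0), c(0, 1))
  f[, , 2] <- rbind(c(0, 2), c(0, 0))
  g <- array(0, c(2, 2, 2))
  g[, , 1] <- 0.5
  g[, , 2] <- rbind(c(1, -1), c(1, -1))
  m <- computeGradCam(f, g)
  expect_equal(m@native, rbind(c(0.5, 0), c(0, 0.5)))
})

test_that("constant gradients scale features and negative weights are rectified away", {
  f <- array(abs(rnorm(3 * 4 * 1)), c(3, 4, 1))
  g <- array(0.5, c(3, 4, 1))
  expect_equal(computeGradCam(f, g)@native, 0.5 * f[, , 1])
  gneg <- array(-1, dim(f))
  expect_true(all(computeGradCam(f, gneg)@native == 0))
  expect_error(computeGradCam(f, array(0, c(3, 4, 2))), "identical shape")
})

test_that("the map is linear in the features while the pre-ReLU sum is non-negative", {
  withSeed(8, {
    f <- array(abs(rnorm(4 * 4 * 3)), c(4, 4, 3))
    g <- array(abs(rnorm(4 * 4 * 3)), c(4, 4, 3))
    m1 <- computeGradCam(f, g)@native
    m3 <- computeGradCam(3 * f, g)@native
    expect_equal(m3, 3 * m1, tolerance = 1e-12)
  })
})

test_that("localize returns a normalized image-size map whose peak survives upsampling", {
  tier <- microTier("primary", seed = 12)
  img <- lowRes(generateCase(microSpec(seed = 3, lesionProbability = 1), 0))
  res <- localize(tier, img, classIndex = 1L)
  m <- res$map
  expect_equal(dim(m@values), c(32L, 64L))
  expect_true(all(m@values >= 0))
  expect_equal(max(m@values), 1)
  # argmax oracle: the native peak, mapped through the upsampling grid,
  # stays within one native cell of the upsampled peak
  natPeak <- arrayInd(which.max(m@native), dim(m@native))
  upPeak <- arrayInd(which.max(m@values), dim(m@values))
  cellH <- 32 / nrow(m@native); cellW <- 64 / ncol(m@native)
  expect_lte(abs(upPeak[1] - (natPeak[1] - 0.5) * cellH), cellH)
  expect_lte(abs(upPeak[2] - (natPeak[2] - 0.5) * cellW), cellW)
})

test_that("an all-zero map normalizes to zeros without dividing by zero", {
  z <- matrix(0, 3, 5)
  expect_identical(cpcnn:::normalizeMap(z), z)
  lm <- new("LocalizationMap", values = z, native = z, classIndex = 1L)
  expect_true(validObject(lm))
})

test_that("the hook gradient matches central finite differences on the tiny preset", {
  tier <- microTier("primary", seed = 21)
  img <- withSeed(3, matrix(runif(32 * 64), 32, 64))
  fw <- tierForward(tier, img, cache = TRUE)
  dhook <- cpcnn:::hookGradient(tier, fw, classIndex = 1L)
  hook <- fw$hook
  withSeed(4, {
    idx <- sample(length(hook), 12)
    h <- 1e-3
    for (i in idx) {
      hp <- hook; hp[i] <- hp[i] + h
      hm <- hook; hm[i] <- hm[i] - h
      fd <- (cpcnn:::forwardFromHook(tier, fw, hp)[2, 1] -
             cpcnn:::forwardFromHook(tier, fw, hm)[2, 1]) / (2 * h)
      expect_equal(dhook[i], fd, tolerance = 1e-3)
    }
  })
})

test_that("after training a tiny classifier on bright-square images the peak finds the square", {
  # toy sanity: squares on noise vs pure noise; the injury-class map should
  # peak inside the bright square for a trained primary tier
  withSeed(55, {
    mk <- function(bright) {
      img <- matrix(runif(32 * 64, 0, 0.3), 32, 64)
      pos <- c(sample(4:24, 1), sample(4:52, 1))
      if (bright) img[pos[1] + 0:7, pos[2] + 0:7] <- 0.95
      list(img = img, pos = pos)
    }
    train <- lapply(1:40, function(i) mk(i <= 20))
    labels <- rep(c(1L, 0L), each = 20)
    # hook block_2 here: at this miniature input size the default block_3
    # tap is 2x4 and cannot resolve an 8 px square
    tier <- buildTier("primary", c(64L, 32L), 0.25, c(1L, 1L, 1L, 1L),
                      hookBlock = 2L)
    vel <- list()
    for (epoch in 1:8) {
      ord <- sample(40)
      for (b in split(ord, ceiling(seq_along(ord) / 8))) {
        x <- cpcnn:::stackImages(lapply(train[b], `[[`, "img"))
        fw <- tierForward(tier, x, train = TRUE)
        tier <- fw$tier
        ls <- cpcnn:::softmaxCELoss(fw$scores$logits, labels[b])
        hb <- cpcnn:::headBackward(tier, fw$caches$head, ls$dlogits)
        bb <- cpcnn:::blocksBackward(tier, fw$caches$blocks, hb$dx, 4L, 1L,
                                     needDx = TRUE)
        sb <- cpcnn:::stemBackward(tier, fw$caches$stem, bb$dx)
        up <- cpcnn:::sgdUpdate(tier, c(sb$grads, list(fc = hb$grads$fc,
                                                       blocks = bb$grads$blocks)),
                                vel, 0.01, 0.9)
        tier <- up$params; vel <- up$vel
      }
    }
    hits <- 0
    for (i in 1:10) {
      probe <- mk(TRUE)
      m <- localize(tier, probe$img, classIndex = 1L)$map@values
      peak <- arrayInd(which.max(m), dim(m))
      # inside the square, allowing one native map cell (8 px) of argmax
      # quantization around it
      inside <- peak[1] >= probe$pos[1] - 8 && peak[1] <= probe$pos[1] + 15 &&
        peak[2] >= probe$pos[2] - 8 && peak[2] <= probe$pos[2] + 15
      hits <- hits + inside
    }
    expect_gte(hits, 7)
  })
})
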