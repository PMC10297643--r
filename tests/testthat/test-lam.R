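microLam <- function(lowC = 3L, highC = 4L, seed = 2L) {
  withSeed(seed, lamInit(lowC, highC))
}

test_that("identical constant inputs give uniform unit attention summing to HW", {
  lam <- microLam()
  low <- array(0.3, c(6, 8, 3, 1))
  high <- array(0.3, c(6, 8, 4, 1))
  A <- featureAttention(lam, low, high)
  expect_equal(A, array(1, c(6, 8, 1, 1)), tolerance = 1e-12)
  # and for any inputs the rescaled softmax sums to exactly HW per sample
  withSeed(5, {
    low2 <- array(rnorm(6 * 8 * 3 * 2), c(6, 8, 3, 2))
    high2 <- array(rnorm(6 * 8 * 4 * 2), c(6, 8, 4, 2))
    A2 <- featureAttention(lam, low2, high2)
    expect_equal(sum(A2[, , , 1]), 48, tolerance = 1e-9)
    expect_equal(sum(A2[, , , 2]), 48, tolerance = 1e-9)
  })
})

test_that("feature attention matches a brute-force softmax oracle", {
  lam <- microLam(seed = 7)
  withSeed(11, {
    low <- array(rnorm(4 * 6 * 3), c(4, 6, 3, 1))
    high <- array(rnorm(4 * 6 * 4), c(4, 6, 4, 1))
    A <- featureAttention(lam, low, high)[, , 1, 1]
    # oracle: explicit 1x1 transforms, sum, fuse, exp/sum loop
    z <- matrix(0, 4, 6)
    for (r in 1:4) for (cc in 1:6) {
      s <- numeric(4)
      for (co in 1:4)
        s[co] <- sum(low[r, cc, , 1] * lam$tLow$w[1, 1, , co]) +
          lam$tLow$b[co] +
          sum(high[r, cc, , 1] * lam$tHigh$w[1, 1, , co]) + lam$tHigh$b[co]
      z[r, cc] <- sum(s * lam$att$w[1, 1, , 1]) + lam$att$b[1]
    }
    e <- exp(z - max(z))
    expect_lt(max(abs(A - e / sum(e) * 24)), 1e-6)
  })
})

test_that("location attention is the identity for zero maps and doubles at the peak", {
  z <- matrix(0, 5, 10)
  expect_equal(locationAttention(z, c(20, 40)), matrix(1, 20, 40))
  one <- z; one[3, 5] <- 1
  L <- locationAttention(one, c(20, 40))
  # peak approaches 2 at the resized cell location; half-pixel bilinear
  # sampling between nodes caps it at 1 + (1 - 1/(2s))^2 for scale s
  expect_gt(max(L), 1.75)
  expect_lte(max(L), 2)
  peak <- arrayInd(which.max(L), dim(L))
  expect_lte(abs(peak[1] - (3 - 0.5) * 4), 4)
  expect_lte(abs(peak[2] - (5 - 0.5) * 4), 4)
  # identity-scale resize keeps the peak at exactly 2
  expect_equal(max(locationAttention(one, c(5, 10))), 2)
  expect_error(locationAttention(z, c(0, 4)), "positive")
})

test_that("resize and the 1+x shift commute", {
  withSeed(3, {
    m <- matrix(runif(40), 5, 8)
    a <- 1 + resizeBilinear(m, 15, 24)
    b <- resizeBilinear(1 + m, 15, 24)
    expect_lt(max(abs(a - b)), 1e-6)
  })
})

test_that("applyLam equals the explicit composition of its three factors", {
  lam <- microLam(seed = 9)
  withSeed(13, {
    low <- array(rnorm(4 * 8 * 3), c(4, 8, 3, 1))
    high <- array(rnorm(4 * 8 * 4), c(4, 8, 4, 1))
    loc <- matrix(runif(8), 2, 4)
    bundle <- applyLam(lam, low, high, loc)
    A <- featureAttention(lam, low, high)
    L <- locationAttention(loc, c(4, 8))
    manual <- array(0, dim(high))
    for (co in 1:4) {
      hT <- matrix(0, 4, 8)
      for (ci in 1:4)
        hT <- hT + high[, , ci, 1] * lam$tOut$w[1, 1, ci, co]
      manual[, , co, 1] <- (hT + lam$tOut$b[co]) * A[, , 1, 1] * L
    }
    expect_lt(max(abs(bundle$weightedHigh - manual)), 1e-5)
  })
})

test_that("zero localization with constant inputs recovers the identity limit", {
  lam <- microLam(lowC = 4L, highC = 4L)
  low <- array(0.2, c(6, 8, 4, 1))
  high <- array(0.7, c(6, 8, 4, 1))
  loc <- matrix(0, 3, 4)
  bundle <- applyLam(lam, low, high, loc)
  # attention uniform at 1, location identity: output = tOut transform of high
  hT <- cpcnn:::convForward(lam$tOut, high)
  expect_equal(bundle$weightedHigh, hT, tolerance = 1e-9)
  # tOut starts at identity, so an untrained LAM passes high straight through
  expect_equal(bundle$weightedHigh, high, tolerance = 1e-9)
})

test_that("amplifying the localization peak monotonically boosts that location", {
  lam <- microLam(lowC = 3L, highC = 4L)
  withSeed(17, {
    low <- array(rnorm(4 * 8 * 3), c(4, 8, 3, 1))
    high <- array(abs(rnorm(4 * 8 * 4)) + 0.1, c(4, 8, 4, 1))
    loc <- matrix(0, 4, 8); loc[2, 3] <- 0.5
    loc2 <- loc; loc2[2, 3] <- 1
    b1 <- applyLam(lam, low, high, loc)
    b2 <- applyLam(lam, low, high, loc2)
    m1 <- sum(abs(b1$weightedHigh[2, 3, , 1]))
    m2 <- sum(abs(b2$weightedHigh[2, 3, , 1]))
    expect_gte(m2, m1)
  })
})

test_that("gradients flow through the LAM to both low and high inputs", {
  lam <- microLam(seed = 19)
  withSeed(23, {
    low <- array(rnorm(4 * 6 * 3), c(4, 6, 3, 1))
    high <- array(rnorm(4 * 6 * 4), c(4, 6, 4, 1))
    loc <- matrix(runif(6), 2, 3)
    bundle <- applyLam(lam, low, high, loc, train = TRUE)
    dwh <- withSeed(1, array(rnorm(length(bundle$weightedHigh)),
                             dim(bundle$weightedHigh)))
    bk <- cpcnn:::lamBackward(lam, bundle, dwh)
    # analytic vs central finite differences on random coordinates
    objective <- function(lowX, highX)
      sum(applyLam(lam, lowX, highX, loc)$weightedHigh * dwh)
    h <- 1e-5
    for (i in sample(length(low), 4)) {
      lp <- low; lp[i] <- lp[i] + h
      lm2 <- low; lm2[i] <- lm2[i] - h
      fd <- (objective(lp, high) - objective(lm2, high)) / (2 * h)
      expect_equal(bk$dlow[i], fd, tolerance = 1e-4)
    }
    for (i in sample(length(high), 4)) {
      hp <- high; hp[i] <- hp[i] + h
      hm <- high; hm[i] <- hm[i] - h
      fd <- (objective(low, hp) - objective(low, hm)) / (2 * h)
      expect_equal(bk$dhigh[i], fd, tolerance = 1e-4)
    }
    expect_gt(max(abs(bk$dlow)), 0)
    expect_gt(max(abs(bk$dhigh)), 0)
  })
})
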