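test_that("fuseFeatures adds equal-size maps exactly and upsamples constants", {
  withSeed(1, {
    a <- array(rnorm(4 * 8 * 3), c(4, 8, 3, 1))
    b <- array(rnorm(4 * 8 * 3), c(4, 8, 3, 1))
    expect_identical(fuseFeatures(a, b), a + b)
    expect_identical(fuseFeatures(array(0, dim(a)), b), b)
    # constant lower map at half size: bilinear upsampling preserves it
    loC <- array(0.7, c(2, 4, 3, 1))
    expect_equal(fuseFeatures(loC, b), b + 0.7, tolerance = 1e-12)
    expect_error(fuseFeatures(array(0, c(4, 8, 2, 1)), b), "channel mismatch")
  })
})

test_that("eval-mode cascade predictions are deterministic with softmax contracts", {
  model <- buildCascade(microConfig(seed = 31))
  cases <- generateDataset(microSpec(seed = 41), 10)
  p1 <- predictCascade(model, cases)
  p2 <- predictCascade(model, cases)
  expect_identical(p1, p2)
  expect_true(all(p1$prob >= 0 & p1$prob <= 1))
  single <- forwardCascade(model, cases[[1]])
  expect_equal(sum(single$scores$probs), 1, tolerance = 1e-6)
  expect_equal(sum(single$primaryScores$probs), 1, tolerance = 1e-6)
  expect_equal(single$label, as.integer(single$prob >= 0.5))
  expect_s4_class(single$localization, "LocalizationMap")
  expect_identical(forwardCascade(model, cases[[1]])$prob, single$prob)
})

test_that("one SGD step on one batch decreases that batch's cascade loss", {
  cfg <- microConfig(seed = 51)
  model <- buildCascade(cfg)
  cases <- generateDataset(microSpec(seed = 61), 8)
  labels <- vapply(cases, caseLabel, integer(1))
  lows <- lapply(cases, lowRes); mids <- lapply(cases, midRes)
  highs <- lapply(cases, highRes)
  locs <- lapply(lows, function(x) matrix(0, 32, 64))
  fw <- cpcnn:::cascadeForwardBatch(model, lows, mids, highs, train = TRUE,
                                    locs = locs)
  model <- fw$model
  loss0 <- cpcnn:::softmaxCELoss(fw$scores$logits, labels)
  grads <- cpcnn:::cascadeBackwardBatch(model, fw, loss0$dlogits)
  sub <- list(secondary = model$secondary, tertiary = model$tertiary,
              lam = model$lam)
  up <- cpcnn:::sgdUpdate(sub, grads, list(), lr = 1e-3, momentum = 0)
  model[names(up$params)] <- up$params
  fw2 <- cpcnn:::cascadeForwardBatch(model, lows, mids, highs, train = TRUE,
                                     locs = locs)
  loss1 <- cpcnn:::softmaxCELoss(fw2$scores$logits, labels)
  expect_lt(loss1$loss, loss0$loss)
})

test_that("two training epochs on 32 phantoms reduce the mean loss per stage", {
  cases <- generateDataset(microSpec(seed = 71), 32)
  cfg <- microConfig(seed = 81, epochsStage1 = 2L, epochsStage2 = 2L)
  model <- trainCascade(cases, cfg)
  s1 <- model$log[model$log$stage == 1, "loss"]
  expect_lt(s1[2], s1[1])
  expect_true(all(is.finite(model$log$loss)))
})

test_that("training twice with the same seed reproduces the weights bit for bit", {
  cases <- generateDataset(microSpec(seed = 91), 12)
  cfg <- microConfig(seed = 101, epochsStage1 = 1L, epochsStage2 = 1L)
  m1 <- trainCascade(cases, cfg)
  m2 <- trainCascade(cases, cfg)
  expect_identical(m1$tertiary$fc$w, m2$tertiary$fc$w)
  expect_identical(m1$secondary$conv1$w, m2$secondary$conv1$w)
  expect_identical(m1$lam$att$w, m2$lam$att$w)
  expect_identical(m1$log, m2$log)
})

test_that("lambdaFinal = 0 leaves the trainable cascade weights untouched", {
  cases <- generateDataset(microSpec(seed = 111), 12)
  cfg <- microConfig(seed = 121, epochsStage1 = 1L, epochsStage2 = 2L,
                     lambdaFinal = 0)
  before <- buildCascade(cfg)
  after <- trainCascade(cases, cfg)
  expect_identical(after$tertiary$conv1$w, before$tertiary$conv1$w)
  expect_identical(after$tertiary$fc$w, before$tertiary$fc$w)
  expect_identical(after$secondary$conv1$w, before$secondary$conv1$w)
  expect_identical(after$lam$tOut$w, before$lam$tOut$w)
  # stage 1 still trains the primary tier
  expect_false(identical(after$primary$fc$w, before$primary$fc$w))
})

test_that("single-class datasets are rejected", {
  cases <- generateDataset(microSpec(seed = 131, lesionProbability = 0), 6)
  expect_error(trainCascade(cases, microConfig()), "both classes")
})

test_that("loss weights must be non-negative and ties classify positive", {
  expect_error(cascadeConfig(lambdaFinal = -1), "non-negative")
  model <- buildCascade(microConfig(seed = 141))
  model$config$threshold <- 0.5
  cases <- generateDataset(microSpec(seed = 151), 4)
  p <- predictCascade(model, cases)
  expect_identical(p$label, as.integer(p$prob >= 0.5))
})
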