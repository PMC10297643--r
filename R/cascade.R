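# The full cascaded-progressive network. The primary tier classifies the low
# level and yields the Grad-CAM lesion map; its block_1 features are fused
# (bilinear upsample + elementwise add) into the secondary tier after
# block_1; the secondary block_2 features are fused into the tertiary tier
# after block_2 (the tertiary conv_2 halves its maps so both taps coincide);
# the LAM re-weights the fused high-resolution features with the lesion map
# before tertiary block_3; the tertiary fc head gives the final diagnosis.
#
# Training is two-stage: the primary tier is trained alone on image labels
# (weak supervision: pixel masks are never used), then frozen while the
# secondary + tertiary tiers and the LAM train on the cascade loss. Training
# through the Grad-CAM backward pass would need second-order gradients, so
# the map enters stage 2 as a constant per case.

#' Cascade configuration
#'
#' @param baseSize `c(W, H)` of the low pyramid level (W = 2H). Nominal
#'   640x320; the tiny preset uses 160x80.
#' @param widthMultiplier,repeats backbone scaling, see [buildTier()].
#' @param hookBlock,hookUnit Grad-CAM hook location on the primary tier.
#' @param lr,momentum SGD learning rate (cosine-decayed per stage) and
#'   momentum.
#' @param batchSize minibatch size.
#' @param epochsStage1,epochsStage2 epochs for the primary stage and the
#'   cascade stage.
#' @param lambdaPrimary weight of the (frozen, report-only) primary
#'   cross-entropy in the stage-2 loss.
#' @param lambdaFinal weight of the tertiary cross-entropy that drives
#'   stage-2 gradients.
#' @param clipNorm global L2 gradient-norm clip for the cascade stage, where
#'   spiky attention maps can produce outsized gradients; `Inf` disables.
#'   Stage 1 is a plain classifier and trains unclipped.
#' @param threshold decision threshold on the injury probability; ties are
#'   classified positive.
#' @param auxSecondaryHead add a supervised auxiliary head on the secondary
#'   block_2 tap (off by default).
#' @param lambdaAux weight of the auxiliary head loss when enabled.
#' @param seed seed for initialization and batch shuffling.
#' @return config list for [buildCascade()] / [trainCascade()].
#' @export
cascadeConfig <- function(baseSize = c(640L, 320L), widthMultiplier = 1,
                          repeats = c(3L, 4L, 6L, 3L), hookBlock = 3L,
                          hookUnit = 1L, lr = 0.01, momentum = 0.9,
                          batchSize = 8L, epochsStage1 = 50L,
                          epochsStage2 = 50L, lambdaPrimary = 1,
                          lambdaFinal = 1, clipNorm = 5, threshold = 0.5,
                          auxSecondaryHead = FALSE, lambdaAux = 0.3,
                          seed = 1L) {
  if (lambdaPrimary < 0 || lambdaFinal < 0 || lambdaAux < 0)
    stop("loss weights must be non-negative")
  as.list(environment())
}

#' Tiny preset configuration for desk-scale runs
#'
#' Quarter-width backbone with single-unit blocks at a 160x80 base, sized so
#' the full cascade trains in minutes on one CPU core.
#'
#' @param ... overrides passed on to [cascadeConfig()].
#' @export
tinyCascadeConfig <- function(...) {
  defaults <- list(baseSize = c(160L, 80L), widthMultiplier = 0.25,
                   repeats = c(1L, 1L, 1L, 1L), batchSize = 8L,
                   epochsStage1 = 8L, epochsStage2 = 4L)
  args <- utils::modifyList(defaults, list(...))
  do.call(cascadeConfig, args)
}

#' Build an untrained cascade model
#'
#' @param config from [cascadeConfig()].
#' @return a `cpcnnModel` list with the three tiers and the LAM.
#' @export
buildCascade <- function(config = cascadeConfig()) {
  withSeed(config$seed, {
    primary <- buildTier("primary", config$baseSize, config$widthMultiplier,
                         config$repeats, config$hookBlock, config$hookUnit)
    secondary <- buildTier("secondary", config$baseSize,
                           config$widthMultiplier, config$repeats)
    tertiary <- buildTier("tertiary", config$baseSize, config$widthMultiplier,
                          config$repeats)
    c2 <- secondary$channels$out[2]
    model <- list(primary = primary, secondary = secondary,
                  tertiary = tertiary, lam = lamInit(c2, c2),
                  auxHead = if (config$auxSecondaryHead) linearInit(c2, 2L, sd = 0.01),
                  config = config, log = NULL, trained = FALSE)
    class(model) <- "cpcnnModel"
    model
  })
}

#' Fuse two feature maps across resolutions
#'
#' The lower-tier map is bilinearly upsampled to the upper map's spatial size
#' when smaller, then the two are added elementwise. Channel counts must
#' match (guaranteed at both cascade fusion points by construction).
#'
#' @param lower,upper feature maps (`(H, W, C, N)` arrays or `(H, W, C)`).
#' @return fused map with `upper`'s shape.
#' @export
fuseFeatures <- function(lower, upper) {
  lower <- asTensor(lower); upper <- asTensor(upper)
  dl <- dim(lower); du <- dim(upper)
  if (dl[3] != du[3])
    stop("channel mismatch in fusion: ", dl[3], " vs ", du[3])
  if (dl[1] != du[1] || dl[2] != du[2])
    lower <- .resizeBilinear(lower, du[1], du[2])
  lower + upper
}

# Stack per-case matrices into an (H, W, 1, N) tensor.
stackImages <- function(imgs) {
  d <- dim(imgs[[1]])
  x <- array(0, c(d[1], d[2], 1L, length(imgs)))
  for (n in seq_along(imgs)) x[, , 1L, n] <- imgs[[n]]
  x
}

caseLevels <- function(cases, level) {
  getter <- switch(level, low = lowRes, mid = midRes, high = highRes)
  lapply(cases, getter)
}

# Batched cascade forward. `locs` is a list of normalized low-level maps, one
# per sample (precomputed in stage 2; computed here otherwise with the injury
# class in train mode and the predicted class in eval mode).
cascadeForwardBatch <- function(model, low, mid, high, train = FALSE,
                                locs = NULL, cache = train,
                                locZero = FALSE) {
  lowT <- stackImages(low); midT <- stackImages(mid); highT <- stackImages(high)
  n <- length(low)
  pfw <- tierForward(model$primary, lowT, train = FALSE, cache = FALSE)
  if (is.null(locs)) {
    locs <- lapply(seq_len(n), function(i) {
      ci <- if (train) 1L else (which.max(pfw$scores$probs[, i]) - 1L)
      localize(model$primary, low[[i]], classIndex = ci)$map@values
    })
  }
  if (locZero)
    locs <- lapply(locs, function(m) matrix(0, nrow(m), ncol(m)))
  # secondary: stem -> block_1 -> (+ primary block_1) -> block_2
  sec <- model$secondary
  sst <- stemForward(sec, midT, train); sec <- sst$tier
  sb1 <- blockForward(sec, 1L, sst$y, train); sec <- sb1$tier
  fused1 <- fuseFeatures(pfw$taps$block_1, sb1$y)
  sb2 <- blockForward(sec, 2L, fused1, train); sec <- sb2$tier
  sTap2 <- sb2$y
  auxScores <- NULL; auxCache <- NULL
  if (!is.null(model$auxHead)) {
    g <- gapForward(sTap2)
    lg <- linearForward(model$auxHead, g)
    auxScores <- list(logits = lg, probs = softmaxCols(lg))
    auxCache <- list(g = g, xdim = dim(sTap2))
  }
  # tertiary: stem (conv_1 + conv_2) -> block_1 -> block_2 -> fuse + LAM
  ter <- model$tertiary
  tst <- stemForward(ter, highT, train); ter <- tst$tier
  tb1 <- blockForward(ter, 1L, tst$y, train); ter <- tb1$tier
  tb2 <- blockForward(ter, 2L, tb1$y, train); ter <- tb2$tier
  tTap2 <- tb2$y
  fused2 <- fuseFeatures(sTap2, tTap2)
  bundle <- applyLam(model$lam, sTap2, fused2, locs, train = train)
  tb3 <- blockForward(ter, 3L, bundle$weightedHigh, train); ter <- tb3$tier
  tb4 <- blockForward(ter, 4L, tb3$y, train); ter <- tb4$tier
  hf <- headForward(ter, tb4$y)
  model$secondary <- sec; model$tertiary <- ter
  list(model = model, scores = list(logits = hf$logits, probs = hf$probs),
       primaryScores = pfw$scores, auxScores = auxScores, locs = locs,
       caches = if (cache)
         list(sStem = sst$cache, sBlocks = list(sb1$caches, sb2$caches),
              tStem = tst$cache,
              tBlocks = list(tb1$caches, tb2$caches, tb3$caches, tb4$caches),
              bundle = bundle, head = hf$cache, aux = auxCache,
              sTap2dim = dim(sTap2)))
}

cascadeBackwardBatch <- function(model, fw, dlogits, dlogitsAux = NULL) {
  cc <- fw$caches
  ter <- model$tertiary; sec <- model$secondary
  hb <- headBackward(ter, cc$head, dlogits)
  r43 <- blocksBackward(ter, list(NULL, NULL, cc$tBlocks[[3]], cc$tBlocks[[4]]),
                        hb$dx, from = 4L, to = 3L, needDx = TRUE)
  lb <- lamBackward(model$lam, cc$bundle, r43$dx)
  dtTap2 <- lb$dhigh                      # fused2 -> tertiary branch
  dsTap2 <- lb$dlow + lb$dhigh            # LAM low input + fused2 -> secondary branch
  if (!is.null(dlogitsAux)) {
    ab <- linearBackward(model$auxHead, cc$aux$g, dlogitsAux)
    d <- cc$aux$xdim
    dsTap2 <- dsTap2 + gapBackward(ab$dx, d[1], d[2], d[3], d[4])
    auxGrads <- ab$grads
  } else auxGrads <- NULL
  r21 <- blocksBackward(ter, list(cc$tBlocks[[1]], cc$tBlocks[[2]]), dtTap2,
                        from = 2L, to = 1L, needDx = TRUE)
  tst <- stemBackward(ter, cc$tStem, r21$dx)
  terGrads <- c(tst$grads, list(fc = hb$grads$fc),
                list(blocks = addGrads(r43$grads$blocks, r21$grads$blocks)))
  s21 <- blocksBackward(sec, list(cc$sBlocks[[1]], cc$sBlocks[[2]]), dsTap2,
                        from = 2L, to = 1L, needDx = TRUE)
  sst <- stemBackward(sec, cc$sStem, s21$dx)
  secGrads <- c(sst$grads, list(blocks = s21$grads$blocks))
  list(secondary = secGrads, tertiary = terGrads, lam = lb$grads,
       auxHead = auxGrads)
}

#' Run the full cascade on one case
#'
#' @param model a `cpcnnModel` (trained or freshly built).
#' @param pyramid a [PyramidImage-class] or [PhantomCase-class].
#' @param mode `"eval"` (localization map from the predicted class) or
#'   `"train"` (map from the injury class).
#' @return a `Prediction` list: `label` (0/1), `prob` (injury probability),
#'   `localization` ([LocalizationMap-class]), `scores` (tertiary) and
#'   `primaryScores`.
#' @export
forwardCascade <- function(model, pyramid, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (is(pyramid, "PhantomCase")) pyramid <- pyramid@pyramid
  fw <- cascadeForwardBatch(model, list(pyramid@low), list(pyramid@mid),
                            list(pyramid@high), train = FALSE, cache = FALSE)
  ci <- if (mode == "train") 1L else (which.max(fw$scores$probs[, 1]) - 1L)
  locFull <- localize(model$primary, pyramid@low, classIndex = ci)
  prob <- fw$scores$probs[2, 1]
  out <- list(label = as.integer(prob >= model$config$threshold), prob = prob,
              localization = locFull$map, scores = fw$scores,
              primaryScores = fw$primaryScores, caseId = pyramid@caseId)
  class(out) <- "cpcnnPrediction"
  out
}

#' @export
print.cpcnnPrediction <- function(x, ...) {
  cat(sprintf("Prediction '%s': label %d, P(injury) = %.3f\n",
              x$caseId, x$label, x$prob))
  invisible(x)
}

cosineLr <- function(lr, epoch, epochs) {
  lr * 0.5 * (1 + cos(pi * (epoch - 1) / epochs))
}

checkFinite <- function(loss, stage, epoch) {
  if (!is.finite(loss))
    stop(sprintf("training diverged (non-finite loss) in %s, epoch %d; lower the learning rate",
                 stage, epoch))
}

batchIndices <- function(n, batchSize, seed) {
  ord <- withSeed(seed, sample.int(n))
  split(ord, ceiling(seq_along(ord) / batchSize))
}

#' Train the C-PCNN on labelled pyramid cases
#'
#' Stage 1 trains the primary tier alone with cross-entropy on image-level
#' labels (weak supervision; lesion masks are never consumed). The primary
#' tier is then frozen, its Grad-CAM map is computed once per case for the
#' injury class, and stage 2 trains the secondary and tertiary tiers plus the
#' LAM with the cascade loss
#' `lambdaPrimary * CE(primary) [frozen, reported] + lambdaFinal * CE(tertiary)`.
#'
#' @param cases list of [PhantomCase-class] (or any objects with `lowRes`,
#'   `midRes`, `highRes`, `caseLabel` methods); both classes must be present.
#' @param config from [cascadeConfig()] / [tinyCascadeConfig()].
#' @return trained `cpcnnModel`; `$log` holds per-epoch losses.
#' @export
trainCascade <- function(cases, config = tinyCascadeConfig()) {
  labels <- vapply(cases, caseLabel, integer(1))
  if (length(unique(labels)) < 2L)
    stop("training needs both classes; got only label ", unique(labels))
  model <- buildCascade(config)
  lows <- caseLevels(cases, "low")
  n <- length(cases)
  log <- list()
  velP <- list()
  # --- stage 1: primary tier alone -----------------------------------------
  for (epoch in seq_len(config$epochsStage1)) {
    lr <- cosineLr(config$lr, epoch, config$epochsStage1)
    losses <- c()
    for (b in batchIndices(n, config$batchSize, streamSeed(config$seed, 1000L + epoch))) {
      x <- stackImages(lows[b])
      fw <- tierForward(model$primary, x, train = TRUE)
      model$primary <- fw$tier
      ls <- softmaxCELoss(fw$scores$logits, labels[b])
      checkFinite(ls$loss, "stage 1", epoch)
      losses <- c(losses, ls$loss)
      hb <- headBackward(model$primary, fw$caches$head, ls$dlogits)
      bb <- blocksBackward(model$primary, fw$caches$blocks, hb$dx,
                           from = length(model$primary$blocks), to = 1L,
                           needDx = TRUE)
      sb <- stemBackward(model$primary, fw$caches$stem, bb$dx)
      grads <- c(sb$grads, list(fc = hb$grads$fc, blocks = bb$grads$blocks))
      up <- sgdUpdate(model$primary, grads, velP, lr, config$momentum)
      model$primary <- up$params; velP <- up$vel
    }
    log[[length(log) + 1L]] <- data.frame(stage = 1L, epoch = epoch,
                                          loss = mean(losses),
                                          lossPrimary = mean(losses), lr = lr)
  }
  # --- frozen primary: one localization map per case -----------------------
  locs <- lapply(lows, function(img)
    localize(model$primary, img, classIndex = 1L)$map@values)
  # --- stage 2: secondary + tertiary + LAM ---------------------------------
  mids <- caseLevels(cases, "mid")
  highs <- caseLevels(cases, "high")
  vel2 <- list()
  for (epoch in seq_len(config$epochsStage2)) {
    lr <- cosineLr(config$lr, epoch, config$epochsStage2)
    losses <- c(); lossesP <- c()
    for (b in batchIndices(n, config$batchSize, streamSeed(config$seed, 2000L + epoch))) {
      fw <- cascadeForwardBatch(model, lows[b], mids[b], highs[b],
                                train = TRUE, locs = locs[b])
      model <- fw$model
      ls <- softmaxCELoss(fw$scores$logits, labels[b])
      lsP <- softmaxCELoss(fw$primaryScores$logits, labels[b])
      total <- config$lambdaFinal * ls$loss + config$lambdaPrimary * lsP$loss
      checkFinite(total, "stage 2", epoch)
      losses <- c(losses, total); lossesP <- c(lossesP, lsP$loss)
      dlogitsAux <- NULL
      if (!is.null(model$auxHead)) {
        lsA <- softmaxCELoss(fw$auxScores$logits, labels[b])
        dlogitsAux <- config$lambdaAux * lsA$dlogits
      }
      grads <- cascadeBackwardBatch(model, fw,
                                    config$lambdaFinal * ls$dlogits,
                                    dlogitsAux)
      sub <- list(secondary = model$secondary, tertiary = model$tertiary,
                  lam = model$lam, auxHead = model$auxHead)
      up <- sgdUpdate(sub, clipGrads(grads, config$clipNorm), vel2, lr,
                      config$momentum)
      model[names(up$params)] <- up$params
      vel2 <- up$vel
    }
    log[[length(log) + 1L]] <- data.frame(stage = 2L, epoch = epoch,
                                          loss = mean(losses),
                                          lossPrimary = mean(lossesP), lr = lr)
  }
  model$log <- do.call(rbind, log)
  model$trained <- TRUE
  model
}

#' Predict a set of cases with a trained cascade
#'
#' @param model trained `cpcnnModel`.
#' @param cases list of [PhantomCase-class] / [PyramidImage-class].
#' @param withMaps also compute per-case localization maps (predicted class).
#' @param locZero ablation: replace the localization map by zeros, making the
#'   location attention an identity.
#' @return data frame `caseId, prob, label`; when `withMaps = TRUE` the
#'   localization maps are attached as `attr(, "maps")`.
#' @export
predictCascade <- function(model, cases, withMaps = FALSE, locZero = FALSE) {
  pyrs <- lapply(cases, function(cs) if (is(cs, "PhantomCase")) cs@pyramid else cs)
  n <- length(pyrs)
  bs <- model$config$batchSize
  probs <- numeric(n)
  maps <- if (withMaps) vector("list", n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / bs))) {
    fw <- cascadeForwardBatch(model, lapply(pyrs[b], lowRes),
                              lapply(pyrs[b], midRes),
                              lapply(pyrs[b], highRes),
                              train = FALSE, cache = FALSE, locZero = locZero)
    probs[b] <- fw$scores$probs[2, ]
    if (withMaps) for (i in seq_along(b)) maps[[b[i]]] <- fw$locs[[i]]
  }
  out <- data.frame(caseId = vapply(pyrs, caseId, character(1)),
                    prob = probs,
                    label = as.integer(probs >= model$config$threshold),
                    stringsAsFactors = FALSE)
  if (withMaps) attr(out, "maps") <- maps
  out
}

#' @export
print.cpcnnModel <- function(x, ...) {
  cat(sprintf("C-PCNN model: base %dx%d, width x%g, repeats (%s), %s\n",
              x$config$baseSize[1], x$config$baseSize[2],
              x$config$widthMultiplier,
              paste(x$config$repeats, collapse = ","),
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  parameters: %s\n", format(countParams(x), big.mark = ",")))
  invisible(x)
}

countParams <- function(obj) {
  if (is.numeric(obj)) return(length(obj))
  if (!is.list(obj)) return(0L)
  total <- 0L
  for (nm in seq_along(obj)) {
    el <- obj[[nm]]
    lbl <- names(obj)[nm]
    if (is.numeric(el) && !is.null(lbl) && lbl %in% TRAINABLE)
      total <- total + length(el)
    else if (is.list(el)) total <- total + countParams(el)
  }
  total
}
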