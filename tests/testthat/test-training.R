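test_that("the reconstruction loss matches its closed form", {
  lg <- retinaseg:::mse_loss_grad(array(0, c(2, 2, 1)), rbind(c(1, 0), c(0, 0)))
  expect_equal(lg$loss, 0.25)
  expect_equal(lg$dout[1, 1, 1], 2 * (0 - 1) / 4)
})

test_that("training configuration validation catches bad values", {
  expect_error(trainConfig(iterations = 0L), "iterations")
  expect_error(trainConfig(learningRate = 0), "learningRate")
  expect_error(trainConfig(freeze = "cnn"), "unknown family")
})

test_that("pretrainStep updates trainable parameters and lowers loss on a fixed batch", {
  cfg <- micro_config(seed = 1L)
  model <- buildModel(cfg)
  set.seed(2)
  imgs <- lapply(1:2, function(i) matrix(runif(256), 16, 16))
  aug <- augmentationConfig(probMask = 1)
  batch <- lapply(imgs, makeAugmentedPair, config = aug)
  tc <- trainConfig(iterations = 20L, batchSize = 2L, learningRate = 0.05,
                    loss = "mse", seed = 3L)
  state <- newOptimizerState(tc)
  losses <- numeric(20)
  for (it in 1:20) {
    stp <- pretrainStep(model, batch, state)
    model <- stp$model; state <- stp$state; losses[it] <- stp$loss
  }
  expect_lt(losses[20], losses[1])
  expect_error(pretrainStep(model, list(), state), "non-empty")
})

test_that("the pre-training loop records one loss per iteration, deterministically", {
  spec <- tiny_spec(seed = 2L)
  spec$imageSize <- 16L
  corpus <- generatePretrainCorpus(4, spec)
  model <- buildModel(micro_config(seed = 4L))
  tc <- trainConfig(iterations = 10L, batchSize = 2L, learningRate = 0.05,
                    loss = "mse", seed = 5L)
  aug <- augmentationConfig(maskSize = 4L)
  ck1 <- runPretraining(corpus, model, tc, aug)
  expect_length(lossHistory(ck1), 10L)
  expect_identical(ck1@iteration, 10L)
  ck2 <- runPretraining(corpus, model, tc, aug)
  expect_identical(lossHistory(ck1), lossHistory(ck2))
  expect_identical(modelParams(ck1), modelParams(ck2))
  expect_error(runPretraining(list(), model, tc, aug), "non-empty")
})

test_that("transformer transfer is bit-exact and touches nothing else", {
  src <- buildModel(micro_config(seed = 6L))
  dst <- buildModel(micro_config(seed = 7L))
  before <- modelParams(dst)
  out <- transferTransformerParams(src, dst)
  fams <- paramFamilies(out)
  for (nm in fams$transformer)
    expect_identical(modelParams(out)[[nm]], modelParams(src)[[nm]])
  for (nm in c(fams$conv_encoder, fams$decoder, fams$head))
    expect_identical(modelParams(out)[[nm]], before[[nm]])
  ## mismatched embedding width is rejected with the parameter named
  big <- buildModel(modelConfig(inputSize = 16L, convChannels = c(4L, 6L),
                                patchSize = 2L, embedDim = 16L, nLayers = 2L,
                                nHeads = 2L, mlpDim = 16L,
                                decoderChannels = c(8L, 6L, 4L), seed = 8L))
  expect_error(transferTransformerParams(src, big), "embed.W|shape")
})

test_that("frozen families stay bit-identical through fine-tuning updates", {
  spec <- syntheticSpec(imageSize = 16L, volumeShape = c(8L, 16L, 16L),
                        nClasses = 1L, objectScale = c(2, 4), seed = 3L)
  pair <- generateLabeledVolume(spec)
  ds <- sliceDataset(pair)
  model <- buildModel(micro_config(nClasses = 2L, seed = 9L))
  start <- modelParams(model)
  tc <- trainConfig(iterations = 15L, batchSize = 2L, learningRate = 0.05,
                    loss = "ce_dice", freeze = "transformer",
                    augment = "none", seed = 10L)
  ck <- runFinetuning(ds, model, tc)
  fams <- paramFamilies(model)
  for (nm in fams$transformer)
    expect_identical(modelParams(ck)[[nm]], start[[nm]])
  changed <- vapply(fams$conv_encoder, function(nm)
    !identical(modelParams(ck)[[nm]], start[[nm]]), TRUE)
  expect_true(all(changed))

  ## freezing everything leaves the loss constant (fixed single-slice batch)
  ds1 <- list(images = ds$images[1], labels = ds$labels[1])
  tc_all <- trainConfig(iterations = 5L, batchSize = 1L, learningRate = 0.05,
                        loss = "ce", augment = "none",
                        freeze = c("conv_encoder", "transformer", "decoder",
                                   "head"), seed = 11L)
  ck_all <- runFinetuning(ds1, model, tc_all)
  expect_lt(diff(range(lossHistory(ck_all))), 1e-12)
  for (nm in names(start))
    expect_identical(modelParams(ck_all)[[nm]], start[[nm]])

  ## no freezing: every family moves under nonzero gradients
  tc_none <- trainConfig(iterations = 15L, batchSize = 2L,
                         learningRate = 0.05, loss = "ce_dice",
                         augment = "none", seed = 12L)
  ck_none <- runFinetuning(ds, model, tc_none)
  for (fam in names(fams)) {
    fam_names <- setdiff(fams[[fam]], c("head.recon.W", "head.recon.b"))
    moved <- vapply(fam_names, function(nm)
      !identical(modelParams(ck_none)[[nm]], start[[nm]]), TRUE)
    expect_true(any(moved), label = sprintf("family %s moved", fam))
  }

  expect_error(setTrainable(model, "bogus"), "unknown family")
})

test_that("fine-tuning validates labels and composes transfer with freezing", {
  model <- buildModel(micro_config(nClasses = 2L, seed = 13L))
  bad <- list(images = list(matrix(0.5, 16, 16), matrix(0.5, 16, 16)),
              labels = list(matrix(0L, 16, 16), matrix(5L, 16, 16)))
  expect_error(runFinetuning(bad, model,
                             trainConfig(iterations = 1L, augment = "none")),
               "slice 2")

  spec <- syntheticSpec(imageSize = 16L, volumeShape = c(8L, 16L, 16L),
                        nClasses = 1L, objectScale = c(2, 4), seed = 5L)
  ds <- sliceDataset(generateLabeledVolume(spec))
  pre <- runPretraining(generatePretrainCorpus(2, spec), model,
                        trainConfig(iterations = 3L, batchSize = 1L,
                                    learningRate = 0.05, loss = "mse",
                                    seed = 1L),
                        augmentationConfig(maskSize = 4L))
  tc <- trainConfig(iterations = 8L, batchSize = 1L, learningRate = 0.05,
                    freeze = "transformer", augment = "none", seed = 2L)
  ck <- runFinetuning(ds, model, tc, source = pre)
  expect_length(lossHistory(ck), 8L)
  for (nm in paramFamilies(model)$transformer)
    expect_identical(modelParams(ck)[[nm]], modelParams(pre)[[nm]])
})

test_that("checkpoints restore into models with shape checking", {
  model <- buildModel(micro_config(seed = 14L))
  spec <- syntheticSpec(imageSize = 16L, seed = 1L)
  ck <- runPretraining(generatePretrainCorpus(2, spec), model,
                       trainConfig(iterations = 2L, batchSize = 1L,
                                   learningRate = 0.01, loss = "mse",
                                   seed = 1L),
                       augmentationConfig(maskSize = 4L))
  m2 <- modelFromCheckpoint(ck)
  expect_identical(modelParams(m2), modelParams(ck))
  other <- buildModel(micro_config(nClasses = 5L, seed = 1L))
  expect_error(applyCheckpoint(other, ck), "parameter")
})
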