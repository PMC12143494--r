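test_that("configuration validation rejects inverted ranges and bad probabilities", {
  expect_error(augmentationConfig(probFlip = 1.5), "probabilities")
  expect_error(augmentationConfig(brightnessRange = c(0.2, -0.2)), "min <= max")
  expect_error(augmentationConfig(maskCountRange = c(0L, 32L)), ">= 1")
})

test_that("record sampling follows the configured distributions", {
  ## degenerate probability: nothing fires
  cfg0 <- augmentationConfig(probFlip = 0, probRotate = 0, probMask = 0)
  set.seed(1)
  recs <- replicate(100, sampleAugmentRecords(cfg0, 64L), simplify = FALSE)
  expect_true(all(!vapply(recs, function(r) r$geometric$flip_h, TRUE)))
  expect_true(all(!vapply(recs, function(r) r$geometric$flip_v, TRUE)))
  expect_true(all(vapply(recs, function(r) r$geometric$rot90_k, 0L) == 0L))

  ## flip frequency at probability 0.5
  cfg <- augmentationConfig()
  set.seed(42)
  fh <- vapply(seq_len(10000), function(i)
    sampleAugmentRecords(cfg, 64L)$geometric$flip_h, TRUE)
  expect_gte(mean(fh), 0.48)
  expect_lte(mean(fh), 0.52)

  ## mask count uniform on 1..32 when masking always fires
  cfgm <- augmentationConfig(probMask = 1)
  set.seed(7)
  counts <- vapply(seq_len(10000), function(i)
    nrow(sampleAugmentRecords(cfgm, 64L)$corruption$mask_patches), 1L)
  expect_identical(range(counts), c(1L, 32L))
  chi <- stats::chisq.test(table(factor(counts, levels = 1:32)))
  expect_gt(chi$p.value, 0.01)
})

test_that("geometric transforms follow the documented order and invert exactly", {
  m <- matrix(1:12, 3, 4)
  idr <- list(flip_h = FALSE, flip_v = FALSE, rot90_k = 0L)
  expect_identical(applyGeometric(m, idr), m)
  fh <- list(flip_h = TRUE, flip_v = FALSE, rot90_k = 0L)
  expect_identical(applyGeometric(applyGeometric(m, fh), fh), m)
  ## hand-derived quarter turn: [[1,2],[3,4]] -> [[2,4],[1,3]]
  r1 <- list(flip_h = FALSE, flip_v = FALSE, rot90_k = 1L)
  expect_identical(applyGeometric(rbind(c(1, 2), c(3, 4)), r1),
                   rbind(c(2, 4), c(1, 3)))
  expect_error(applyGeometric(array(0, c(2, 2, 2)), idr), "2D")

  ## invertibility over random records (square image)
  set.seed(3)
  img <- matrix(runif(64), 8, 8)
  for (i in 1:50) {
    rec <- list(flip_h = runif(1) < 0.5, flip_v = runif(1) < 0.5,
                rot90_k = sample(0:3, 1))
    expect_identical(invertGeometric(applyGeometric(img, rec), rec), img)
  }
})

test_that("corruption applies brightness, masking and clipping as specified", {
  neutral <- list(brightness_delta = 0, contrast_gain = 1, noise_sd = 0,
                  blur_sd = 0, mask_patches = NULL, fill_value = 0,
                  noise_seed = 1L)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(corruptImage(img, neutral), img)

  bright <- neutral; bright$brightness_delta <- 0.1
  expect_equal(corruptImage(matrix(0.5, 4, 4), bright), matrix(0.6, 4, 4))

  ## one 16x16 patch: exactly 256 pixels at fill value, others untouched
  rec <- neutral
  rec$mask_patches <- cbind(row = 10L, col = 20L, size = 16L)
  rec$fill_value <- 0
  img224 <- matrix(runif(224 * 224, min = 0.2, max = 0.9), 224, 224)
  out <- corruptImage(img224, rec)
  changed <- which(out != img224)
  expect_length(changed, 256L)
  expect_true(all(out[changed] == 0))
  ## out-of-bounds patch is rejected
  bad <- rec; bad$mask_patches <- cbind(row = 215L, col = 1L, size = 16L)
  expect_error(corruptImage(img224, bad), "outside")

  ## results always clipped to [0,1]
  hot <- neutral; hot$brightness_delta <- 0.9
  expect_lte(max(corruptImage(img, hot)), 1)
})

test_that("pairs satisfy the alignment and locality invariants", {
  set.seed(11)
  img <- matrix(runif(64 * 64), 64, 64)
  cfg <- augmentationConfig()
  for (i in 1:100) {
    pair <- makeAugmentedPair(img, cfg)
    expect_identical(targetImage(pair),
                     applyGeometric(img, geometricRecord(pair)))
    expect_identical(invertGeometric(targetImage(pair), geometricRecord(pair)),
                     img)
    expect_gte(min(inputImage(pair)), 0)
    expect_lte(max(inputImage(pair)), 1)
  }

  ## replay from stored records is bit-exact
  set.seed(12)
  pair <- makeAugmentedPair(img, cfg)
  re <- replayAugmentedPair(img, geometricRecord(pair), corruptionRecord(pair))
  expect_identical(inputImage(re), inputImage(pair))
  expect_identical(targetImage(re), targetImage(pair))

  ## with all corruption disabled the input equals the target
  cfg_off <- augmentationConfig(probBrightness = 0, probContrast = 0,
                                probNoise = 0, probBlur = 0, probMask = 0)
  set.seed(13)
  p0 <- makeAugmentedPair(img, cfg_off)
  expect_identical(inputImage(p0), targetImage(p0))

  ## corruption locality: masking only -> pixels outside patches untouched
  cfg_mask <- augmentationConfig(probBrightness = 0, probContrast = 0,
                                 probNoise = 0, probBlur = 0, probMask = 1,
                                 maskSize = 8L)
  set.seed(14)
  pm <- makeAugmentedPair(img, cfg_mask)
  diffpix <- inputImage(pm) != targetImage(pm)
  mp <- corruptionRecord(pm)$mask_patches
  inpatch <- matrix(FALSE, 64, 64)
  for (i in seq_len(nrow(mp)))
    inpatch[mp[i, "row"] + 0:(mp[i, "size"] - 1),
            mp[i, "col"] + 0:(mp[i, "size"] - 1)] <- TRUE
  expect_true(all(!diffpix | inpatch))
})

test_that("seeded pair generation is reproducible", {
  img <- matrix(runif(64 * 64), 64, 64)
  cfg <- augmentationConfig()
  set.seed(99)
  a <- makeAugmentedPair(img, cfg)
  set.seed(99)
  b <- makeAugmentedPair(img, cfg)
  expect_identical(inputImage(a), inputImage(b))
  expect_identical(geometricRecord(a), geometricRecord(b))
})
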