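test_that("configuration invariants are enforced with named offenders", {
  expect_error(modelConfig(inputSize = 100L, convChannels = c(8L, 16L),
                           patchSize = 2L, embedDim = 32L, nHeads = 2L,
                           decoderChannels = c(16L, 16L, 8L)),
               "inputSize")
  expect_error(modelConfig(inputSize = 64L, convChannels = c(8L, 16L),
                           patchSize = 2L, embedDim = 30L, nHeads = 4L,
                           decoderChannels = c(16L, 16L, 8L)),
               "nHeads")
  expect_error(modelConfig(inputSize = 64L, convChannels = c(8L, 16L),
                           patchSize = 2L, embedDim = 32L, nHeads = 2L,
                           decoderChannels = c(16L, 8L)),
               "decoderChannels")
})

test_that("token grid size follows (inputSize / 2^stages / patchSize)^2", {
  cfg <- modelConfig(inputSize = 64L, convChannels = c(8L, 16L),
                     patchSize = 2L, embedDim = 32L, nLayers = 1L,
                     nHeads = 2L, mlpDim = 32L,
                     decoderChannels = c(16L, 16L, 8L))
  expect_identical(cfg$nTokens, 64L)  # (64/4/2)^2
  ## property: formula holds across valid configurations
  for (ps in c(1L, 2L)) for (nstage in 1:2) {
    ch <- rep(4L, nstage)
    nup <- nstage + as.integer(log2(ps))
    cfg2 <- modelConfig(inputSize = 32L, convChannels = ch, patchSize = ps,
                        embedDim = 8L, nLayers = 1L, nHeads = 2L,
                        mlpDim = 16L, decoderChannels = rep(8L, nup))
    expect_identical(cfg2$nTokens,
                     as.integer((32 / 2^nstage / ps)^2))
  }
})

test_that("building is deterministic and families partition all parameters", {
  m1 <- buildModel(micro_config(seed = 5L))
  m2 <- buildModel(micro_config(seed = 5L))
  expect_identical(modelParams(m1), modelParams(m2))
  m3 <- buildModel(micro_config(seed = 6L))
  expect_false(identical(modelParams(m1), modelParams(m3)))

  fams <- paramFamilies(m1)
  all_names <- unlist(fams, use.names = FALSE)
  expect_identical(sort(all_names), sort(names(modelParams(m1))))
  expect_identical(anyDuplicated(all_names), 0L)
  ## transformer family includes embedding, positional and final-norm weights
  expect_true(all(c("embed.W", "pos", "lnf.g") %in% fams$transformer))
})

test_that("encode produces the contracted token and skip shapes deterministically", {
  m <- buildModel(micro_config(seed = 1L))
  imgs <- lapply(1:3, function(i) matrix(runif(256), 16, 16))
  enc <- encodeImages(m, imgs)
  expect_identical(dim(enc$tokens), c(3L, 4L, 8L))  # (16/4/2)^2 = 4 tokens
  expect_length(enc$skips, 2L)                       # one per conv stage
  expect_identical(dim(enc$skips[[1]]), c(3L, 16L, 16L, 4L))
  expect_identical(dim(enc$skips[[2]]), c(3L, 8L, 8L, 6L))
  enc2 <- encodeImages(m, imgs)
  expect_identical(enc$tokens, enc2$tokens)
  expect_error(encodeImages(m, matrix(0, 8, 8)), "size")
})

test_that("decode restores full resolution and actually uses the skips", {
  m <- buildModel(micro_config(seed = 2L))
  img <- matrix(runif(256), 16, 16)
  enc <- encodeImages(m, img)
  dec <- decodeTokens(m, enc$tokens, enc$skips)
  expect_identical(dim(dec), c(1L, 16L, 16L, 4L))
  expect_true(all(is.finite(dec)))
  zskips <- lapply(enc$skips, function(s) array(0, dim(s)))
  dec0 <- decodeTokens(m, enc$tokens, zskips)
  expect_gt(max(abs(dec - dec0)), 1e-8)
  expect_error(decodeTokens(m, array(0, c(1, 9, 8)), enc$skips), "tokens")
})

test_that("reconstruction preserves shape and is deterministic", {
  m <- buildModel(micro_config(seed = 3L))
  img <- matrix(runif(256), 16, 16)
  r1 <- reconstructImages(m, img)
  expect_identical(dim(r1), c(1L, 16L, 16L))
  expect_identical(r1, reconstructImages(m, img))
})

test_that("segmentation scores are per-pixel distributions", {
  m <- buildModel(micro_config(nClasses = 4L, seed = 4L))
  img <- matrix(runif(256), 16, 16)
  pr <- segmentImages(m, img)
  expect_identical(dim(pr), c(1L, 4L, 16L, 16L))
  sums <- apply(pr[1, , , ], c(2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  lab <- apply(pr[1, , , ], c(2, 3), which.max) - 1L
  expect_true(all(lab %in% 0:3))
})

test_that("hand-written backpropagation matches numerical gradients", {
  cfg <- micro_config(nClasses = 3L, seed = 9L)
  m <- buildModel(cfg)
  P <- modelParams(m)
  set.seed(20)
  x <- matrix(runif(256), 16, 16)
  tgt <- matrix(runif(256), 16, 16)
  fw <- retinaseg:::net_forward(P, cfg, x, "recon")
  dout <- array(2 * (fw$out[, , 1] - tgt) / 256, c(16, 16, 1))
  G <- retinaseg:::net_backward(P, cfg, fw$cache, dout)
  loss_at <- function(P) {
    r <- retinaseg:::net_forward(P, cfg, x, "recon")$out[, , 1]
    mean((r - tgt)^2)
  }
  eps <- 1e-5
  for (nm in c("enc.s1.a.W", "enc.s2.b.W", "embed.W", "pos", "blk1.q.W",
               "blk2.fc1.W", "blk1.ln1.g", "lnf.b", "dec.s2.W",
               "head.recon.W")) {
    i <- sample(length(P[[nm]]), 1)
    Pp <- P; Pp[[nm]][i] <- Pp[[nm]][i] + eps
    Pm <- P; Pm[[nm]][i] <- Pm[[nm]][i] - eps
    num <- (loss_at(Pp) - loss_at(Pm)) / (2 * eps)
    expect_lt(abs(num - G[[nm]][i]) / max(1e-6, abs(num), abs(G[[nm]][i])),
              1e-4)
  }
})
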