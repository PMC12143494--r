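#' Model configuration
#'
#' Defines the hybrid CNN--transformer encoder--decoder.  Each convolutional
#' stage is a stride-1 feature conv (whose output feeds the matching skip
#' connection) followed by a stride-2 downsampling conv, so `length(convChannels)`
#' stages downsample by `2^length(convChannels)`.  The final feature map is
#' tokenised by a learned linear patch embedding over `patchSize` x
#' `patchSize` cells, refined by `nLayers` pre-norm transformer blocks, and
#' progressively upsampled by the decoder with skip concatenation at
#' matching resolutions.
#'
#' @param inputSize square input side in pixels; must be divisible by
#'   `2^length(convChannels) * patchSize`.
#' @param convChannels integer vector of per-stage channel counts.
#' @param patchSize cells per token side on the conv feature map (power of 2).
#' @param embedDim token width; divisible by `nHeads`.
#' @param nLayers transformer block count.
#' @param nHeads attention heads.
#' @param mlpDim hidden width of the transformer MLP.
#' @param decoderChannels channel schedule of the upsampling decoder; its
#'   length must equal `log2(inputSize / tokenGridSize)` so the decoder
#'   reaches full resolution.
#' @param nClasses segmentation classes (>= 2; binary tasks use 2 with
#'   softmax so one code path serves binary and multiclass).
#' @param seed initialisation seed.
#' @return validated configuration list.
#' @examples
#' cfg <- modelConfig(inputSize = 64, convChannels = c(8, 16), embedDim = 32,
#'                    nHeads = 2, nLayers = 2, mlpDim = 64,
#'                    decoderChannels = c(16, 16, 8))
#' @export
modelConfig <- function(inputSize = 224L, convChannels = c(32L, 64L, 128L),
                        patchSize = 2L, embedDim = 256L, nLayers = 6L,
                        nHeads = 8L, mlpDim = 512L,
                        decoderChannels = c(128L, 64L, 32L, 16L),
                        nClasses = 2L, seed = 0L) {
  S <- length(convChannels)
  down <- 2^S * patchSize
  if (log2(patchSize) != floor(log2(patchSize)))
    stopf("patchSize must be a power of 2, got %s", patchSize)
  if (inputSize %% down != 0)
    stopf("inputSize (%d) must be divisible by 2^length(convChannels) * patchSize = %d",
          inputSize, down)
  if (embedDim %% nHeads != 0)
    stopf("embedDim (%d) must be divisible by nHeads (%d)", embedDim, nHeads)
  grid <- as.integer(inputSize %/% down)
  nUp <- as.integer(round(log2(inputSize / grid)))
  if (length(decoderChannels) != nUp)
    stopf("decoderChannels must have length %d (= stages + log2(patchSize)) to reach full resolution, got %d",
          nUp, length(decoderChannels))
  if (nClasses < 2) stopf("nClasses must be >= 2 (binary tasks use 2 + softmax)")
  cfg <- list(inputSize = as.integer(inputSize),
              convChannels = as.integer(convChannels),
              patchSize = as.integer(patchSize),
              embedDim = as.integer(embedDim), nLayers = as.integer(nLayers),
              nHeads = as.integer(nHeads), mlpDim = as.integer(mlpDim),
              decoderChannels = as.integer(decoderChannels),
              nClasses = as.integer(nClasses), seed = as.integer(seed),
              grid = grid, nTokens = as.integer(grid * grid))
  ## decoder plan: resolution after each x2 upsample, and which encoder stage
  ## (if any) supplies a skip at that resolution
  stageRes <- inputSize / 2^(seq_len(S) - 1L)       # stage skip resolutions
  plan <- vector("list", nUp)
  prevCh <- cfg$embedDim
  for (j in seq_len(nUp)) {
    res <- grid * 2^j
    sk <- which(stageRes == res)
    inCh <- prevCh + if (length(sk)) convChannels[sk] else 0L
    plan[[j]] <- list(res = res, skip = if (length(sk)) sk else NA_integer_,
                      inCh = inCh, outCh = cfg$decoderChannels[j])
    prevCh <- cfg$decoderChannels[j]
  }
  cfg$plan <- plan
  attr(cfg, "retinaModelConfig") <- TRUE
  cfg
}

#' Tiny model configuration for desk-scale runs
#'
#' A small preset (64-pixel input, two conv stages, two transformer blocks)
#' that trains in seconds on a CPU; the full pipeline is exercised end to
#' end at this scale in the tests and examples.
#'
#' @param nClasses segmentation classes.
#' @param seed initialisation seed.
#' @return a [modelConfig()] list.
#' @export
tinyModelConfig <- function(nClasses = 2L, seed = 0L) {
  modelConfig(inputSize = 64L, convChannels = c(16L, 32L), patchSize = 2L,
              embedDim = 32L, nLayers = 2L, nHeads = 2L, mlpDim = 64L,
              decoderChannels = c(32L, 32L, 16L), nClasses = nClasses,
              seed = seed)
}

## He-normal conv weight (9*cin x cout); xavier for linear layers.
rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

init_params <- function(cfg) {
  p <- list(); fam <- list(conv_encoder = character(), transformer = character(),
                           decoder = character(), head = character())
  add <- function(name, value, family) {
    p[[name]] <<- value
    fam[[family]] <<- c(fam[[family]], name)
  }
  cin <- 1L
  for (i in seq_along(cfg$convChannels)) {
    co <- cfg$convChannels[i]
    add(sprintf("enc.s%d.a.W", i), rnorm_mat(9L * cin, co, sqrt(2 / (9 * cin))),
        "conv_encoder")
    add(sprintf("enc.s%d.a.b", i), numeric(co), "conv_encoder")
    add(sprintf("enc.s%d.b.W", i), rnorm_mat(9L * co, co, sqrt(2 / (9 * co))),
        "conv_encoder")
    add(sprintf("enc.s%d.b.b", i), numeric(co), "conv_encoder")
    cin <- co
  }
  pd <- cfg$patchSize^2 * cin
  D <- cfg$embedDim
  add("embed.W", rnorm_mat(pd, D, sqrt(2 / (pd + D))), "transformer")
  add("embed.b", numeric(D), "transformer")
  add("pos", rnorm_mat(cfg$nTokens, D, 0.02), "transformer")
  for (l in seq_len(cfg$nLayers)) {
    pre <- sprintf("blk%d.", l)
    add(paste0(pre, "ln1.g"), rep(1, D), "transformer")
    add(paste0(pre, "ln1.b"), numeric(D), "transformer")
    for (nm in c("q", "k", "v", "o")) {
      add(paste0(pre, nm, ".W"), rnorm_mat(D, D, sqrt(1 / D)), "transformer")
      add(paste0(pre, nm, ".b"), numeric(D), "transformer")
    }
    add(paste0(pre, "ln2.g"), rep(1, D), "transformer")
    add(paste0(pre, "ln2.b"), numeric(D), "transformer")
    add(paste0(pre, "fc1.W"), rnorm_mat(D, cfg$mlpDim, sqrt(2 / (D + cfg$mlpDim))),
        "transformer")
    add(paste0(pre, "fc1.b"), numeric(cfg$mlpDim), "transformer")
    add(paste0(pre, "fc2.W"), rnorm_mat(cfg$mlpDim, D, sqrt(2 / (D + cfg$mlpDim))),
        "transformer")
    add(paste0(pre, "fc2.b"), numeric(D), "transformer")
  }
  add("lnf.g", rep(1, D), "transformer")
  add("lnf.b", numeric(D), "transformer")
  for (j in seq_along(cfg$plan)) {
    pl <- cfg$plan[[j]]
    add(sprintf("dec.s%d.W", j),
        rnorm_mat(9L * pl$inCh, pl$outCh, sqrt(2 / (9 * pl$inCh))), "decoder")
    add(sprintf("dec.s%d.b", j), numeric(pl$outCh), "decoder")
  }
  cl <- cfg$decoderChannels[length(cfg$decoderChannels)]
  add("head.recon.W", rnorm_mat(cl, 1L, 0.01), "head")
  add("head.recon.b", numeric(1L), "head")
  add("head.seg.W", rnorm_mat(cl, cfg$nClasses, 0.01), "head")
  add("head.seg.b", numeric(cfg$nClasses), "head")
  list(params = p, families = fam)
}

#' Build the hybrid segmentation model
#'
#' Instantiates all parameters (seeded, deterministic) and their family
#' partition.  Two builds from the same configuration are bit-identical.
#'
#' @param config a [modelConfig()] list.
#' @return a [SegModel-class] object.
#' @examples
#' m <- buildModel(tinyModelConfig())
#' lengths(paramFamilies(m))
#' @export
buildModel <- function(config) {
  if (!isTRUE(attr(config, "retinaModelConfig")))
    stopf("config must come from modelConfig()")
  ini <- with_seed(config$seed, init_params(config))
  methods::new("SegModel", config = config, params = ini$params,
               families = ini$families)
}

## ---- forward / backward ---------------------------------------------------

## Patch-embedding permutation: (p*g, p*g, C) feature map -> (g^2, p^2*C)
## matrix, tokens ordered column-major over the (row, col) token grid.
tokenize <- function(f, p, g) {
  C <- dim(f)[3]
  a <- array(f, c(p, g, p, g, C))
  a <- aperm(a, c(2L, 4L, 1L, 3L, 5L))
  matrix(a, g * g, p * p * C)
}

untokenize <- function(m, p, g, C) {
  a <- array(m, c(g, g, p, p, C))
  a <- aperm(a, c(3L, 1L, 4L, 2L, 5L))
  array(a, c(p * g, p * g, C))
}

## Full forward pass on one image (matrix H x W); returns output plus caches.
net_forward <- function(P, cfg, x, head = c("recon", "seg")) {
  head <- match.arg(head)
  cc <- list()
  h <- array(x, c(dim(x), 1L))
  skips <- vector("list", length(cfg$convChannels))
  for (i in seq_along(cfg$convChannels)) {
    a <- conv2d_fwd(h, P[[sprintf("enc.s%d.a.W", i)]],
                    P[[sprintf("enc.s%d.a.b", i)]], 1L)
    ra <- relu_fwd(a$out)
    b <- conv2d_fwd(ra$out, P[[sprintf("enc.s%d.b.W", i)]],
                    P[[sprintf("enc.s%d.b.b", i)]], 2L)
    rb <- relu_fwd(b$out)
    skips[[i]] <- ra$out
    cc[[sprintf("s%d", i)]] <- list(a = a$cache, ra = ra$cache,
                                    b = b$cache, rb = rb$cache)
    h <- rb$out
  }
  p <- cfg$patchSize; g <- cfg$grid
  cc$fmapC <- dim(h)[3]
  tokm <- tokenize(h, p, g)
  emb <- linear_fwd(tokm, P$embed.W, P$embed.b)
  t <- emb$out + P$pos
  cc$tokm <- tokm
  blocks <- vector("list", cfg$nLayers)
  for (l in seq_len(cfg$nLayers)) {
    pre <- sprintf("blk%d.", l)
    ln1 <- layernorm_fwd(t, P[[paste0(pre, "ln1.g")]], P[[paste0(pre, "ln1.b")]])
    att <- attention_fwd(ln1$out,
                         list(q.W = P[[paste0(pre, "q.W")]], q.b = P[[paste0(pre, "q.b")]],
                              k.W = P[[paste0(pre, "k.W")]], k.b = P[[paste0(pre, "k.b")]],
                              v.W = P[[paste0(pre, "v.W")]], v.b = P[[paste0(pre, "v.b")]],
                              o.W = P[[paste0(pre, "o.W")]], o.b = P[[paste0(pre, "o.b")]]),
                         cfg$nHeads)
    t1 <- t + att$out
    ln2 <- layernorm_fwd(t1, P[[paste0(pre, "ln2.g")]], P[[paste0(pre, "ln2.b")]])
    f1 <- linear_fwd(ln2$out, P[[paste0(pre, "fc1.W")]], P[[paste0(pre, "fc1.b")]])
    ge <- gelu_fwd(f1$out)
    f2 <- linear_fwd(ge$out, P[[paste0(pre, "fc2.W")]], P[[paste0(pre, "fc2.b")]])
    blocks[[l]] <- list(ln1 = ln1$cache, att = att$cache, ln2 = ln2$cache,
                        f1 = f1$cache, ge = ge$cache, f2 = f2$cache)
    t <- t1 + f2$out
  }
  lnf <- layernorm_fwd(t, P$lnf.g, P$lnf.b)
  tokens <- lnf$out
  cc$blocks <- blocks
  cc$lnf <- lnf$cache
  ## decoder
  h <- array(tokens, c(g, g, cfg$embedDim))
  dec <- vector("list", length(cfg$plan))
  for (j in seq_along(cfg$plan)) {
    pl <- cfg$plan[[j]]
    u <- upsample2_fwd(h)
    if (!is.na(pl$skip)) u <- concat_ch(u, skips[[pl$skip]])
    cv <- conv2d_fwd(u, P[[sprintf("dec.s%d.W", j)]],
                     P[[sprintf("dec.s%d.b", j)]], 1L)
    rl <- relu_fwd(cv$out)
    dec[[j]] <- list(cv = cv$cache, rl = rl$cache, upCh = dim(h)[3])
    h <- rl$out
  }
  cc$dec <- dec
  hw <- if (head == "recon") conv1x1_fwd(h, P$head.recon.W, P$head.recon.b)
        else conv1x1_fwd(h, P$head.seg.W, P$head.seg.b)
  cc$head <- hw$cache
  cc$headName <- head
  cc$skipDims <- lapply(skips, dim)
  list(out = hw$out, tokens = tokens, skips = skips, cache = cc)
}

## Backward pass; dout matches the head output shape.  Returns named grads.
net_backward <- function(P, cfg, cache, dout) {
  G <- list()
  headW <- if (cache$headName == "recon") "head.recon" else "head.seg"
  hb <- conv1x1_bwd(dout, P[[paste0(headW, ".W")]], cache$head)
  G[[paste0(headW, ".W")]] <- hb$dW
  G[[paste0(headW, ".b")]] <- hb$db
  dh <- hb$dx
  dskips <- lapply(cache$skipDims, function(d) array(0, d))
  for (j in rev(seq_along(cfg$plan))) {
    pl <- cfg$plan[[j]]
    dcv <- relu_bwd(dh, cache$dec[[j]]$rl)
    cb <- conv2d_bwd(dcv, P[[sprintf("dec.s%d.W", j)]], cache$dec[[j]]$cv)
    G[[sprintf("dec.s%d.W", j)]] <- cb$dW
    G[[sprintf("dec.s%d.b", j)]] <- cb$db
    du <- cb$dx
    upCh <- cache$dec[[j]]$upCh
    if (!is.na(pl$skip)) {
      dskips[[pl$skip]] <- dskips[[pl$skip]] +
        du[, , (upCh + 1L):dim(du)[3], drop = FALSE]
      du <- du[, , seq_len(upCh), drop = FALSE]
    }
    dh <- upsample2_bwd(du)
  }
  g <- cfg$grid
  dtok <- matrix(dh, g * g, cfg$embedDim)
  lb <- layernorm_bwd(dtok, cache$lnf)
  G$lnf.g <- lb$dg; G$lnf.b <- lb$db
  dt <- lb$dx
  for (l in rev(seq_len(cfg$nLayers))) {
    pre <- sprintf("blk%d.", l)
    bc <- cache$blocks[[l]]
    ## t_out = t1 + f2(ge(f1(ln2(t1))))
    f2b <- linear_bwd(dt, P[[paste0(pre, "fc2.W")]], bc$f2)
    G[[paste0(pre, "fc2.W")]] <- f2b$dW; G[[paste0(pre, "fc2.b")]] <- f2b$db
    geb <- gelu_bwd(f2b$dx, bc$ge)
    f1b <- linear_bwd(geb, P[[paste0(pre, "fc1.W")]], bc$f1)
    G[[paste0(pre, "fc1.W")]] <- f1b$dW; G[[paste0(pre, "fc1.b")]] <- f1b$db
    ln2b <- layernorm_bwd(f1b$dx, bc$ln2)
    G[[paste0(pre, "ln2.g")]] <- ln2b$dg; G[[paste0(pre, "ln2.b")]] <- ln2b$db
    dt1 <- dt + ln2b$dx
    ## t1 = t + att(ln1(t))
    ab <- attention_bwd(dt1,
                        list(q.W = P[[paste0(pre, "q.W")]], k.W = P[[paste0(pre, "k.W")]],
                             v.W = P[[paste0(pre, "v.W")]], o.W = P[[paste0(pre, "o.W")]]),
                        bc$att)
    for (nm in c("q", "k", "v", "o")) {
      G[[paste0(pre, nm, ".W")]] <- ab[[paste0(nm, ".W")]]
      G[[paste0(pre, nm, ".b")]] <- ab[[paste0(nm, ".b")]]
    }
    ln1b <- layernorm_bwd(ab$dx, bc$ln1)
    G[[paste0(pre, "ln1.g")]] <- ln1b$dg; G[[paste0(pre, "ln1.b")]] <- ln1b$db
    dt <- dt1 + ln1b$dx
  }
  G$pos <- dt
  eb <- linear_bwd(dt, P$embed.W, cache$tokm)
  G$embed.W <- eb$dW; G$embed.b <- eb$db
  dfl <- untokenize(eb$dx, cfg$patchSize, cfg$grid, cache$fmapC)
  dh <- dfl
  for (i in rev(seq_along(cfg$convChannels))) {
    sc <- cache[[sprintf("s%d", i)]]
    drb <- relu_bwd(dh, sc$rb)
    bb <- conv2d_bwd(drb, P[[sprintf("enc.s%d.b.W", i)]], sc$b)
    G[[sprintf("enc.s%d.b.W", i)]] <- bb$dW
    G[[sprintf("enc.s%d.b.b", i)]] <- bb$db
    dra <- bb$dx + dskips[[i]]
    dra <- relu_bwd(dra, sc$ra)
    ab2 <- conv2d_bwd(dra, P[[sprintf("enc.s%d.a.W", i)]], sc$a)
    G[[sprintf("enc.s%d.a.W", i)]] <- ab2$dW
    G[[sprintf("enc.s%d.a.b", i)]] <- ab2$db
    dh <- ab2$dx
  }
  G
}

as_image_list <- function(images) {
  if (is.matrix(images)) return(list(images))
  if (is.list(images)) return(images)
  stopf("images must be a matrix or a list of matrices")
}

check_input_size <- function(cfg, img) {
  if (!identical(dim(img), c(cfg$inputSize, cfg$inputSize)))
    stopf("image size %s does not match model input size %dx%d",
          paste(dim(img), collapse = "x"), cfg$inputSize, cfg$inputSize)
}

#' Encode images into transformer tokens and skip features
#'
#' Runs the convolutional stages and transformer blocks.  Token count is
#' `(inputSize / 2^stages / patchSize)^2`; one skip feature map is returned
#' per conv stage at its native resolution.
#'
#' @param model a [SegModel-class].
#' @param images a matrix or list of matrices, each `inputSize` x `inputSize`.
#' @return list with `tokens` — array `(batch, nTokens, embedDim)` — and
#'   `skips` — list (one per stage) of arrays `(batch, H_i, W_i, C_i)`.
#' @export
encodeImages <- function(model, images) {
  cfg <- getConfig(model); P <- modelParams(model)
  imgs <- as_image_list(images)
  lapply(imgs, check_input_size, cfg = cfg)
  B <- length(imgs)
  tokens <- array(0, c(B, cfg$nTokens, cfg$embedDim))
  skips <- NULL
  for (bi in seq_len(B)) {
    fw <- net_forward(P, cfg, imgs[[bi]], "recon")
    tokens[bi, , ] <- fw$tokens
    if (is.null(skips))
      skips <- lapply(fw$skips, function(s) array(0, c(B, dim(s))))
    for (i in seq_along(fw$skips)) skips[[i]][bi, , , ] <- fw$skips[[i]]
  }
  list(tokens = tokens, skips = skips)
}

#' Decode tokens (plus skips) to a full-resolution feature map
#'
#' Reshapes the token sequence to the spatial grid and applies the
#' progressive upsampling decoder with skip concatenation.
#'
#' @param model a [SegModel-class].
#' @param tokens array `(batch, nTokens, embedDim)` from [encodeImages()].
#' @param skips skip list from [encodeImages()].
#' @return array `(batch, inputSize, inputSize, lastDecoderChannels)`.
#' @export
decodeTokens <- function(model, tokens, skips) {
  cfg <- getConfig(model); P <- modelParams(model)
  if (length(dim(tokens)) != 3L || dim(tokens)[2] != cfg$nTokens)
    stopf("tokens must be (batch, %d, %d)", cfg$nTokens, cfg$embedDim)
  B <- dim(tokens)[1]
  out <- NULL
  for (bi in seq_len(B)) {
    h <- array(tokens[bi, , ], c(cfg$grid, cfg$grid, cfg$embedDim))
    for (j in seq_along(cfg$plan)) {
      pl <- cfg$plan[[j]]
      u <- upsample2_fwd(h)
      if (!is.na(pl$skip)) {
        sk <- skips[[pl$skip]]
        u <- concat_ch(u, array(sk[bi, , , ], dim(sk)[-1]))
      }
      cv <- conv2d_fwd(u, P[[sprintf("dec.s%d.W", j)]],
                       P[[sprintf("dec.s%d.b", j)]], 1L)
      h <- relu_fwd(cv$out)$out
    }
    if (is.null(out)) out <- array(0, c(B, dim(h)))
    out[bi, , , ] <- h
  }
  out
}

#' Reconstruct images through the reconstruction head
#'
#' @param model a [SegModel-class].
#' @param images matrix or list of matrices at the model input size.
#' @return array `(batch, inputSize, inputSize)` of reconstructions.
#' @export
reconstructImages <- function(model, images) {
  cfg <- getConfig(model); P <- modelParams(model)
  imgs <- as_image_list(images)
  lapply(imgs, check_input_size, cfg = cfg)
  out <- array(0, c(length(imgs), cfg$inputSize, cfg$inputSize))
  for (bi in seq_along(imgs))
    out[bi, , ] <- net_forward(P, cfg, imgs[[bi]], "recon")$out[, , 1L]
  out
}

softmax_ch <- function(z) {
  ## z: (H, W, C) -> per-pixel softmax over C
  m <- apply(z, c(1, 2), max)
  e <- exp(z - as.vector(m))
  e / as.vector(apply(e, c(1, 2), sum))
}

#' Per-pixel class probabilities through the segmentation head
#'
#' @param model a [SegModel-class].
#' @param images matrix or list of matrices at the model input size.
#' @return array `(batch, nClasses, inputSize, inputSize)` of softmax
#'   probabilities (class axis sums to 1 at every pixel).
#' @export
segmentImages <- function(model, images) {
  cfg <- getConfig(model); P <- modelParams(model)
  imgs <- as_image_list(images)
  lapply(imgs, check_input_size, cfg = cfg)
  out <- array(0, c(length(imgs), cfg$nClasses, cfg$inputSize, cfg$inputSize))
  for (bi in seq_along(imgs)) {
    z <- net_forward(P, cfg, imgs[[bi]], "seg")$out
    out[bi, , , ] <- aperm(softmax_ch(z), c(3L, 1L, 2L))
  }
  out
}
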