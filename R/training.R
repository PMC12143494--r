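#' Training configuration
#'
#' Controls both the reconstruction pre-training loop and the segmentation
#' fine-tuning loop.  Each iteration is one batch-level parameter update
#' with a corresponding learning-rate adjustment; the default schedule is
#' polynomial decay `lr * (1 - t/T)^power` (power 0.9), the common
#' TransUNet-style practice, driven by stochastic gradient descent with
#' momentum 0.9.
#'
#' @param iterations number of batch-level updates (>= 1).
#' @param batchSize images per update.
#' @param learningRate base learning rate (> 0).
#' @param lrSchedule `"poly"` or `"constant"`.
#' @param optimizer `"sgd"` (momentum) or `"adam"`.
#' @param momentum SGD momentum coefficient.
#' @param polyPower exponent of the polynomial decay.
#' @param loss fine-tuning loss: `"ce"` (pixel-wise cross-entropy),
#'   `"ce_dice"` (equally weighted cross-entropy + soft Dice, the default)
#'   or `"mse"` (used by pre-training regardless of this field).
#' @param freeze character vector of parameter families excluded from
#'   updates; subset of `conv_encoder`, `transformer`, `decoder`, `head`.
#'   The pre-trained-transfer default policy is `"transformer"`.
#' @param augment fine-tuning augmentation: `"flips"` (random flips and
#'   right-angle rotations applied jointly to image and label) or `"none"`.
#' @param seed RNG seed for batch sampling and augmentation.
#' @return validated configuration list.
#' @export
trainConfig <- function(iterations = 100L, batchSize = 4L, learningRate = 0.1,
                        lrSchedule = c("poly", "constant"),
                        optimizer = c("sgd", "adam"), momentum = 0.9,
                        polyPower = 0.9, loss = c("ce_dice", "ce", "mse"),
                        freeze = character(), augment = c("flips", "none"),
                        seed = 0L) {
  lrSchedule <- match.arg(lrSchedule)
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss)
  augment <- match.arg(augment)
  if (!is_count(iterations) || iterations < 1) stopf("iterations must be >= 1")
  if (learningRate <= 0) stopf("learningRate must be > 0")
  if (!is_count(batchSize) || batchSize < 1) stopf("batchSize must be >= 1")
  fams <- c("conv_encoder", "transformer", "decoder", "head")
  if (!all(freeze %in% fams))
    stopf("unknown family in freeze: %s",
          paste(setdiff(freeze, fams), collapse = ", "))
  list(iterations = as.integer(iterations), batchSize = as.integer(batchSize),
       learningRate = learningRate, lrSchedule = lrSchedule,
       optimizer = optimizer, momentum = momentum, polyPower = polyPower,
       loss = loss, freeze = freeze, augment = augment, seed = as.integer(seed))
}

lr_at <- function(cfg, t) {
  if (cfg$lrSchedule == "constant") return(cfg$learningRate)
  cfg$learningRate * (1 - (t - 1) / cfg$iterations)^cfg$polyPower
}

## Optimizer state: velocity (sgd) or first/second moments (adam), keyed by
## parameter name, created lazily.
new_opt_state <- function(cfg) {
  list(cfg = cfg, t = 0L, v = list(), m = list(), s = list())
}

opt_update <- function(P, G, state, trainable) {
  cfg <- state$cfg
  state$t <- state$t + 1L
  lr <- lr_at(cfg, state$t)
  for (nm in intersect(names(G), trainable)) {
    g <- G[[nm]]
    if (cfg$optimizer == "sgd") {
      v <- if (is.null(state$v[[nm]])) g * 0 else state$v[[nm]]
      v <- cfg$momentum * v + g
      state$v[[nm]] <- v
      P[[nm]] <- P[[nm]] - lr * v
    } else {
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      m <- if (is.null(state$m[[nm]])) g * 0 else state$m[[nm]]
      s <- if (is.null(state$s[[nm]])) g * 0 else state$s[[nm]]
      m <- b1 * m + (1 - b1) * g
      s <- b2 * s + (1 - b2) * g^2
      state$m[[nm]] <- m; state$s[[nm]] <- s
      mh <- m / (1 - b1^state$t); sh <- s / (1 - b2^state$t)
      P[[nm]] <- P[[nm]] - lr * mh / (sqrt(sh) + eps)
    }
  }
  list(P = P, state = state)
}

trainable_names <- function(model, extraFreeze = character()) {
  fams <- paramFamilies(model)
  frozen <- union(frozenFamilies(model), extraFreeze)
  unlist(fams[setdiff(names(fams), frozen)], use.names = FALSE)
}

## ---- losses ---------------------------------------------------------------

## MSE loss and gradient w.r.t. the reconstruction (H, W, 1).
mse_loss_grad <- function(recon, target) {
  r <- recon[, , 1L]
  diff <- r - target
  list(loss = mean(diff^2),
       dout = array(2 * diff / length(diff), dim(recon)))
}

## Cross-entropy (+ optional soft Dice) loss and gradient w.r.t. logits
## (H, W, C); labels are integers in 0..C-1.
seg_loss_grad <- function(logits, labels, loss = "ce_dice") {
  d <- dim(logits); n <- d[1] * d[2]; C <- d[3]
  p <- softmax_ch(logits)
  pm <- matrix(p, n, C)
  li <- as.vector(labels) + 1L
  onehot <- matrix(0, n, C)
  onehot[cbind(seq_len(n), li)] <- 1
  ce <- -sum(log(pmax(pm[cbind(seq_len(n), li)], 1e-12))) / n
  dce <- (pm - onehot) / n
  if (loss == "ce") {
    return(list(loss = ce, dout = array(dce, d)))
  }
  ## soft Dice per class over probabilities, mean over classes
  eps <- 1e-6
  inter <- colSums(pm * onehot)
  sums <- colSums(pm) + colSums(onehot)
  dice <- (2 * inter + eps) / (sums + eps)
  dl_dp <- -(2 * onehot * rep(sums + eps, each = n) -
               rep(2 * inter + eps, each = n)) / rep((sums + eps)^2, each = n) / C
  ## chain through softmax: dz = p * (u - sum(u * p)) per pixel
  dz_dice <- pm * (dl_dp - rowSums(dl_dp * pm))
  list(loss = 0.5 * ce + 0.5 * (1 - mean(dice)),
       dout = array(0.5 * dce + 0.5 * dz_dice, d))
}

## ---- pre-training ---------------------------------------------------------

#' One reconstruction pre-training step
#'
#' Computes the batch-mean pixel MSE between the reconstructions of the
#' corrupted inputs and the clean aligned targets, and applies one
#' optimizer update to the trainable parameters.
#'
#' @param model a [SegModel-class].
#' @param batch non-empty list of [AugmentedPair-class] objects.
#' @param state optimizer state from [newOptimizerState()] (created from a
#'   [trainConfig()]).
#' @return list with updated `model`, `state` and the scalar `loss`.
#' @export
pretrainStep <- function(model, batch, state) {
  if (length(batch) == 0L) stopf("batch must be non-empty")
  cfg <- getConfig(model)
  P <- modelParams(model)
  G <- NULL
  loss <- 0
  for (pair in batch) {
    fw <- net_forward(P, cfg, inputImage(pair), "recon")
    lg <- mse_loss_grad(fw$out, targetImage(pair))
    loss <- loss + lg$loss
    g <- net_backward(P, cfg, fw$cache, lg$dout)
    G <- if (is.null(G)) g else mapply(`+`, G, g[names(G)], SIMPLIFY = FALSE)
  }
  B <- length(batch)
  G <- lapply(G, `/`, B)
  loss <- loss / B
  upd <- opt_update(P, G, state, trainable_names(model))
  model@params <- upd$P
  list(model = model, state = upd$state, loss = loss)
}

#' Create optimizer state for step-wise training
#'
#' @param config a [trainConfig()].
#' @return opaque optimizer-state list consumed by [pretrainStep()].
#' @export
newOptimizerState <- function(config) new_opt_state(config)

#' Run reconstruction pre-training
#'
#' The self-supervised pre-training loop: at every iteration a fresh batch
#' of images is drawn from the corpus, fresh augmentation records are
#' sampled, and the model is updated to minimise the MSE between the
#' reconstruction of the corrupted input and the geometrically aligned
#' clean target.
#'
#' @param corpus non-empty list of square grayscale matrices in [0,1]
#'   (see [generatePretrainCorpus()]).
#' @param model a [SegModel-class] whose input size matches the corpus.
#' @param config a [trainConfig()].
#' @param augConfig an [augmentationConfig()].
#' @return a [TrainingCheckpoint-class] with loss history of length
#'   `iterations`.
#' @export
runPretraining <- function(corpus, model, config,
                           augConfig = augmentationConfig()) {
  if (length(corpus) == 0L) stopf("corpus must be non-empty")
  set.seed(config$seed)
  state <- new_opt_state(config)
  history <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    idx <- sample.int(length(corpus), config$batchSize, replace = TRUE)
    batch <- lapply(corpus[idx], makeAugmentedPair, config = augConfig)
    stp <- pretrainStep(model, batch, state)
    model <- stp$model; state <- stp$state
    history[it] <- stp$loss
  }
  methods::new("TrainingCheckpoint", params = modelParams(model),
               families = paramFamilies(model), modelConfig = getConfig(model),
               trainConfig = config, iteration = config$iterations,
               lossHistory = history)
}

## ---- transfer and freezing ------------------------------------------------

#' Transfer pre-trained transformer parameters
#'
#' Copies every transformer-family array (patch embedding, positional
#' embedding, all block weights, final norm) from a pre-training checkpoint
#' (or another model) into the target model, bit-exactly.  All other
#' families are untouched.
#'
#' @param source a [TrainingCheckpoint-class] or [SegModel-class].
#' @param target a [SegModel-class] with matching transformer shapes.
#' @return the target model with transferred transformer parameters.
#' @export
transferTransformerParams <- function(source, target) {
  sp <- modelParams(source)
  sf <- paramFamilies(source)$transformer
  tf <- paramFamilies(target)$transformer
  for (nm in sf) {
    if (!nm %in% tf)
      stopf("transformer parameter '%s' missing in target", nm)
    if (!identical(dim1(sp[[nm]]), dim1(target@params[[nm]])))
      stopf("shape mismatch for transformer parameter '%s': source %s, target %s",
            nm, paste(dim1(sp[[nm]]), collapse = "x"),
            paste(dim1(target@params[[nm]]), collapse = "x"))
    target@params[[nm]] <- sp[[nm]]
  }
  target
}

dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Set the frozen parameter families of a model
#'
#' Frozen families are excluded from all optimizer updates; their arrays
#' remain bit-identical across any number of training steps.  The transfer
#' policy used after pre-training freezes only the transformer family,
#' leaving the convolutional layers free to adapt to the downstream data.
#'
#' @param model a [SegModel-class].
#' @param freeze character vector of family names (possibly empty).
#' @return the model with its freeze set replaced.
#' @export
setTrainable <- function(model, freeze = character()) {
  fams <- names(paramFamilies(model))
  if (!all(freeze %in% fams))
    stopf("unknown family name(s): %s",
          paste(setdiff(freeze, fams), collapse = ", "))
  model@freeze <- as.character(freeze)
  methods::validObject(model)
  model
}

## ---- fine-tuning ----------------------------------------------------------

validate_dataset <- function(dataset, nClasses) {
  if (is.null(dataset$images) || is.null(dataset$labels) ||
      length(dataset$images) != length(dataset$labels) ||
      length(dataset$images) == 0L)
    stopf("dataset must contain matching non-empty 'images' and 'labels' lists")
  for (i in seq_along(dataset$images)) {
    if (!identical(dim(dataset$images[[i]]), dim(dataset$labels[[i]])))
      stopf("slice %d: image and label shapes differ", i)
    l <- dataset$labels[[i]]
    if (any(l < 0) || any(l >= nClasses))
      stopf("slice %d: label values must be integers in [0, %d)", i, nClasses)
  }
}

#' Convert a labeled volume pair to a slice dataset
#'
#' Slices a (z, y, x) intensity/label pair along z into the paired
#' image/label lists consumed by [runFinetuning()].
#'
#' @param pair list with `intensity` array and `labels`
#'   ([LabelVolume-class]), as produced by [generateLabeledVolume()] or
#'   [splitDataset()].
#' @return list with `images` and `labels` (lists of matrices).
#' @export
sliceDataset <- function(pair) {
  vol <- pair$intensity
  lab <- labelData(pair$labels)
  d <- dim(vol)
  list(images = lapply(seq_len(d[1]), function(z) matrix(vol[z, , ], d[2], d[3])),
       labels = lapply(seq_len(d[1]), function(z) matrix(lab[z, , ], d[2], d[3])))
}

#' Run segmentation fine-tuning
#'
#' Optionally transfers transformer parameters from a pre-training
#' checkpoint, applies the freeze policy, then runs `iterations`
#' batch-level updates of the segmentation loss on 2D image/label pairs
#' (3D volumes are sliced beforehand; see [sliceDataset()]).
#'
#' @param dataset list with `images` and `labels`: parallel lists of 2D
#'   matrices, labels integer in `[0, nClasses)`.  Images smaller than the
#'   model input are reflection-padded (labels edge-padded via the same
#'   index map).
#' @param model a [SegModel-class].
#' @param config a [trainConfig()]; `config$freeze` is applied via
#'   [setTrainable()] after the optional transfer.
#' @param source optional [TrainingCheckpoint-class] whose transformer
#'   parameters are transferred before training.
#' @return a [TrainingCheckpoint-class] with the fine-tuned parameters.
#' @export
runFinetuning <- function(dataset, model, config, source = NULL) {
  cfg <- getConfig(model)
  validate_dataset(dataset, cfg$nClasses)
  if (!is.null(source)) model <- transferTransformerParams(source, model)
  model <- setTrainable(model, config$freeze)
  set.seed(config$seed)
  n <- length(dataset$images)
  sz <- cfg$inputSize
  state <- new_opt_state(config)
  history <- numeric(config$iterations)
  trainable <- trainable_names(model)
  P <- modelParams(model)
  for (it in seq_len(config$iterations)) {
    idx <- sample.int(n, min(config$batchSize, n), replace = config$batchSize > n)
    G <- NULL; loss <- 0
    for (i in idx) {
      img <- dataset$images[[i]]
      lab <- dataset$labels[[i]]
      if (config$augment == "flips") {
        rec <- list(flip_h = stats::runif(1) < 0.5,
                    flip_v = stats::runif(1) < 0.5,
                    rot90_k = safe_sample1(0:3))
        img <- applyGeometric(img, rec)
        lab <- applyGeometric(lab, rec)
      }
      fit <- fit_to_size(img, sz)
      lab <- pad_with_idx(lab, fit$ri, fit$ci)
      fw <- net_forward(P, cfg, fit$img, "seg")
      lg <- seg_loss_grad(fw$out, lab, config$loss)
      loss <- loss + lg$loss
      g <- net_backward(P, cfg, fw$cache, lg$dout)
      G <- if (is.null(G)) g else mapply(`+`, G, g[names(G)], SIMPLIFY = FALSE)
    }
    G <- lapply(G, `/`, length(idx))
    upd <- opt_update(P, G, state, trainable)
    P <- upd$P; state <- upd$state
    history[it] <- loss / length(idx)
  }
  model@params <- P
  methods::new("TrainingCheckpoint", params = P,
               families = paramFamilies(model), modelConfig = cfg,
               trainConfig = config, iteration = config$iterations,
               lossHistory = history)
}

## Reflection-pad (or crop nothing) a 2D image up to (sz, sz); returns the
## padded image plus the row/col index maps so labels can follow.
fit_to_size <- function(img, sz) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr > sz || nc > sz)
    stopf("slice (%dx%d) larger than model input (%d); use predictPlane tiling",
          nr, nc, sz)
  ri <- reflect_idx(nr, 0L, sz - nr)
  ci <- reflect_idx(nc, 0L, sz - nc)
  list(img = img[ri, ci, drop = FALSE], ri = ri, ci = ci)
}

pad_with_idx <- function(m, ri, ci) m[ri, ci, drop = FALSE]

#' Rebuild a model from a checkpoint
#'
#' @param ckpt a [TrainingCheckpoint-class].
#' @return a [SegModel-class] carrying the checkpoint's parameters.
#' @export
modelFromCheckpoint <- function(ckpt) {
  model <- buildModel(modelConfig_from(ckpt))
  applyCheckpoint(model, ckpt)
}

modelConfig_from <- function(ckpt) {
  mc <- ckpt@modelConfig
  attr(mc, "retinaModelConfig") <- TRUE
  mc
}

#' Load all checkpoint parameters into a model
#'
#' Shape-checked, bit-exact copy of every parameter array; errors name the
#' first mismatching parameter.
#'
#' @param model a [SegModel-class].
#' @param ckpt a [TrainingCheckpoint-class].
#' @return the model with replaced parameters.
#' @export
applyCheckpoint <- function(model, ckpt) {
  sp <- modelParams(ckpt)
  if (!setequal(names(sp), names(modelParams(model))))
    stopf("checkpoint parameter set does not match the model")
  for (nm in names(sp)) {
    if (!identical(dim1(sp[[nm]]), dim1(model@params[[nm]])))
      stopf("shape mismatch for parameter '%s'", nm)
    model@params[[nm]] <- sp[[nm]]
  }
  model
}
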