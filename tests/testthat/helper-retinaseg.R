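## Shared fixtures and independent brute-force oracles.

tiny_spec <- function(seed = 1L, ...) {
  syntheticSpec(imageSize = 64L, volumeShape = c(16L, 64L, 64L),
                nClasses = 2L, seed = seed, ...)
}

## Very small model so construction/forward tests run in milliseconds.
micro_config <- function(nClasses = 2L, seed = 0L) {
  modelConfig(inputSize = 16L, convChannels = c(4L, 6L), patchSize = 2L,
              embedDim = 8L, nLayers = 2L, nHeads = 2L, mlpDim = 16L,
              decoderChannels = c(8L, 6L, 4L), nClasses = nClasses,
              seed = seed)
}

random_mask <- function(dims, p = 0.3) {
  array(stats::runif(prod(dims)) < p, dims)
}

random_labels <- function(dims, nClasses) {
  array(sample(0:nClasses, prod(dims), replace = TRUE), dims)
}

## Brute-force per-voxel confusion counting (independent of the package's
## vectorised implementation).
bf_confusion <- function(pred, gt, cl) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] == cl; g <- gt[i] == cl
    if (p && g) tp <- tp + 1
    else if (p && !g) fp <- fp + 1
    else if (!p && g) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

## Coordinates (in voxel units scaled by spacing) of TRUE entries.
mask_coords <- function(mask, spacing = NULL) {
  d <- dim(mask)
  if (is.null(spacing)) spacing <- rep(1, length(d))
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx, 2L, spacing, `*`)
}

## O(n*m) nearest-neighbour distances from each point of A to the set B.
bf_nn_dist <- function(A, B) {
  apply(A, 1L, function(a)
    sqrt(min(colSums((t(B) - a)^2))))
}

bf_directed_hausdorff <- function(A, B) max(bf_nn_dist(A, B))

bf_mfd <- function(pred, gt, cl = 1L, spacing = NULL) {
  A <- mask_coords(pred == cl, spacing)
  B <- mask_coords(gt == cl, spacing)
  (bf_directed_hausdorff(A, B) + bf_directed_hausdorff(B, A)) / 2
}

bf_adgt_adf <- function(pred, gt, cl = 1L, spacing = NULL) {
  A <- mask_coords(pred == cl, spacing)
  B <- mask_coords(gt == cl, spacing)
  list(adgt = mean(bf_nn_dist(A, B)), adf = mean(bf_nn_dist(B, A)))
}

## Constant-probability stub predictor for inference tests.
constant_stub <- function(p) {
  force(p)
  function(img) {
    out <- array(0, c(nrow(img), ncol(img), length(p)))
    for (k in seq_along(p)) out[, , k] <- p[k]
    out
  }
}
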