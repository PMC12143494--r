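#' Augmentation configuration
#'
#' Parameters of the paired augmentation pipeline used for reconstruction
#' pre-training.  Geometric operations (flips, right-angle rotations) are
#' applied to both members of a pair so input and target stay aligned;
#' photometric corruption (brightness, contrast, noise, blur) and patch
#' masking are applied to the network input only.  Flips and rotation are
#' each applied with probability 0.5 by default, and the number of masked
#' patches is drawn uniformly from 1--32, matching common EM pre-training
#' practice; the remaining parameter ranges are documented artifact
#' defaults.
#'
#' @param probFlip probability of each flip (horizontal and vertical drawn
#'   independently).
#' @param probRotate probability that a non-trivial rotation (90/180/270
#'   degrees, uniform) is applied.
#' @param probBrightness,probContrast,probNoise,probBlur,probMask per-op
#'   application probabilities for the corruption stage.
#' @param brightnessRange additive intensity offset range.
#' @param contrastRange multiplicative gain range (about mid-gray 0.5).
#' @param noiseSdRange Gaussian pixel-noise standard-deviation range.
#' @param blurSdRange Gaussian blur sigma range in pixels.
#' @param maskCountRange integer (min, max) number of masked patches.
#' @param maskSize masked patch side in pixels.
#' @param fillValue intensity written into masked patches.
#' @return validated configuration list.
#' @export
augmentationConfig <- function(probFlip = 0.5, probRotate = 0.5,
                               probBrightness = 0.5, probContrast = 0.5,
                               probNoise = 0.5, probBlur = 0.5, probMask = 0.5,
                               brightnessRange = c(-0.2, 0.2),
                               contrastRange = c(0.8, 1.2),
                               noiseSdRange = c(0, 0.05),
                               blurSdRange = c(0, 1.5),
                               maskCountRange = c(1L, 32L),
                               maskSize = 16L, fillValue = 0) {
  probs <- c(probFlip, probRotate, probBrightness, probContrast, probNoise,
             probBlur, probMask)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0,1]")
  for (nm in c("brightnessRange", "contrastRange", "noiseSdRange",
               "blurSdRange", "maskCountRange")) {
    r <- get(nm)
    if (length(r) != 2L || r[1] > r[2])
      stopf("%s must be a (min, max) range with min <= max", nm)
  }
  if (maskCountRange[1] < 1) stopf("maskCountRange minimum must be >= 1")
  if (maskSize < 1) stopf("maskSize must be >= 1")
  if (fillValue < 0 || fillValue > 1) stopf("fillValue must lie in [0,1]")
  list(probFlip = probFlip, probRotate = probRotate,
       probBrightness = probBrightness, probContrast = probContrast,
       probNoise = probNoise, probBlur = probBlur, probMask = probMask,
       brightnessRange = as.numeric(brightnessRange),
       contrastRange = as.numeric(contrastRange),
       noiseSdRange = as.numeric(noiseSdRange),
       blurSdRange = as.numeric(blurSdRange),
       maskCountRange = as.integer(maskCountRange),
       maskSize = as.integer(maskSize), fillValue = fillValue)
}

#' Sample geometric and corruption records
#'
#' Draws one transform-record pair from the configured distributions using
#' the current RNG stream.  The geometric record holds `flip_h`, `flip_v`
#' (independent Bernoulli draws) and `rot90_k` (0, or uniform 1--3 when the
#' rotation fires).  The corruption record stores neutral values (delta 0,
#' gain 1, sd 0, no patches) for operations that do not fire, plus a
#' private `noise_seed` so the noise realization replays bit-exactly from
#' the record alone.
#'
#' @param config an [augmentationConfig()].
#' @param imageSize side of the (square) image the records will apply to;
#'   needed to place masked patches fully inside the image.
#' @return list with elements `geometric` and `corruption`.
#' @export
sampleAugmentRecords <- function(config, imageSize) {
  if (config$maskSize > imageSize)
    stopf("maskSize (%d) exceeds imageSize (%d)", config$maskSize, imageSize)
  geometric <- list(
    flip_h = stats::runif(1) < config$probFlip,
    flip_v = stats::runif(1) < config$probFlip,
    rot90_k = if (stats::runif(1) < config$probRotate) safe_sample1(1:3) else 0L)
  draw_range <- function(p, r, neutral) {
    if (stats::runif(1) < p) stats::runif(1, r[1], r[2]) else neutral
  }
  mask <- NULL
  if (stats::runif(1) < config$probMask) {
    count <- safe_sample1(config$maskCountRange[1]:config$maskCountRange[2])
    lim <- imageSize - config$maskSize + 1L
    mask <- cbind(row = sample.int(lim, count, replace = TRUE),
                  col = sample.int(lim, count, replace = TRUE),
                  size = rep(config$maskSize, count))
  }
  corruption <- list(
    brightness_delta = draw_range(config$probBrightness, config$brightnessRange, 0),
    contrast_gain = draw_range(config$probContrast, config$contrastRange, 1),
    noise_sd = draw_range(config$probNoise, config$noiseSdRange, 0),
    blur_sd = draw_range(config$probBlur, config$blurSdRange, 0),
    mask_patches = mask, fill_value = config$fillValue,
    noise_seed = sample.int(.Machine$integer.max, 1L))
  list(geometric = geometric, corruption = corruption)
}

rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

#' Apply a geometric record to an image
#'
#' Fixed operation order: horizontal flip (columns reversed), vertical flip
#' (rows reversed), then `rot90_k` counter-clockwise quarter turns.  Exactly
#' invertible via [invertGeometric()]; no interpolation is involved.
#'
#' @param image 2D numeric matrix.
#' @param record geometric record (`flip_h`, `flip_v`, `rot90_k`).
#' @return transformed matrix (same shape for square inputs).
#' @examples
#' applyGeometric(rbind(c(1, 2), c(3, 4)), list(flip_h = FALSE,
#'   flip_v = FALSE, rot90_k = 1))
#' @export
applyGeometric <- function(image, record) {
  if (!is.matrix(image)) stopf("image must be a 2D matrix")
  out <- image
  if (isTRUE(record$flip_h)) out <- out[, ncol(out):1, drop = FALSE]
  if (isTRUE(record$flip_v)) out <- out[nrow(out):1, , drop = FALSE]
  k <- record$rot90_k %% 4L
  while (k > 0L) {
    out <- rot90ccw(out)
    k <- k - 1L
  }
  out
}

#' Undo a geometric record
#'
#' `invertGeometric(applyGeometric(x, r), r)` is bit-identical to `x`.
#'
#' @param image transformed matrix.
#' @param record the geometric record that produced it.
#' @return the original matrix.
#' @export
invertGeometric <- function(image, record) {
  if (!is.matrix(image)) stopf("image must be a 2D matrix")
  out <- image
  k <- (4L - record$rot90_k %% 4L) %% 4L
  while (k > 0L) {
    out <- rot90ccw(out)
    k <- k - 1L
  }
  if (isTRUE(record$flip_v)) out <- out[nrow(out):1, , drop = FALSE]
  if (isTRUE(record$flip_h)) out <- out[, ncol(out):1, drop = FALSE]
  out
}

#' Apply a corruption record to an image
#'
#' Operations are applied in the fixed order brightness/contrast
#' adjustment, noise addition, blurring, then patch masking, with the
#' result clipped to [0,1].  Contrast is a gain about mid-gray:
#' `x -> (x - 0.5) * gain + 0.5 + delta`.  The Gaussian noise realization
#' is drawn from the record's private `noise_seed`, so corruption is a pure
#' function of (image, record).
#'
#' @param image matrix with values in [0,1].
#' @param record corruption record from [sampleAugmentRecords()].
#' @return corrupted matrix in [0,1]; masked patches equal `fill_value`.
#' @export
corruptImage <- function(image, record) {
  if (!is.matrix(image)) stopf("image must be a 2D matrix")
  x <- image
  if (record$contrast_gain != 1 || record$brightness_delta != 0)
    x <- (x - 0.5) * record$contrast_gain + 0.5 + record$brightness_delta
  if (record$noise_sd > 0) {
    n <- with_seed(record$noise_seed,
                   matrix(stats::rnorm(length(x), 0, record$noise_sd),
                          nrow(x), ncol(x)))
    x <- x + n
  }
  if (record$contrast_gain != 1 || record$brightness_delta != 0 ||
      record$noise_sd > 0)
    x <- clamp01(x)
  if (record$blur_sd > 0) x <- gauss_blur2d(x, record$blur_sd)
  mp <- record$mask_patches
  if (!is.null(mp) && nrow(mp) > 0) {
    if (any(mp[, "row"] < 1 | mp[, "col"] < 1 |
            mp[, "row"] + mp[, "size"] - 1 > nrow(x) |
            mp[, "col"] + mp[, "size"] - 1 > ncol(x)))
      stopf("masked patch lies outside the image")
    for (i in seq_len(nrow(mp))) {
      r <- mp[i, "row"]; cc <- mp[i, "col"]; s <- mp[i, "size"]
      x[r:(r + s - 1L), cc:(cc + s - 1L)] <- record$fill_value
    }
  }
  clamp01(x)
}

#' Build an augmented input/target pair
#'
#' Samples fresh records from the current RNG stream, applies the geometric
#' transform to obtain the clean target, and corrupts the target to obtain
#' the network input.  The records are stored on the returned object so the
#' pair can be reproduced bit-exactly with [replayAugmentedPair()].
#'
#' @param image square grayscale matrix in [0,1].
#' @param config an [augmentationConfig()].
#' @return an [AugmentedPair-class].
#' @export
makeAugmentedPair <- function(image, config) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stopf("image must be a square matrix")
  if (min(image) < 0 || max(image) > 1) stopf("image values must lie in [0,1]")
  rec <- sampleAugmentRecords(config, nrow(image))
  replayAugmentedPair(image, rec$geometric, rec$corruption)
}

#' Rebuild an augmented pair from stored records
#'
#' Deterministic companion of [makeAugmentedPair()]: applies the given
#' records without sampling, reproducing a pair bit-exactly.
#'
#' @param image original square matrix in [0,1].
#' @param geometric geometric record.
#' @param corruption corruption record.
#' @return an [AugmentedPair-class].
#' @export
replayAugmentedPair <- function(image, geometric, corruption) {
  target <- applyGeometric(image, geometric)
  input <- corruptImage(target, corruption)
  methods::new("AugmentedPair", input = input, target = target,
               geometric = geometric, corruption = corruption)
}
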