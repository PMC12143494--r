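#' Synthetic EM-like data specification
#'
#' Describes the generator used to emulate electron-microscopy-style inputs
#' at desk scale: grayscale textures in [0,1] built from Gaussian-blurred
#' white noise (rescaled to [0.3, 0.7]) with elliptical "organelle" blobs
#' that raise or lower local intensity, plus matching integer label
#' volumes.  Identical specs (including the seed) produce bit-identical
#' outputs.
#'
#' @param imageSize side of square pre-training patches in pixels.
#' @param volumeShape integer (depth, height, width) of generated volumes,
#'   axis order (z, y, x).
#' @param nClasses number of foreground classes (1--8); labels take values
#'   in 0..nClasses with 0 = background.
#' @param objectsPerClass integer range (min, max) of objects drawn per class.
#' @param objectScale range (min, max) of ellipsoid semi-axes in voxels
#'   (in-plane; the axial semi-axis is divided by `anisotropyFactor`).
#' @param textureNoiseSd standard deviation of per-pixel intensity noise.
#' @param anisotropyFactor ratio of z spacing to xy spacing (1 = isotropic).
#'   Anisotropy is carried as metadata and as coarser axial object sampling;
#'   no physical point-spread simulation is attempted.
#' @param seed integer generator seed.
#' @return validated spec list.
#' @examples
#' sp <- syntheticSpec(imageSize = 64, volumeShape = c(8, 64, 64), seed = 1)
#' @export
syntheticSpec <- function(imageSize = 224L, volumeShape = c(16L, 64L, 64L),
                          nClasses = 2L, objectsPerClass = c(2L, 5L),
                          objectScale = c(3, 7), textureNoiseSd = 0.05,
                          anisotropyFactor = 1, seed = 0L) {
  if (nClasses < 1 || nClasses > 8) stopf("nClasses must be in 1..8")
  if (length(volumeShape) != 3L || any(volumeShape < 1))
    stopf("volumeShape must be three positive extents (z, y, x)")
  if (imageSize < 8) stopf("imageSize must be >= 8")
  for (nm in c("objectsPerClass", "objectScale")) {
    r <- get(nm)
    if (length(r) != 2L || r[1] > r[2] || any(r < 0))
      stopf("%s must be a non-empty (min, max) range", nm)
  }
  if (textureNoiseSd < 0) stopf("textureNoiseSd must be >= 0")
  if (anisotropyFactor < 1) stopf("anisotropyFactor must be >= 1")
  list(imageSize = as.integer(imageSize),
       volumeShape = as.integer(volumeShape), nClasses = as.integer(nClasses),
       objectsPerClass = as.integer(objectsPerClass),
       objectScale = as.numeric(objectScale),
       textureNoiseSd = textureNoiseSd,
       anisotropyFactor = anisotropyFactor, seed = as.integer(seed))
}

## sample() treats a length-1 numeric as sample.int(n); guard against that.
safe_sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

## centre coordinate keeping the whole semi-axis inside [1, n]; degenerate
## (object as large as the axis) falls back to the axis midpoint
runif_centre <- function(n, a) {
  if (n - a > 1 + a) stats::runif(1, 1 + a, n - a) else (n + 1) / 2
}

## Textured background: blurred white noise rescaled to [0.3, 0.7].
texture_background2d <- function(h, w) {
  rescale_range(gauss_blur2d(matrix(stats::rnorm(h * w), h, w), 2), 0.3, 0.7)
}

## Add one soft-edged ellipse to `img` (modified in place via return value).
## Returns list(img, mask) where mask is the hard (q <= 1) support.
draw_ellipse2d <- function(img, cy, cx, ay, ax, theta, offset) {
  h <- nrow(img); w <- ncol(img)
  Y <- row(img) - cy; X <- col(img) - cx
  u <- (cos(theta) * Y + sin(theta) * X) / ay
  v <- (-sin(theta) * Y + cos(theta) * X) / ax
  q <- u^2 + v^2
  soft <- pmin(pmax((1.2 - q) / 0.4, 0), 1)  # blurred edge over q in [0.8, 1.2]
  list(img = img + offset * soft, mask = q <= 1)
}

#' Generate an unlabeled pre-training corpus
#'
#' Produces `n` square grayscale patches emulating the geometry of a large
#' EM patch corpus: smooth random texture with dark and bright blob
#' structures, values in [0,1].  Deterministic for a given spec.
#'
#' @param n number of patches (>= 0).
#' @param spec a [syntheticSpec()].
#' @return list of `imageSize` x `imageSize` matrices (empty list if n = 0).
#' @examples
#' imgs <- generatePretrainCorpus(2, syntheticSpec(imageSize = 64, seed = 1))
#' range(imgs[[1]])
#' @export
generatePretrainCorpus <- function(n, spec) {
  if (!is_count(n)) stopf("n must be a non-negative integer")
  n <- as.integer(n)
  if (n == 0L) return(list())
  sz <- spec$imageSize
  with_seed(spec$seed, lapply(seq_len(n), function(i) {
    img <- texture_background2d(sz, sz)
    nblob <- safe_sample1(3:8)
    for (b in seq_len(nblob)) {
      a <- stats::runif(2, spec$objectScale[1],
                        max(spec$objectScale[2], spec$objectScale[1] + 1e-9))
      off <- sample(c(-1, 1), 1L) * stats::runif(1, 0.15, 0.3)
      img <- draw_ellipse2d(img, stats::runif(1, 1, sz), stats::runif(1, 1, sz),
                            a[1], a[2], stats::runif(1, 0, pi), off)$img
    }
    if (spec$textureNoiseSd > 0)
      img <- img + matrix(stats::rnorm(sz * sz, 0, spec$textureNoiseSd), sz, sz)
    clamp01(img)
  }))
}

#' Generate a labeled intensity/label volume pair
#'
#' Builds a (z, y, x) intensity volume in [0,1] (blurred-noise background)
#' and a matching integer [LabelVolume-class].  Each class draws a number
#' of soft-edged ellipsoids whose interior raises or lowers local intensity
#' (alternating sign per class) so segmentation is learnable; overlapping
#' objects resolve to the later-drawn class.  The axial semi-axis of every
#' object is divided by `anisotropyFactor`, emulating coarser z sampling.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `intensity` (numeric array) and `labels`
#'   ([LabelVolume-class], anisotropy recorded as metadata).
#' @examples
#' v <- generateLabeledVolume(syntheticSpec(volumeShape = c(8, 48, 48), seed = 2))
#' table(labelData(v$labels))
#' @export
generateLabeledVolume <- function(spec) {
  d <- spec$volumeShape
  af <- spec$anisotropyFactor
  if (2 * max(spec$objectScale) > min(d[2], d[3]) ||
      2 * max(spec$objectScale) / af > d[1])
    stopf("objectScale up to %g does not fit volumeShape (%s) at anisotropy %g",
          max(spec$objectScale), paste(d, collapse = "x"), af)
  with_seed(spec$seed + 1L, {
    vol <- rescale_range(gauss_blur3d(array(stats::rnorm(prod(d)), d), 2, 2 / af),
                         0.3, 0.7)
    lab <- array(0L, d)
    zc <- seq_len(d[1]); yc <- seq_len(d[2]); xc <- seq_len(d[3])
    for (cl in seq_len(spec$nClasses)) {
      sgn <- if (cl %% 2L == 1L) 1 else -1
      mag <- stats::runif(1, 0.15, 0.3)
      k <- safe_sample1(spec$objectsPerClass[1]:spec$objectsPerClass[2])
      for (o in seq_len(k)) {
        a <- stats::runif(3, spec$objectScale[1],
                          max(spec$objectScale[2], spec$objectScale[1] + 1e-9))
        az <- max(a[1] / af, 0.8)
        cz <- runif_centre(d[1], az)
        cy <- runif_centre(d[2], a[2])
        cx <- runif_centre(d[3], a[3])
        q <- outer(((zc - cz) / az)^2,
                   outer(((yc - cy) / a[2])^2, ((xc - cx) / a[3])^2, `+`), `+`)
        soft <- pmin(pmax((1.2 - q) / 0.4, 0), 1)
        vol <- vol + sgn * mag * soft
        lab[q <= 1] <- cl
      }
    }
    if (spec$textureNoiseSd > 0)
      vol <- vol + array(stats::rnorm(prod(d), 0, spec$textureNoiseSd), d)
    list(intensity = clamp01(vol),
         labels = methods::new("LabelVolume", data = lab, anisotropy = af))
  })
}

#' Split a labeled volume into train and test sets
#'
#' Splits along the slowest (z) axis in contiguous blocks: the leading
#' `round(depth * trainFraction)` slices (clamped so both sets are
#' non-empty) form the training set, the remainder the test set.  The split
#' is deterministic; `seed` is accepted for interface stability.
#'
#' @param pair list with `intensity` and `labels` as returned by
#'   [generateLabeledVolume()].
#' @param trainFraction proportion in (0, 1).
#' @param seed unused; reserved.
#' @return list with `train` and `test` (each a pair list) plus
#'   `trainIdx`/`testIdx` slice index vectors (disjoint, exhaustive).
#' @export
splitDataset <- function(pair, trainFraction, seed = NULL) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stopf("trainFraction must be in (0, 1)")
  vol <- pair$intensity
  depth <- dim(vol)[1]
  if (is.na(depth) || depth < 2L) stopf("volume must have at least 2 slices")
  nTrain <- min(max(round(depth * trainFraction), 1L), depth - 1L)
  trainIdx <- seq_len(nTrain)
  testIdx <- setdiff(seq_len(depth), trainIdx)
  af <- anisotropy(pair$labels)
  subset_pair <- function(idx) list(
    intensity = pair$intensity[idx, , , drop = FALSE],
    labels = methods::new("LabelVolume",
                          data = labelData(pair$labels)[idx, , , drop = FALSE],
                          anisotropy = af))
  list(train = subset_pair(trainIdx), test = subset_pair(testIdx),
       trainIdx = trainIdx, testIdx = testIdx)
}
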