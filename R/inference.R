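## Volumetric inference: slicing, tiled per-plane prediction, orthoplane
## averaging, label extraction.  Volume axis order is fixed as (z, y, x);
## the TIFF page axis maps to z.

plane_names <- c("xy", "xz", "yz")

#' Slice a volume along a cardinal plane
#'
#' `xy` slices index z (each slice is a (y, x) matrix), `xz` slices index y
#' (each slice (z, x)), `yz` slices index x (each slice (z, y)).
#' Reassembling the returned slices reproduces the volume bit-exactly.
#'
#' @param volume 3D numeric array in (z, y, x) order (a 2D matrix is
#'   promoted to a single xy slice).
#' @param plane one of `"xy"`, `"xz"`, `"yz"`.
#' @return list with `slices` (list of matrices), `plane` and `dim`.
#' @export
sliceVolume <- function(volume, plane = "xy") {
  if (!plane %in% plane_names) stopf("plane must be one of xy, xz, yz")
  if (is.matrix(volume)) {
    if (plane != "xy") stopf("2D input supports only the xy plane")
    volume <- array(volume, c(1L, dim(volume)))
  }
  d <- dim(volume)
  if (length(d) != 3L) stopf("volume must be a 3D (z, y, x) array")
  slices <- switch(plane,
    xy = lapply(seq_len(d[1]), function(z) matrix(volume[z, , ], d[2], d[3])),
    xz = lapply(seq_len(d[2]), function(y) matrix(volume[, y, ], d[1], d[3])),
    yz = lapply(seq_len(d[3]), function(x) matrix(volume[, , x], d[1], d[2])))
  list(slices = slices, plane = plane, dim = d)
}

#' Reassemble slices into a volume
#'
#' Inverse of [sliceVolume()].
#'
#' @param sliced list as returned by [sliceVolume()].
#' @return 3D array with the original dimensions.
#' @export
reassembleSlices <- function(sliced) {
  d <- sliced$dim
  vol <- array(0, d)
  for (i in seq_along(sliced$slices)) {
    s <- sliced$slices[[i]]
    switch(sliced$plane,
           xy = {vol[i, , ] <- s},
           xz = {vol[, i, ] <- s},
           yz = {vol[, , i] <- s})
  }
  vol
}

## Predict class probabilities for one 2D slice of arbitrary size:
## reflection-pad up to a multiple of the model input, run overlap-free
## tiles, stitch, crop.  Returns (H, W, C).
predict_slice <- function(predictFn, img, inputSize, nClasses) {
  nr <- nrow(img); nc <- ncol(img)
  nrT <- ceiling(nr / inputSize); ncT <- ceiling(nc / inputSize)
  ri <- reflect_idx(nr, 0L, nrT * inputSize - nr)
  ci <- reflect_idx(nc, 0L, ncT * inputSize - nc)
  padded <- img[ri, ci, drop = FALSE]
  out <- array(0, c(nrow(padded), ncol(padded), nClasses))
  for (ti in seq_len(nrT)) for (tj in seq_len(ncT)) {
    rr <- (ti - 1L) * inputSize + seq_len(inputSize)
    cc <- (tj - 1L) * inputSize + seq_len(inputSize)
    out[rr, cc, ] <- predictFn(padded[rr, cc, drop = FALSE])
  }
  out[seq_len(nr), seq_len(nc), , drop = FALSE]
}

as_predict_fn <- function(model) {
  if (is.function(model)) return(list(fn = model, inputSize = NULL,
                                      nClasses = NULL))
  cfg <- getConfig(model)
  list(fn = function(img) {
         pr <- segmentImages(model, img)           # (1, C, H, W)
         aperm(array(pr[1L, , , ], dim(pr)[-1]), c(2L, 3L, 1L))
       },
       inputSize = cfg$inputSize, nClasses = cfg$nClasses)
}

#' Predict a probability volume slice-wise along one plane
#'
#' Each slice is reflection-padded/tiled to the model input size (no
#' rescaling, so label geometry is preserved), predicted, stitched and
#' cropped back; the per-slice probabilities are reassembled into a
#' [ProbabilityVolume-class] aligned voxel-for-voxel with the input.
#' Anisotropic volumes should use `plane = "xy"` only.
#'
#' @param model a [SegModel-class], or a function `f(image)` returning an
#'   `(H, W, nClasses)` probability array (useful for stubs and testing);
#'   when a function is given, `inputSize`/`nClasses` must be supplied.
#' @param volume 3D (z, y, x) intensity array in [0,1] (or 2D matrix).
#' @param plane slicing plane.
#' @param inputSize,nClasses overrides used when `model` is a plain
#'   function.
#' @return a [ProbabilityVolume-class].
#' @export
predictPlane <- function(model, volume, plane = "xy", inputSize = NULL,
                         nClasses = NULL) {
  pf <- as_predict_fn(model)
  inputSize <- if (is.null(pf$inputSize)) inputSize else pf$inputSize
  nClasses <- if (is.null(pf$nClasses)) nClasses else pf$nClasses
  if (is.null(inputSize) || is.null(nClasses))
    stopf("inputSize and nClasses are required with a function predictor")
  sl <- sliceVolume(volume, plane)
  d <- sl$dim
  probs <- array(0, c(nClasses, d))
  for (i in seq_along(sl$slices)) {
    pr <- predict_slice(pf$fn, sl$slices[[i]], inputSize, nClasses)  # (a,b,C)
    switch(plane,
           xy = {probs[, i, , ] <- aperm(pr, c(3L, 1L, 2L))},
           xz = {probs[, , i, ] <- aperm(pr, c(3L, 1L, 2L))},
           yz = {probs[, , , i] <- aperm(pr, c(3L, 1L, 2L))})
  }
  methods::new("ProbabilityVolume", data = probs)
}

#' Orthoplane prediction for isotropic volumes
#'
#' Predicts the volume slice-wise on the xy, xz and yz planes and averages
#' the three probability volumes voxel-wise (the mean of three softmax
#' distributions is again a distribution).  Warns when the volume is
#' declared anisotropic, where xy-only prediction is the appropriate mode.
#'
#' @inheritParams predictPlane
#' @param anisotropy declared anisotropy factor of the volume (1 =
#'   isotropic).
#' @return a [ProbabilityVolume-class].
#' @export
orthoplanePredict <- function(model, volume, anisotropy = 1, inputSize = NULL,
                              nClasses = NULL) {
  if (anisotropy != 1)
    warning("orthoplane prediction on an anisotropic volume; ",
            "xy-only prediction is recommended", call. = FALSE)
  ps <- lapply(plane_names, function(pl)
    probData(predictPlane(model, volume, pl, inputSize, nClasses)))
  methods::new("ProbabilityVolume",
               data = (ps[[1]] + ps[[2]] + ps[[3]]) / 3)
}

#' Extract labels from a probability volume
#'
#' Voxel-wise argmax over the class axis; ties break toward the smaller
#' class ID.
#'
#' @param probs a [ProbabilityVolume-class].
#' @param anisotropy anisotropy factor recorded on the returned
#'   [LabelVolume-class].
#' @return a [LabelVolume-class] with values in `0..nClasses-1`.
#' @export
labelsFromProbs <- function(probs, anisotropy = 1) {
  pd <- probData(probs)
  d <- dim(pd)
  m <- matrix(pd, d[1], prod(d[-1]))
  lab <- max.col(t(m), ties.method = "first") - 1L
  methods::new("LabelVolume", data = array(as.integer(lab), d[-1]),
               anisotropy = anisotropy)
}
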