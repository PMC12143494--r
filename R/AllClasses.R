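#' Augmented image pair for reconstruction pre-training
#'
#' Couples a corrupted network input with its geometrically aligned clean
#' reconstruction target, together with the sampled transform records so the
#' pair can be replayed bit-exactly.  The target is the original image after
#' the geometric transform only; the input is the target after the
#' photometric/masking corruption.
#'
#' @slot input numeric matrix in [0,1]; the corrupted image fed to the network.
#' @slot target numeric matrix in [0,1]; the clean, geometrically aligned target.
#' @slot geometric list with elements \code{flip_h}, \code{flip_v},
#'   \code{rot90_k} (counter-clockwise quarter turns, 0--3).
#' @slot corruption list describing brightness/contrast/noise/blur/masking
#'   (see [corruptImage()]).
#'
#' @seealso [makeAugmentedPair()], [applyGeometric()], [corruptImage()]
#' @export
setClass("AugmentedPair",
  representation(input = "matrix", target = "matrix",
                 geometric = "list", corruption = "list"))

setValidity("AugmentedPair", function(object) {
  if (!identical(dim(object@input), dim(object@target)))
    return("input and target must have identical dimensions")
  if (min(object@input) < 0 || max(object@input) > 1)
    return("input values must lie in [0,1]")
  if (!object@geometric$rot90_k %in% 0:3)
    return("rot90_k must be in 0..3")
  TRUE
})

#' Hybrid CNN--transformer segmentation model
#'
#' An encoder--decoder in which convolutional stages extract multi-scale
#' features, a patch embedding tokenises the final feature map, pre-norm
#' transformer blocks (multi-head self-attention + MLP) refine the tokens,
#' and a convolutional decoder with skip connections restores full
#' resolution.  Two interchangeable heads share the trunk: a single-channel
#' reconstruction head and an \code{n_classes}-channel segmentation head.
#'
#' Every parameter belongs to exactly one named family
#' (\code{conv_encoder}, \code{transformer}, \code{decoder}, \code{head});
#' the partition drives selective transfer and freezing.
#'
#' @slot config list produced by [modelConfig()].
#' @slot params named list of numeric parameter arrays.
#' @slot families named list mapping family name -> character vector of
#'   parameter names.
#'
#' @slot freeze character vector of family names currently frozen (excluded
#'   from optimizer updates); see [setTrainable()].
#'
#' @seealso [buildModel()], [paramFamilies()], [transferTransformerParams()]
#' @export
setClass("SegModel",
  representation(config = "list", params = "list", families = "list",
                 freeze = "character"),
  prototype(freeze = character()))

setValidity("SegModel", function(object) {
  fam <- unlist(object@families, use.names = FALSE)
  if (anyDuplicated(fam)) return("parameter families overlap")
  if (!setequal(fam, names(object@params)))
    return("families must partition the parameter set")
  if (!setequal(names(object@families),
                c("conv_encoder", "transformer", "decoder", "head")))
    return("families must be conv_encoder, transformer, decoder, head")
  if (!all(object@freeze %in% names(object@families)))
    return("freeze must name existing families")
  TRUE
})

#' @describeIn SegModel-class family names currently frozen
#' @export
setGeneric("frozenFamilies", function(object) standardGeneric("frozenFamilies"))
setMethod("frozenFamilies", "SegModel", function(object) object@freeze)

#' Training checkpoint
#'
#' Snapshot of all model parameters with their family map, the model and
#' training configurations, the iteration counter and the per-iteration loss
#' history.  Save/load round trips ([saveCheckpoint()]) are bit-exact.
#'
#' @slot params named list of parameter arrays.
#' @slot families family -> parameter-name map (as in [SegModel-class]).
#' @slot modelConfig the [modelConfig()] list the parameters belong to.
#' @slot trainConfig the [trainConfig()] list used to produce them.
#' @slot iteration integer update counter.
#' @slot lossHistory numeric vector, one entry per batch-level update.
#' @export
setClass("TrainingCheckpoint",
  representation(params = "list", families = "list", modelConfig = "list",
                 trainConfig = "list", iteration = "integer",
                 lossHistory = "numeric"))

#' Integer label volume
#'
#' A 2D or 3D array of integer class IDs (0 = background) in fixed
#' \code{(z, y, x)} axis order for 3D data, carrying the axial anisotropy
#' factor (ratio of z spacing to in-plane spacing; 1 = isotropic) as
#' metadata.
#'
#' @slot data integer array of class IDs.
#' @slot anisotropy numeric scalar >= 1.
#' @export
setClass("LabelVolume",
  representation(data = "array", anisotropy = "numeric"))

setValidity("LabelVolume", function(object) {
  if (any(object@data < 0) || any(object@data != floor(object@data)))
    return("labels must be non-negative integers")
  if (length(object@anisotropy) != 1L || object@anisotropy < 1)
    return("anisotropy must be a single value >= 1")
  TRUE
})

#' Per-class probability volume
#'
#' Class probabilities aligned voxel-for-voxel with an intensity volume,
#' stored as a \code{(n_classes, z, y, x)} array.  At every voxel the class
#' axis sums to 1 (within 1e-5).
#'
#' @slot data numeric array shaped (n_classes, z, y, x).
#' @export
setClass("ProbabilityVolume", representation(data = "array"))

setValidity("ProbabilityVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be (n_classes, z, y, x)")
  if (min(object@data) < -1e-8 || max(object@data) > 1 + 1e-8)
    return("probabilities must lie in [0,1]")
  s <- apply(object@data, 2:4, sum)
  if (max(abs(s - 1)) > 1e-5)
    return("class probabilities must sum to 1 at every voxel")
  TRUE
})

#' Semantic segmentation metric report
#'
#' Per-class IoU/precision/recall/F-score/Mean-False-Distance plus
#' aggregates, with an optional CREMI-style block (ADGT, ADF, their mean,
#' FP/FN counts, 1 - F).
#'
#' @slot perClass data.frame with one row per evaluated class.
#' @slot aggregate list with \code{mean_iou}, \code{mean_f} (and friends).
#' @slot cremi list (possibly empty) with \code{adgt}, \code{adf},
#'   \code{cremi_score}, \code{fp}, \code{fn}, \code{one_minus_f}.
#' @export
setClass("MetricReport",
  representation(perClass = "data.frame", aggregate = "list", cremi = "list"))

## ---- accessors ------------------------------------------------------------

#' @describeIn AugmentedPair-class the corrupted network input
#' @param object an object of the documented class
#' @export
setGeneric("inputImage", function(object) standardGeneric("inputImage"))
#' @describeIn AugmentedPair-class the clean aligned target
#' @export
setGeneric("targetImage", function(object) standardGeneric("targetImage"))
#' @describeIn AugmentedPair-class the geometric transform record
#' @export
setGeneric("geometricRecord", function(object) standardGeneric("geometricRecord"))
#' @describeIn AugmentedPair-class the corruption record
#' @export
setGeneric("corruptionRecord", function(object) standardGeneric("corruptionRecord"))

setMethod("inputImage", "AugmentedPair", function(object) object@input)
setMethod("targetImage", "AugmentedPair", function(object) object@target)
setMethod("geometricRecord", "AugmentedPair", function(object) object@geometric)
setMethod("corruptionRecord", "AugmentedPair", function(object) object@corruption)

#' @describeIn SegModel-class the model configuration list
#' @param object an object of the documented class
#' @export
setGeneric("getConfig", function(object) standardGeneric("getConfig"))
#' @describeIn SegModel-class named list of parameter arrays
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))
#' @describeIn SegModel-class family -> parameter-name map
#' @export
setGeneric("paramFamilies", function(object) standardGeneric("paramFamilies"))

setMethod("getConfig", "SegModel", function(object) object@config)
setMethod("modelParams", "SegModel", function(object) object@params)
setMethod("paramFamilies", "SegModel", function(object) object@families)
setMethod("getConfig", "TrainingCheckpoint", function(object) object@modelConfig)
setMethod("modelParams", "TrainingCheckpoint", function(object) object@params)
setMethod("paramFamilies", "TrainingCheckpoint", function(object) object@families)

#' @describeIn TrainingCheckpoint-class per-iteration loss values
#' @param object an object of the documented class
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))
setMethod("lossHistory", "TrainingCheckpoint", function(object) object@lossHistory)

#' @describeIn LabelVolume-class the integer class-ID array
#' @param object an object of the documented class
#' @export
setGeneric("labelData", function(object) standardGeneric("labelData"))
#' @describeIn LabelVolume-class axial anisotropy factor
#' @export
setGeneric("anisotropy", function(object) standardGeneric("anisotropy"))
setMethod("labelData", "LabelVolume", function(object) object@data)
setMethod("anisotropy", "LabelVolume", function(object) object@anisotropy)

#' @describeIn ProbabilityVolume-class the (n_classes, z, y, x) array
#' @param object an object of the documented class
#' @export
setGeneric("probData", function(object) standardGeneric("probData"))
setMethod("probData", "ProbabilityVolume", function(object) object@data)

#' @describeIn MetricReport-class per-class metric table
#' @param object an object of the documented class
#' @export
setGeneric("perClassMetrics", function(object) standardGeneric("perClassMetrics"))
#' @describeIn MetricReport-class aggregate metrics list
#' @export
setGeneric("aggregateMetrics", function(object) standardGeneric("aggregateMetrics"))
#' @describeIn MetricReport-class CREMI-style metric block (may be empty)
#' @export
setGeneric("cremiMetrics", function(object) standardGeneric("cremiMetrics"))
setMethod("perClassMetrics", "MetricReport", function(object) object@perClass)
setMethod("aggregateMetrics", "MetricReport", function(object) object@aggregate)
setMethod("cremiMetrics", "MetricReport", function(object) object@cremi)

## ---- show methods ---------------------------------------------------------

setMethod("show", "AugmentedPair", function(object) {
  g <- object@geometric
  cat(sprintf("AugmentedPair %dx%d | flip_h=%s flip_v=%s rot90_k=%d | %d masked patch(es)\n",
              nrow(object@input), ncol(object@input), g$flip_h, g$flip_v,
              g$rot90_k,
              if (is.null(object@corruption$mask_patches)) 0L
              else nrow(object@corruption$mask_patches)))
})

setMethod("show", "SegModel", function(object) {
  np <- vapply(object@families, function(f)
    sum(vapply(object@params[f], length, 1L)), 1)
  cat(sprintf("SegModel: input %dx%d, %d conv stage(s), %d transformer block(s), %d class(es)\n",
              object@config$inputSize, object@config$inputSize,
              length(object@config$convChannels), object@config$nLayers,
              object@config$nClasses))
  cat("  parameters by family:\n")
  for (f in names(np)) cat(sprintf("    %-13s %d\n", f, np[[f]]))
})

setMethod("show", "TrainingCheckpoint", function(object) {
  cat(sprintf("TrainingCheckpoint: iteration %d, %d parameter array(s)\n",
              object@iteration, length(object@params)))
  if (length(object@lossHistory))
    cat(sprintf("  loss: first %.5f, last %.5f\n",
                object@lossHistory[1], utils::tail(object@lossHistory, 1)))
})

setMethod("show", "LabelVolume", function(object) {
  cat(sprintf("LabelVolume %s | classes present: {%s} | anisotropy %.3g\n",
              paste(dim(object@data), collapse = "x"),
              paste(sort(unique(as.vector(object@data))), collapse = ","),
              object@anisotropy))
})

setMethod("show", "ProbabilityVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ProbabilityVolume: %d class(es) over %dx%dx%d (z,y,x)\n",
              d[1], d[2], d[3], d[4]))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n")
  print(object@perClass, row.names = FALSE)
  cat(sprintf("  mean IoU %.4f | mean F %.4f\n",
              object@aggregate$mean_iou, object@aggregate$mean_f))
  if (length(object@cremi))
    cat(sprintf("  CREMI: ADGT %.4f ADF %.4f score %.4f\n",
                object@cremi$adgt, object@cremi$adf, object@cremi$cremi_score))
})
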