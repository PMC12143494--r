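## Exact squared Euclidean distance transform (lower-envelope-of-parabolas
## algorithm), applied separably per axis with per-axis sample spacing.
## Background-only lines stay Inf.

dt1d_sq <- function(f, w) {
  n <- length(f)
  idx <- which(is.finite(f))
  if (!length(idx)) return(rep(Inf, n))
  m <- length(idx)
  v <- integer(m); z <- numeric(m + 1L)
  k <- 1L; v[1] <- idx[1]; z[1] <- -Inf; z[2] <- Inf
  if (m > 1L) for (qi in 2:m) {
    q <- idx[qi]
    repeat {
      p <- v[k]
      s <- ((f[q] + (q * w)^2) - (f[p] + (p * w)^2)) / (2 * w * (q - p))
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q * w) k <- k + 1L
    p <- v[k]
    d[q] <- (q - p)^2 * w^2 + f[p]
  }
  d
}

#' Euclidean distance transform of a foreground mask
#'
#' Exact distance from every voxel to the nearest foreground (TRUE) voxel,
#' with optional anisotropic voxel spacing.  Distances are computed on
#' foreground voxel sets (not surfaces).  An all-background mask yields
#' `Inf` everywhere.
#'
#' @param mask logical 2D or 3D array.
#' @param spacing numeric voxel spacing per axis (length = number of
#'   dimensions; 3D axis order (z, y, x)).
#' @return numeric array of distances, same shape as `mask`.
#' @export
distanceTransform <- function(mask, spacing = NULL) {
  d <- dim(mask)
  nd <- length(d)
  if (is.null(spacing)) spacing <- rep(1, nd)
  if (length(spacing) != nd) stopf("spacing must have one value per axis")
  f <- array(ifelse(mask, 0, Inf), d)
  if (nd == 2L) {
    for (i in seq_len(d[1])) f[i, ] <- dt1d_sq(f[i, ], spacing[2])
    for (j in seq_len(d[2])) f[, j] <- dt1d_sq(f[, j], spacing[1])
  } else if (nd == 3L) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      f[i, j, ] <- dt1d_sq(f[i, j, ], spacing[3])
    for (i in seq_len(d[1])) for (k in seq_len(d[3]))
      f[i, , k] <- dt1d_sq(f[i, , k], spacing[2])
    for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      f[, j, k] <- dt1d_sq(f[, j, k], spacing[1])
  } else stopf("mask must be 2D or 3D")
  sqrt(f)
}

as_label_array <- function(x) {
  if (methods::is(x, "LabelVolume")) labelData(x) else x
}

#' Confusion counts for one class
#'
#' Treats `classId` as foreground in both volumes and counts true/false
#' positives/negatives over all voxels; the four counts sum to the voxel
#' count.
#'
#' @param pred,gt integer label arrays or [LabelVolume-class] objects of
#'   equal shape.
#' @param classId the class treated as foreground.
#' @return named numeric vector `(tp, fp, fn, tn)`.
#' @export
confusionCounts <- function(pred, gt, classId) {
  p <- as_label_array(pred); g <- as_label_array(gt)
  if (!identical(dim(p), dim(g))) stopf("pred and gt shapes differ")
  pf <- p == classId; gf <- g == classId
  tp <- sum(pf & gf)
  c(tp = tp, fp = sum(pf) - tp, fn = sum(gf) - tp,
    tn = sum(!pf & !gf))
}

#' Pixel-level semantic scores for one class
#'
#' IoU (Jaccard) = tp/(tp+fp+fn), precision = tp/(tp+fp), recall =
#' tp/(tp+fn), F = 2PR/(P+R).  If both masks are empty all four scores are
#' 1 (perfect agreement); if exactly one is empty the ratios follow the
#' formulas with 0 where a denominator vanishes.
#'
#' @inheritParams confusionCounts
#' @return list with `iou`, `precision`, `recall`, `f_score`.
#' @export
semanticScores <- function(pred, gt, classId) {
  cc <- confusionCounts(pred, gt, classId)
  tp <- cc["tp"]; fp <- cc["fp"]; fn <- cc["fn"]
  if (tp + fp + fn == 0)
    return(list(iou = 1, precision = 1, recall = 1, f_score = 1))
  ratio <- function(num, den) if (den == 0) 0 else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  list(iou = unname(tp / (tp + fp + fn)), precision = unname(precision),
       recall = unname(recall),
       f_score = unname(ratio(2 * precision * recall, precision + recall)))
}

mask_of <- function(x, classId) as_label_array(x) == classId

spacing_for <- function(m, spacing) {
  if (!is.null(spacing)) return(spacing)
  rep(1, length(dim(m)))
}

#' Mean False Distance between two masks
#'
#' Mean of the two directed Hausdorff distances between the foreground
#' voxel sets: `d(A -> B) = max_{a in A} min_{b in B} ||a - b||`, Euclidean,
#' scaled by the voxel spacing.  Undefined (error) when either mask is
#' empty; report it as missing rather than 0 in that case.
#'
#' @param pred,gt label arrays or [LabelVolume-class] objects.
#' @param classId foreground class.
#' @param spacing per-axis voxel spacing (defaults to isotropic 1).
#' @return non-negative scalar distance.
#' @export
meanFalseDistance <- function(pred, gt, classId = 1L, spacing = NULL) {
  pm <- mask_of(pred, classId); gm <- mask_of(gt, classId)
  if (!identical(dim(pm), dim(gm))) stopf("pred and gt shapes differ")
  if (!any(pm) || !any(gm))
    stopf("mean false distance undefined for an empty mask; report as missing")
  sp <- spacing_for(pm, spacing)
  dg <- distanceTransform(gm, sp)
  dp <- distanceTransform(pm, sp)
  (max(dg[pm]) + max(dp[gm])) / 2
}

#' CREMI-style distance metrics
#'
#' ADGT is the average distance of any predicted foreground voxel to the
#' closest ground-truth foreground voxel; ADF is the average distance of
#' any ground-truth foreground voxel to the closest predicted voxel; the
#' CREMI score is their mean.  FP/FN come from the confusion counts and
#' `one_minus_f` is 1 - F-score.  If either mask is empty the distance
#' terms cannot be calculated and are reported as `NA`.
#'
#' @inheritParams meanFalseDistance
#' @return list with `adgt`, `adf`, `cremi_score`, `fp`, `fn`,
#'   `one_minus_f`.
#' @export
cremiScores <- function(pred, gt, classId = 1L, spacing = NULL) {
  pm <- mask_of(pred, classId); gm <- mask_of(gt, classId)
  if (!identical(dim(pm), dim(gm))) stopf("pred and gt shapes differ")
  cc <- confusionCounts(pred, gt, classId)
  sc <- semanticScores(pred, gt, classId)
  if (!any(pm) || !any(gm)) {
    adgt <- NA_real_; adf <- NA_real_; cs <- NA_real_
  } else {
    sp <- spacing_for(pm, spacing)
    adgt <- mean(distanceTransform(gm, sp)[pm])
    adf <- mean(distanceTransform(pm, sp)[gm])
    cs <- (adgt + adf) / 2
  }
  list(adgt = adgt, adf = adf, cremi_score = cs,
       fp = unname(cc["fp"]), fn = unname(cc["fn"]),
       one_minus_f = 1 - sc$f_score)
}

#' Evaluate a predicted labeling against ground truth
#'
#' Builds a [MetricReport-class]: per-class IoU/precision/recall/F plus the
#' Mean False Distance (missing when a mask is empty), and aggregate means
#' over foreground classes (background excluded unless requested).
#' Distance metrics are reported per class and never averaged with the
#' ratio metrics.
#'
#' @param pred,gt label arrays or [LabelVolume-class] objects of equal shape.
#' @param classes integer vector of class IDs to evaluate; defaults to all
#'   foreground classes present in `gt` (or in `pred` when `gt` is empty).
#' @param spacing per-axis voxel spacing; defaults to (anisotropy, 1, 1)
#'   when `gt` is a [LabelVolume-class] with 3D data.
#' @param includeBackground also evaluate class 0 and include it in the
#'   aggregates.
#' @param cremi also compute the CREMI block for the (single) foreground
#'   class.
#' @return a [MetricReport-class].
#' @export
evaluateSegmentation <- function(pred, gt, classes = NULL, spacing = NULL,
                                 includeBackground = FALSE, cremi = FALSE) {
  p <- as_label_array(pred); g <- as_label_array(gt)
  if (!identical(dim(p), dim(g))) stopf("pred and gt shapes differ")
  if (is.null(spacing) && methods::is(gt, "LabelVolume") &&
      length(dim(g)) == 3L)
    spacing <- c(anisotropy(gt), 1, 1)
  if (is.null(classes)) {
    classes <- sort(unique(c(g[g > 0], p[p > 0])))
    if (!length(classes)) classes <- 1L
  }
  if (includeBackground) classes <- union(0L, classes)
  rows <- lapply(classes, function(cl) {
    sc <- semanticScores(p, g, cl)
    mfd <- if (any(p == cl) && any(g == cl))
      meanFalseDistance(p, g, cl, spacing) else NA_real_
    data.frame(class = cl, iou = sc$iou, precision = sc$precision,
               recall = sc$recall, f_score = sc$f_score, mfd = mfd)
  })
  tab <- do.call(rbind, rows)
  fg <- if (includeBackground) tab else tab[tab$class != 0, , drop = FALSE]
  if (!nrow(fg)) fg <- tab
  agg <- list(mean_iou = mean(fg$iou), mean_f = mean(fg$f_score),
              mean_precision = mean(fg$precision),
              mean_recall = mean(fg$recall))
  cr <- if (cremi) cremiScores(p, g, classes[classes > 0][1], spacing)
        else list()
  methods::new("MetricReport", perClass = tab, aggregate = agg, cremi = cr)
}

#' Aggregate metric reports across tasks or classes
#'
#' `"mean_over_tasks"` takes the unweighted mean of each report's aggregate
#' metrics — the convention for benchmarks whose structures are trained as
#' independent binary tasks and then averaged into a final IoU.
#' `"mean_over_classes"` pools all foreground-class rows across reports and
#' averages them (background excluded).
#'
#' @param reports non-empty list of [MetricReport-class] objects.
#' @param scheme aggregation scheme.
#' @return list with `mean_iou`, `mean_f`, `mean_precision`, `mean_recall`
#'   and `n` (tasks or classes averaged).
#' @examples
#' ## task-average of per-structure binary IoUs
#' r <- lapply(c(0.885, 0.890, 0.991, 0.910), function(x)
#'   methods::new("MetricReport",
#'                perClass = data.frame(class = 1, iou = x, precision = x,
#'                                      recall = x, f_score = x, mfd = NA),
#'                aggregate = list(mean_iou = x, mean_f = x,
#'                                 mean_precision = x, mean_recall = x),
#'                cremi = list()))
#' aggregateReports(r)$mean_iou  # 0.919
#' @export
aggregateReports <- function(reports,
                             scheme = c("mean_over_tasks", "mean_over_classes")) {
  scheme <- match.arg(scheme)
  if (!length(reports)) stopf("reports must be non-empty")
  if (methods::is(reports, "MetricReport")) reports <- list(reports)
  if (scheme == "mean_over_tasks") {
    pick <- function(field)
      mean(vapply(reports, function(r) aggregateMetrics(r)[[field]], 1))
    list(mean_iou = pick("mean_iou"), mean_f = pick("mean_f"),
         mean_precision = pick("mean_precision"),
         mean_recall = pick("mean_recall"), n = length(reports))
  } else {
    tab <- do.call(rbind, lapply(reports, perClassMetrics))
    tab <- tab[tab$class != 0, , drop = FALSE]
    if (!nrow(tab)) stopf("no foreground classes to aggregate")
    list(mean_iou = mean(tab$iou), mean_f = mean(tab$f_score),
         mean_precision = mean(tab$precision), mean_recall = mean(tab$recall),
         n = nrow(tab))
  }
}
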