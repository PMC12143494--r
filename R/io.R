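## Readers/writers for the supported plain formats.  Volumes travel as
## multi-page TIFF (page axis = z) or single-page PNG (2D), with a JSON
## sidecar (<path>.json) carrying kind ("intensity"/"labels"), axis order
## and anisotropy.  Checkpoints are serialized with R's native
## serialization (bit-exact round trip).

ext_of <- function(path) tolower(tools::file_ext(path))

stop_config <- function(fmt, ...) {
  stop(structure(class = c("retina_config_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

stop_data <- function(fmt, ...) {
  stop(structure(class = c("retina_data_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write an intensity or label volume
#'
#' Multi-page TIFF (`.tif`/`.tiff`; float32 for intensities, 8-bit for
#' labels) or PNG (`.png`, 2D only).  A JSON sidecar `<path>.json` records
#' the kind, the (z, y, x) axis order and the anisotropy factor.
#'
#' @param data numeric array (z, y, x), 2D matrix, or a
#'   [LabelVolume-class].
#' @param path output path; extension selects the format.
#' @param metadata optional list; `anisotropy` defaults to 1 (or the
#'   [LabelVolume-class] metadata).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(data, path, metadata = list()) {
  kind <- "intensity"
  if (methods::is(data, "LabelVolume")) {
    if (is.null(metadata$anisotropy)) metadata$anisotropy <- anisotropy(data)
    data <- labelData(data)
    kind <- "labels"
  } else if (is.integer(data) || isTRUE(metadata$kind == "labels")) {
    kind <- "labels"
  }
  if (is.null(metadata$anisotropy)) metadata$anisotropy <- 1
  metadata$kind <- kind
  metadata$axis_order <- "zyx"
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  d <- dim(data)
  if (length(d) != 3L) stop_data("volume must be 2D or 3D")
  pages <- lapply(seq_len(d[1]), function(z) matrix(data[z, , ], d[2], d[3]))
  ext <- ext_of(path)
  if (ext %in% c("tif", "tiff")) {
    if (kind == "labels") {
      if (max(data) > 255) stop_data("label values exceed 8-bit range")
      pages <- lapply(pages, function(m) m / 255)
      tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
    } else {
      tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
    }
  } else if (ext == "png") {
    if (d[1] != 1L) stop_data("PNG supports 2D images only")
    png::writePNG(if (kind == "labels") pages[[1]] / 255 else pages[[1]], path)
  } else if (ext %in% c("h5", "hdf5")) {
    stop_config("HDF5 output is not supported by this build; use TIFF")
  } else {
    stop_config("unknown volume format '.%s' (use .tif/.tiff or .png)", ext)
  }
  jsonlite::write_json(metadata, sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read an intensity or label volume
#'
#' Inverse of [writeVolume()]; the sidecar (when present) restores kind and
#' anisotropy.  Returns intensities as a numeric (z, y, x) array in [0,1]
#' and labels as integers.
#'
#' @param path file path (`.tif`/`.tiff`/`.png`).
#' @return list with `data` (array) and `metadata` (list).
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  else list(kind = "intensity", anisotropy = 1, axis_order = "zyx")
  ext <- ext_of(path)
  labels <- identical(meta$kind, "labels")
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = labels)
    if (is.matrix(pages)) pages <- list(pages)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    pages <- list(if (labels) round(img * 255) else img)
  } else if (ext %in% c("h5", "hdf5")) {
    stop_config("HDF5 input is not supported by this build; use TIFF")
  } else {
    stop_config("unknown volume format '.%s'", ext)
  }
  d <- c(length(pages), dim(pages[[1]]))
  vol <- array(if (labels) 0L else 0, d)
  for (z in seq_len(d[1])) vol[z, , ] <- pages[[z]]
  if (labels) storage.mode(vol) <- "integer"
  list(data = vol, metadata = meta)
}

#' Read a volume as a LabelVolume object
#'
#' @param path label volume path written by [writeVolume()].
#' @return a [LabelVolume-class].
#' @export
readLabelVolume <- function(path) {
  v <- readVolume(path)
  af <- if (is.null(v$metadata$anisotropy)) 1 else v$metadata$anisotropy
  methods::new("LabelVolume", data = v$data, anisotropy = af)
}

#' Write / read an unlabeled patch corpus as a PNG directory
#'
#' @param corpus list of matrices in [0,1].
#' @param dir output directory (created if needed).
#' @return the directory (write) or list of matrices (read), invisibly for
#'   the writer.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(corpus))
    png::writePNG(corpus[[i]], file.path(dir, sprintf("patch_%05d.png", i)))
  invisible(dir)
}

#' @rdname writeCorpus
#' @export
readCorpus <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop_data("no PNG patches found in %s", dir)
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img
  })
}

#' Save / load a training checkpoint
#'
#' Bit-exact round trip of all parameter arrays, the family map, config
#' snapshots, iteration counter and loss history.
#'
#' @param ckpt a [TrainingCheckpoint-class].
#' @param path file path (conventionally `.rds`).
#' @return `path` invisibly (save); the checkpoint (load).
#' @export
saveCheckpoint <- function(ckpt, path) {
  if (!methods::is(ckpt, "TrainingCheckpoint"))
    stopf("ckpt must be a TrainingCheckpoint")
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop_data("checkpoint not found: %s", path)
  ckpt <- readRDS(path)
  if (!methods::is(ckpt, "TrainingCheckpoint"))
    stop_data("corrupt checkpoint: not a TrainingCheckpoint object")
  if (!length(ckpt@families))
    stop_data("corrupt checkpoint: family map missing")
  ckpt
}

#' Write a metric report as JSON
#'
#' @param report a [MetricReport-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeMetricReport <- function(report, path) {
  out <- list(per_class = perClassMetrics(report),
              aggregate = aggregateMetrics(report))
  if (length(cremiMetrics(report))) out$cremi <- cremiMetrics(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
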