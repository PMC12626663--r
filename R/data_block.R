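#' Construct a multispectral data block
#'
#' A data block is the complete acquisition for one sample area: one grayscale
#' intensity image per spectral channel plus a brightfield image, with sample
#' metadata. All images must share the same pixel geometry and the channel
#' image set must match the governing channel table exactly.
#'
#' @param sample_id,patient_id Identifiers.
#' @param group_label Group name (e.g. `"ATN"`, `"REJECTION"`, `"IFTA"`, or a
#'   synthetic group name).
#' @param channels A `channel_table`.
#' @param images Named list of 2-D numeric matrices, names = channel ids, in
#'   channel-table order.
#' @param brightfield 2-D numeric matrix, same shape as the channel images.
#' @param calibrated Logical; raw camera blocks are `FALSE`, the output of
#'   [calibrate_block()] is `TRUE`.
#' @return Object of class `data_block`.
#' @export
data_block <- function(sample_id, patient_id, group_label, channels, images,
                       brightfield, calibrated = FALSE) {
  block <- structure(
    list(sample_id = sample_id, patient_id = patient_id,
         group_label = group_label, channels = channels, images = images,
         brightfield = brightfield, calibrated = isTRUE(calibrated)),
    class = "data_block"
  )
  validate_data_block(block)
}

#' Validate a data block against its channel table
#'
#' @param block A `data_block`.
#' @return The block, invisibly, or an error describing the violation.
#' @export
validate_data_block <- function(block) {
  channels <- validate_channel_table(block$channels)
  if (!identical(names(block$images), channels$channel_id)) {
    missing <- setdiff(channels$channel_id, names(block$images))
    extra <- setdiff(names(block$images), channels$channel_id)
    if (length(missing)) {
      stop("incomplete block: missing channel image(s) ",
           paste(missing, collapse = ", "))
    }
    if (length(extra)) {
      stop("block has image(s) not in the channel table: ",
           paste(extra, collapse = ", "))
    }
    stop("channel images out of channel-table order")
  }
  shp <- dim(block$brightfield)
  for (id in names(block$images)) {
    img <- block$images[[id]]
    if (!is.matrix(img) || any(img < 0, na.rm = TRUE)) {
      stop("channel ", id, " is not a nonnegative 2-D matrix")
    }
    if (!identical(dim(img), shp)) {
      stop("geometry error: channel ", id, " shape (",
           paste(dim(img), collapse = "x"),
           ") differs from brightfield (", paste(shp, collapse = "x"), ")")
    }
  }
  block
}

#' @export
print.data_block <- function(x, ...) {
  cat(sprintf("<data_block> %s  patient %s  group %s\n  %d channels, %dx%d px, %s\n",
              x$sample_id, x$patient_id, x$group_label,
              length(x$images), nrow(x$brightfield), ncol(x$brightfield),
              if (x$calibrated) "calibrated" else "raw"))
  invisible(x)
}

#' Pixel geometry of a block
#' @param block A `data_block`.
#' @return Integer vector `(rows, cols)`.
#' @export
pixel_shape <- function(block) dim(block$brightfield)

MAX_COUNT <- 65535L  # 16-bit camera full scale used for integer TIFF storage

write_image_tiff <- function(img, path, float = FALSE) {
  if (float) {
    scale <- max(img, 1e-12)
    tiff::writeTIFF(img / scale, path, bits.per.sample = 32L,
                    compression = "none")
    scale
  } else {
    if (any(img > MAX_COUNT)) {
      stop("integer TIFF overflow: counts exceed ", MAX_COUNT)
    }
    tiff::writeTIFF(round(img) / MAX_COUNT, path, bits.per.sample = 16L,
                    compression = "none")
    1
  }
}

read_image_tiff <- function(path, scale = 1, float = FALSE) {
  if (float) {
    img <- tiff::readTIFF(path) * scale
  } else {
    img <- tiff::readTIFF(path, as.is = TRUE)
    storage.mode(img) <- "double"
  }
  img
}

#' Write a data block to a directory
#'
#' Raw blocks are stored as one 16-bit unsigned TIFF per channel (cameras are
#' integer-valued), calibrated blocks as 32-bit float TIFFs with a per-channel
#' scale recorded in the manifest (float TIFF payloads are stored normalized to
#' [0, 1]). A JSON manifest carries the channel table, metadata and file list;
#' [read_data_block()] on the result reproduces the block (bit-exactly for raw
#' integer blocks).
#'
#' @param block A valid `data_block`.
#' @param directory Output directory (created if needed).
#' @return Path of the JSON manifest, invisibly.
#' @export
write_data_block <- function(block, directory) {
  validate_data_block(block)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  float <- block$calibrated
  scales <- numeric(0)
  for (id in names(block$images)) {
    scales[[id]] <- write_image_tiff(block$images[[id]],
                                     file.path(directory, paste0(id, ".tif")),
                                     float = float)
  }
  bf_scale <- write_image_tiff(block$brightfield,
                               file.path(directory, "brightfield.tif"),
                               float = float)
  manifest <- list(
    sample_id = block$sample_id,
    patient_id = block$patient_id,
    group_label = block$group_label,
    pixel_shape = dim(block$brightfield),
    calibrated = block$calibrated,
    channel_scales = as.list(scales),
    brightfield_scale = bf_scale,
    channels = unclass(block$channels)
  )
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a data block from a directory written by [write_data_block()]
#'
#' @param directory Block directory containing per-channel TIFFs,
#'   `brightfield.tif` and `manifest.json`.
#' @return A `data_block`.
#' @export
read_data_block <- function(directory) {
  mpath <- file.path(directory, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json under ", directory)
  manifest <- jsonlite::fromJSON(mpath)
  channels <- validate_channel_table(as.data.frame(manifest$channels))
  float <- isTRUE(manifest$calibrated)
  images <- list()
  for (id in channels$channel_id) {
    f <- file.path(directory, paste0(id, ".tif"))
    if (!file.exists(f)) stop("incomplete block: missing channel file for ", id)
    scale <- if (float) manifest$channel_scales[[id]] else 1
    images[[id]] <- read_image_tiff(f, scale = scale, float = float)
  }
  brightfield <- read_image_tiff(file.path(directory, "brightfield.tif"),
                                 scale = manifest$brightfield_scale,
                                 float = float)
  data_block(manifest$sample_id, manifest$patient_id, manifest$group_label,
             channels, images, brightfield, calibrated = float)
}

#' Read cell masks from a 16-bit label TIFF
#'
#' Label value 0 is background; each positive integer labels the pixels of one
#' cell. Distinct cells are disjoint by construction of a label image.
#'
#' @param path Path to a label TIFF (or an integer label matrix, accepted
#'   directly).
#' @return A list of masks, each `list(cell_id, label, pixels, area_px)` where
#'   `pixels` are linear indices into the image. The label matrix itself is
#'   attached as attribute `"label_image"`. An all-zero image yields an empty
#'   list.
#' @export
read_masks <- function(path) {
  label <- if (is.matrix(path)) path else read_image_tiff(path)
  storage.mode(label) <- "integer"
  labs <- sort(unique(label[label > 0]))
  masks <- lapply(labs, function(l) {
    px <- which(label == l)
    list(cell_id = sprintf("cell%03d", as.integer(l)), label = as.integer(l),
         pixels = px, area_px = length(px))
  })
  names(masks) <- vapply(masks, `[[`, "", "cell_id")
  attr(masks, "label_image") <- label
  masks
}

#' Write a label image as a 16-bit TIFF mask file
#'
#' @param label Integer matrix, 0 = background.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_masks <- function(label, path) {
  write_image_tiff(label, path, float = FALSE)
  invisible(path)
}
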