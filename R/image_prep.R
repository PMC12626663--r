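## Image preparation: despiking, smoothing, and reference-fluid calibration.
## Filters are vectorized pure R: a 3x3 median via a 19-exchange sorting
## network on shifted matrices, and separable Gaussian smoothing by
## shift-and-accumulate on an edge-replicated pad.

pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

#' 3x3 median filter
#'
#' Replaces each pixel by the median of its 3x3 neighbourhood (edges
#' replicated), which restores isolated dead (zero) and saturated (full-well)
#' pixels to their local level. Implemented as a vectorized median-of-9
#' sorting network.
#'
#' @param img 2-D numeric matrix.
#' @return Filtered matrix, same shape.
#' @export
median_filter3 <- function(img) {
  stopifnot(is.matrix(img))
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 2 || nc < 2) return(img)
  P <- pad_replicate(img, 1L)
  sh <- function(dr, dc) P[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  p <- list(sh(0, 0), sh(0, 1), sh(0, 2),
            sh(1, 0), sh(1, 1), sh(1, 2),
            sh(2, 0), sh(2, 1), sh(2, 2))
  s <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  # Paeth's 19-exchange median-of-9 network
  s(2, 3); s(5, 6); s(8, 9); s(1, 2); s(4, 5); s(7, 8)
  s(2, 3); s(5, 6); s(8, 9); s(1, 4); s(6, 9); s(5, 8)
  s(4, 7); s(2, 5); s(3, 6); s(5, 8); s(5, 3); s(7, 5)
  s(5, 3)
  p[[5]]
}

#' Separable Gaussian smoothing
#'
#' @param img 2-D numeric matrix.
#' @param sigma Gaussian SD in pixels; the kernel is truncated at 3 sigma.
#'   `sigma = 0` returns the input unchanged.
#' @return Smoothed matrix, same shape; edges replicated.
#' @export
gaussian_smooth <- function(img, sigma = 1) {
  stopifnot(is.matrix(img), sigma >= 0)
  if (sigma == 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  nr <- nrow(img); nc <- ncol(img)
  P <- pad_replicate(img, r)
  tmp <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(k)) {
    tmp <- tmp + k[i] * P[(i):(i + nr - 1L), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) {
    out <- out + k[j] * tmp[, (j):(j + nc - 1L), drop = FALSE]
  }
  out
}

#' Despike and smooth a channel image
#'
#' The standard pre-processing applied to every raw frame: a 3x3 median filter
#' removes isolated dead/saturated pixels and the worst of the shot noise,
#' then Gaussian smoothing suppresses remaining pixel noise. Shape is
#' preserved and the output is nonnegative for nonnegative input.
#'
#' @param img 2-D nonnegative matrix.
#' @param sigma Gaussian SD in pixels (default 1).
#' @return Filtered image.
#' @export
despike_and_smooth <- function(img, sigma = 1) {
  gaussian_smooth(median_filter3(img), sigma = sigma)
}

#' Fit a per-channel calibration model from reference frames
#'
#' From the water (background) and calibration-fluid frames the model derives,
#' per channel c, after [despike_and_smooth()]:
#' \itemize{
#'   \item `background[[c]]` -- the smoothed water frame (per-pixel, so the
#'     illumination pattern of the background is carried along);
#'   \item `flatfield[[c]]` -- the smoothed excess (calibration - water)
#'     frame divided by its own spatial mean, i.e. a unit-mean image of the
#'     illumination pattern;
#'   \item `scale[[c]]` -- the spectrofluorometer reference value divided by
#'     the spatial mean excess, anchoring corrected intensities to reference
#'     units.
#' }
#'
#' Reference frames estimate fields that are physically smooth (background
#' and illumination vary over tens of pixels, not pixel-to-pixel), so they are
#' smoothed much more strongly (`reference_sigma`, default 8 px) than the cell
#' frames; this suppresses reference shot noise without biasing the per-cell
#' intensities.
#'
#' @param refs A `reference_set` (see [render_reference_set()] /
#'   [read_reference_set()]).
#' @param sigma Smoothing SD applied to cell frames in [calibrate_block()]
#'   (recorded in the model).
#' @param reference_sigma Smoothing SD applied to the reference frames.
#' @param flatfield_floor Lower clamp applied to the unit-mean flat field so
#'   division stays defined in photon-starved corners (default 1e-3).
#' @return Object of class `calibration_model` with elements `background`,
#'   `flatfield`, `scale` (named per channel) and `sigma`.
#' @export
fit_calibration <- function(refs, sigma = 1, reference_sigma = 8,
                            flatfield_floor = 1e-3) {
  ids <- names(refs$background_images)
  stopifnot(identical(ids, names(refs$calibration_images)))
  background <- list(); flatfield <- list(); scale <- numeric(0)
  for (id in ids) {
    b <- despike_and_smooth(refs$background_images[[id]] - refs$dark_offset,
                            sigma = reference_sigma)
    cal <- despike_and_smooth(refs$calibration_images[[id]] - refs$dark_offset,
                              sigma = reference_sigma)
    excess <- cal - b
    m <- mean(excess)
    if (!is.finite(m) || m <= 0) {
      stop("uncalibratable channel ", id,
           ": calibration frame does not exceed background")
    }
    rv <- refs$reference_values[[id]]
    if (is.null(rv) || !is.finite(rv) || rv <= 0) {
      stop("uncalibratable channel ", id, ": nonpositive reference value")
    }
    background[[id]] <- b
    flatfield[[id]] <- pmax(excess / m, flatfield_floor)
    scale[[id]] <- rv / m
  }
  structure(list(background = background, flatfield = flatfield,
                 scale = scale, sigma = sigma),
            class = "calibration_model")
}

#' Calibrate a raw data block
#'
#' Per channel, each raw frame is despiked and smoothed, the per-pixel
#' background estimate is subtracted (negatives clamped to zero -- intensities
#' are physical nonnegatives; the clamp only bites at the noise floor), the
#' result is divided by the unit-mean flat field to undo uneven illumination,
#' and finally scaled so that intensities are expressed in spectrofluorometer
#' reference units. Calibrating an already calibrated block is an error, not a
#' no-op: the transform is not idempotent.
#'
#' @param block A raw `data_block`.
#' @param model A `calibration_model` covering all of the block's channels.
#' @return A calibrated `data_block` (float intensities, `calibrated = TRUE`).
#' @export
calibrate_block <- function(block, model) {
  validate_data_block(block)
  if (block$calibrated) stop("block is already calibrated")
  missing <- setdiff(names(block$images), names(model$flatfield))
  if (length(missing)) {
    stop("calibration model lacks channel(s): ", paste(missing, collapse = ", "))
  }
  images <- block$images
  for (id in names(images)) {
    s <- despike_and_smooth(images[[id]], sigma = model$sigma)
    images[[id]] <- pmax(0, s - model$background[[id]]) /
      model$flatfield[[id]] * model$scale[[id]]
  }
  data_block(block$sample_id, block$patient_id, block$group_label,
             block$channels, images, block$brightfield, calibrated = TRUE)
}

#' Serialize a calibration model to a directory (JSON + TIFF bundle)
#'
#' @param model A `calibration_model`.
#' @param directory Output directory.
#' @return The directory, invisibly.
#' @export
write_calibration_model <- function(model, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  scales_b <- numeric(0); scales_f <- numeric(0)
  for (id in names(model$flatfield)) {
    scales_b[[id]] <- write_image_tiff(model$background[[id]],
                                       file.path(directory, paste0(id, "_background.tif")),
                                       float = TRUE)
    scales_f[[id]] <- write_image_tiff(model$flatfield[[id]],
                                       file.path(directory, paste0(id, "_flatfield.tif")),
                                       float = TRUE)
  }
  meta <- list(channel_ids = names(model$flatfield), scale = as.list(model$scale),
               sigma = model$sigma, background_tiff_scale = as.list(scales_b),
               flatfield_tiff_scale = as.list(scales_f))
  jsonlite::write_json(meta, file.path(directory, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' Read a calibration model written by [write_calibration_model()]
#'
#' @param directory Bundle directory.
#' @return A `calibration_model`.
#' @export
read_calibration_model <- function(directory) {
  meta <- jsonlite::fromJSON(file.path(directory, "calibration.json"))
  background <- list(); flatfield <- list()
  for (id in meta$channel_ids) {
    background[[id]] <- read_image_tiff(
      file.path(directory, paste0(id, "_background.tif")),
      scale = meta$background_tiff_scale[[id]], float = TRUE)
    flatfield[[id]] <- read_image_tiff(
      file.path(directory, paste0(id, "_flatfield.tif")),
      scale = meta$flatfield_tiff_scale[[id]], float = TRUE)
  }
  structure(list(background = background, flatfield = flatfield,
                 scale = unlist(meta$scale), sigma = meta$sigma),
            class = "calibration_model")
}
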