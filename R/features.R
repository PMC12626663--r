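## Per-cell spectral features: channel means, population SDs, skewness, and
## ordered channel-mean intensity ratios.

#' Build a feature catalog
#'
#' The catalog enumerates the per-cell features derived from a channel table:
#' one MEAN, SD and SKEW per channel, plus one RATIO per ordered channel pair
#' (both orientations, since selection may prefer either). For C channels with
#' all families enabled the total is `3C + C(C-1)` (1224 for the default
#' 34-channel table).
#'
#' @param channel_ids Character vector of channel ids.
#' @param families Subset of `c("MEAN", "SD", "SKEW", "RATIO")`.
#' @return A `feature_catalog` data.frame with columns `name`, `family`,
#'   `channel_i`, `channel_j` (`channel_j` is `NA` except for RATIO) and
#'   attribute `total_count`.
#' @export
feature_catalog <- function(channel_ids,
                            families = c("MEAN", "SD", "SKEW", "RATIO")) {
  families <- match.arg(families, several.ok = TRUE)
  rows <- list()
  for (fam in intersect(c("MEAN", "SD", "SKEW"), families)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(fam, "_", channel_ids), family = fam,
      channel_i = channel_ids, channel_j = NA_character_)
  }
  if ("RATIO" %in% families && length(channel_ids) > 1) {
    pairs <- expand.grid(channel_j = channel_ids, channel_i = channel_ids,
                         stringsAsFactors = FALSE)[, c("channel_i", "channel_j")]
    pairs <- pairs[pairs$channel_i != pairs$channel_j, ]
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("RATIO_", pairs$channel_i, "_over_", pairs$channel_j),
      family = "RATIO", channel_i = pairs$channel_i,
      channel_j = pairs$channel_j)
  }
  cat_df <- do.call(rbind, rows)
  rownames(cat_df) <- NULL
  if (anyDuplicated(cat_df$name)) stop("duplicate feature names in catalog")
  attr(cat_df, "total_count") <- nrow(cat_df)
  class(cat_df) <- c("feature_catalog", "data.frame")
  cat_df
}

#' Serialize / read a feature catalog as JSON
#' @param catalog A `feature_catalog`.
#' @param path JSON path.
#' @return `path` (write) or the catalog (read).
#' @export
write_feature_catalog <- function(catalog, path) {
  jsonlite::write_json(unclass(catalog), path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_feature_catalog
#' @export
read_feature_catalog <- function(path) {
  df <- as.data.frame(jsonlite::fromJSON(path))
  if (!"channel_j" %in% names(df)) df$channel_j <- NA_character_
  attr(df, "total_count") <- nrow(df)
  class(df) <- c("feature_catalog", "data.frame")
  df
}

#' Mean, SD and skewness of the pixels of one cell in one channel
#'
#' Population (divisor-n) moments: `sd = sqrt(m2)` and Fisher-Pearson
#' skewness `g1 = m3 / m2^(3/2)` with `m_k` the k-th central moment. A
#' zero-variance cell has skewness 0 by convention.
#'
#' @param image 2-D intensity matrix.
#' @param pixels Linear pixel indices of the cell (nonempty, in bounds).
#' @return Numeric vector `c(mean, sd, skewness)`.
#' @export
cell_channel_stats <- function(image, pixels) {
  if (length(pixels) == 0) stop("empty mask")
  if (any(pixels < 1 | pixels > length(image))) stop("mask outside image bounds")
  v <- image[pixels]
  m <- mean(v)
  d <- v - m
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  c(mean = m, sd = sqrt(m2), skewness = skew)
}

#' Regularized intensity ratio between two channel means
#'
#' @param mean_i,mean_j Calibrated cell means.
#' @param eps Positive regularizer guarding near-zero denominators.
#' @return `(mean_i + eps) / (mean_j + eps)`.
#' @export
channel_ratio <- function(mean_i, mean_j, eps) {
  (mean_i + eps) / (mean_j + eps)
}

#' Extract the per-cell feature table from a calibrated block
#'
#' One row per cell in the label image; columns follow the catalog order. The
#' ratio regularizer defaults to `1e-6` times the global mean intensity of the
#' block's channel images (recorded in the result's `eps` attribute). Cells
#' whose pixels fall outside the image are skipped with a warning and listed
#' in the `rejects` attribute.
#'
#' @param block A calibrated `data_block`.
#' @param masks A label image matrix, a mask list from [read_masks()], or a
#'   path to a label TIFF.
#' @param catalog A [feature_catalog()] consistent with the block's channels.
#' @param eps Ratio regularizer; `NULL` for the default.
#' @return A `feature_table` with one row per extracted cell.
#' @export
extract_features <- function(block, masks, catalog = NULL, eps = NULL) {
  validate_data_block(block)
  if (!block$calibrated) {
    stop("features are defined on calibrated blocks; run calibrate_block() first")
  }
  if (is.null(catalog)) catalog <- feature_catalog(block$channels$channel_id)
  unknown <- setdiff(unique(stats::na.omit(c(catalog$channel_i, catalog$channel_j))),
                     block$channels$channel_id)
  if (length(unknown)) {
    stop("catalog references channel(s) absent from block: ",
         paste(unknown, collapse = ", "))
  }
  if (!is.list(masks)) masks <- read_masks(masks)
  if (is.null(eps)) {
    eps <- 1e-6 * mean(vapply(block$images, mean, numeric(1)))
  }
  npix <- length(block$brightfield)
  ids <- block$channels$channel_id
  rows <- list(); rejects <- character(0)
  for (m in masks) {
    if (any(m$pixels < 1 | m$pixels > npix)) {
      warning("mask ", m$cell_id, " outside image bounds; cell skipped")
      rejects <- c(rejects, m$cell_id)
      next
    }
    stats3 <- vapply(ids, function(id) cell_channel_stats(block$images[[id]], m$pixels),
                     numeric(3))  # 3 x C
    means <- stats3[1, ]
    vals <- numeric(nrow(catalog))
    for (i in seq_len(nrow(catalog))) {
      fam <- catalog$family[i]
      vals[i] <- switch(fam,
        MEAN = means[[catalog$channel_i[i]]],
        SD = stats3[2, catalog$channel_i[i]],
        SKEW = stats3[3, catalog$channel_i[i]],
        RATIO = channel_ratio(means[[catalog$channel_i[i]]],
                              means[[catalog$channel_j[i]]], eps),
        stop("unknown feature family ", fam))
    }
    row <- as.data.frame(as.list(stats::setNames(vals, catalog$name)),
                         check.names = FALSE)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(cell_id = paste0(block$sample_id, "_", m$cell_id),
                 patient_id = block$patient_id,
                 group_label = block$group_label),
      row)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    empty <- as.data.frame(matrix(numeric(0), 0, nrow(catalog),
                                  dimnames = list(NULL, catalog$name)),
                           check.names = FALSE)
    cbind(data.frame(cell_id = character(0), patient_id = character(0),
                     group_label = character(0)), empty)
  }
  out <- feature_table(out)
  attr(out, "eps") <- eps
  attr(out, "rejects") <- rejects
  out
}

#' Extract and pool features across a cohort of calibrated blocks
#'
#' @param blocks Named list of calibrated `data_block`s.
#' @param labels Named list of label images, parallel to `blocks`.
#' @param catalog Optional [feature_catalog()].
#' @return Pooled `feature_table`.
#' @export
extract_cohort_features <- function(blocks, labels, catalog = NULL) {
  stopifnot(identical(names(blocks), names(labels)))
  tabs <- lapply(names(blocks), function(sid) {
    as.data.frame(extract_features(blocks[[sid]], labels[[sid]], catalog))
  })
  feature_table(do.call(rbind, tabs))
}
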