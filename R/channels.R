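#' Construct a single spectral channel specification
#'
#' A channel is one excitation-band / emission-band combination of a
#' multispectral filter-cube acquisition. Channel ids are self-describing:
#' `Ex{excitation_center}Em{emission_midpoint}` in integer nanometres.
#'
#' @param excitation_center_nm Excitation band center (nm).
#' @param emission_low_nm,emission_high_nm Emission window bounds (nm),
#'   `emission_low_nm < emission_high_nm`.
#' @param excitation_halfwidth_nm Excitation half-width (nm); narrowband LED
#'   sources are typically +/- 5 nm.
#' @param index Zero-based position in the acquisition order.
#' @return A one-row `data.frame` with the channel fields.
#' @export
channel_spec <- function(excitation_center_nm, emission_low_nm,
                         emission_high_nm, excitation_halfwidth_nm = 5,
                         index = 0L) {
  stopifnot(emission_low_nm < emission_high_nm,
            excitation_halfwidth_nm > 0)
  data.frame(
    channel_id = sprintf("Ex%dEm%d", as.integer(round(excitation_center_nm)),
                         as.integer(round((emission_low_nm + emission_high_nm) / 2))),
    excitation_center_nm = excitation_center_nm,
    excitation_halfwidth_nm = excitation_halfwidth_nm,
    emission_low_nm = emission_low_nm,
    emission_high_nm = emission_high_nm,
    index = as.integer(index),
    stringsAsFactors = FALSE
  )
}

#' Default 34-channel acquisition table
#'
#' The acquisition system provides 34 spectral channels spanning excitation
#' 340--510 nm and emission 420--650 nm. The exact band list of the instrument
#' is not published, so the default table is a documented stand-in: a grid of
#' eight narrowband excitation centers by five contiguous emission windows,
#' keeping only physically valid pairs (emission window strictly above the
#' excitation center). That grid yields exactly 34 channels within the printed
#' ranges. Users with a real band list can load it with
#' [read_channel_table()] instead.
#'
#' @return A `channel_table` data.frame with 34 rows, columns `channel_id`,
#'   `excitation_center_nm`, `excitation_halfwidth_nm`, `emission_low_nm`,
#'   `emission_high_nm`, `index`.
#' @export
default_channel_table <- function() {
  exc <- c(340, 365, 390, 415, 440, 465, 490, 510)
  em_low <- c(420, 466, 512, 558, 604)
  em_high <- c(465, 511, 557, 603, 650)
  rows <- list()
  for (e in exc) {
    for (b in seq_along(em_low)) {
      if (em_low[b] > e) {
        rows[[length(rows) + 1L]] <-
          channel_spec(e, em_low[b], em_high[b], index = length(rows))
      }
    }
  }
  tab <- do.call(rbind, rows)
  validate_channel_table(tab)
}

#' Validate a channel table
#'
#' Checks uniqueness of channel ids, ordering of emission bounds, and
#' contiguity of the zero-based acquisition index.
#'
#' @param tab A data.frame of channel specifications.
#' @return The table, invisibly classed as `channel_table`.
#' @export
validate_channel_table <- function(tab) {
  required <- c("channel_id", "excitation_center_nm", "excitation_halfwidth_nm",
                "emission_low_nm", "emission_high_nm", "index")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("channel table missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$channel_id)) {
    stop("duplicate channel_id in channel table: ",
         paste(unique(tab$channel_id[duplicated(tab$channel_id)]), collapse = ", "))
  }
  if (any(tab$emission_low_nm >= tab$emission_high_nm)) {
    stop("emission_low_nm must be < emission_high_nm for every channel")
  }
  if (!identical(as.integer(tab$index), seq_len(nrow(tab)) - 1L)) {
    stop("channel indices must be contiguous 0..n-1 in row order")
  }
  class(tab) <- c("channel_table", "data.frame")
  tab
}

#' Read a channel table from a CSV or JSON sidecar
#'
#' @param path CSV file with the channel columns, or a JSON array of objects.
#' @return A validated `channel_table`.
#' @export
read_channel_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_channel_table(tab)
}

#' Write a channel table sidecar
#'
#' @param tab A `channel_table`.
#' @param path Output path (`.csv` or `.json` by extension).
#' @return `path`, invisibly.
#' @export
write_channel_table <- function(tab, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(tab), path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
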