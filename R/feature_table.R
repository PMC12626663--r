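#' Construct a per-cell feature table
#'
#' Rows are cells, identified by `cell_id` / `patient_id` / `group_label`;
#' remaining columns are named real-valued spectral features.
#'
#' @param df data.frame with the three metadata columns followed by numeric
#'   feature columns.
#' @return A `feature_table` (data.frame subclass) with attribute
#'   `feature_names`.
#' @export
feature_table <- function(df) {
  meta <- c("cell_id", "patient_id", "group_label")
  missing <- setdiff(meta, names(df))
  if (length(missing)) {
    stop("feature table missing column(s): ", paste(missing, collapse = ", "))
  }
  feats <- setdiff(names(df), meta)
  if (anyDuplicated(feats)) stop("duplicate feature names")
  for (f in feats) {
    if (!is.numeric(df[[f]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[f]]))))[1]
      stop("non-numeric feature value in column '", f, "', row ",
           if (is.na(bad)) "?" else bad)
    }
    if (anyNA(df[[f]])) {
      stop("missing value in feature column '", f, "', row ",
           which(is.na(df[[f]]))[1])
    }
  }
  df <- df[, c(meta, feats), drop = FALSE]
  attr(df, "feature_names") <- feats
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Names of the feature columns
#' @param table A `feature_table`.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table) {
  fn <- attr(table, "feature_names")
  if (is.null(fn)) setdiff(names(table), c("cell_id", "patient_id", "group_label")) else fn
}

#' Write a feature table as CSV
#'
#' Header is `cell_id,patient_id,group_label,<features...>`; floats are
#' written with 12 significant digits so that read-after-write agrees within
#' 1e-9 relative.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  out <- as.data.frame(table)
  for (f in feature_names(table)) {
    out[[f]] <- formatC(out[[f]], digits = 12, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV or a spreadsheet
#'
#' CSV is the native format. Spreadsheet files (`.xlsx`) with the same column
#' contract are imported through the readxl package when available, matching
#' the layout of deposited per-cell feature workbooks.
#'
#' @param path Path to a `.csv` or `.xlsx` file.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("spreadsheet import requires the 'readxl' package")
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  meta <- c("cell_id", "patient_id", "group_label")
  feats <- setdiff(names(df), meta)
  for (f in feats) {
    v <- df[[f]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (anyNA(conv) && !anyNA(v)) {
        stop("non-numeric feature value in column '", f, "', row ",
             which(is.na(conv))[1])
      }
      df[[f]] <- conv
    }
  }
  feature_table(df)
}

#' Restrict a feature table to two classes for binary comparison
#'
#' @param table A `feature_table`.
#' @param class_a,class_b Group labels.
#' @return A `feature_table` with rows of the two classes only.
#' @export
restrict_classes <- function(table, class_a, class_b) {
  keep <- table$group_label %in% c(class_a, class_b)
  if (!any(table$group_label == class_a) || !any(table$group_label == class_b)) {
    stop("both classes must be present: ", class_a, ", ", class_b)
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  feature_table(as.data.frame(out))
}
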