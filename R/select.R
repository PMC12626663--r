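## Entropy-based feature selection: threshold information gain with greedy
## redundancy filtering.

#' Shannon entropy of a class-label vector, in bits
#'
#' `H = -sum_y p_y log2 p_y` with the `0 log 0 = 0` convention.
#'
#' @param labels Vector of class labels (any type; at least one).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(labels) {
  stopifnot(length(labels) >= 1)
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

entropy_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Information gain of a continuous feature about binary class labels
#'
#' Default discretization is the exhaustive binary threshold: every midpoint
#' between consecutive distinct sorted values is tried, and the gain is the
#' maximum over thresholds of `H(Y) - sum_side (n_side / n) H(Y | side)`. A
#' constant feature has zero gain. The threshold criterion is invariant to any
#' strictly increasing transform of the feature. An equal-frequency multi-bin
#' discretization is available as an alternative.
#'
#' @param values Finite numeric feature values.
#' @param labels Class labels, exactly two classes present.
#' @param discretization `"threshold"` (default) or `"equalfreq"`.
#' @param bins Number of bins for `"equalfreq"`.
#' @return Information gain in bits (in `[0, H(Y)]`).
#' @export
information_gain <- function(values, labels,
                             discretization = c("threshold", "equalfreq"),
                             bins = 4) {
  discretization <- match.arg(discretization)
  stopifnot(length(values) == length(labels), all(is.finite(values)))
  y <- as.integer(factor(labels))
  if (length(unique(y)) != 2) stop("exactly two classes required")
  n <- length(y)
  h0 <- shannon_entropy(y)

  if (discretization == "equalfreq") {
    qs <- unique(stats::quantile(values, probs = seq(0, 1, length.out = bins + 1)))
    cut_v <- cut(values, breaks = qs, include.lowest = TRUE)
    cond <- 0
    for (lev in levels(cut_v)) {
      idx <- cut_v == lev
      if (any(idx)) {
        cond <- cond + sum(idx) / n * shannon_entropy(y[idx])
      }
    }
    return(max(0, h0 - cond))
  }

  ord <- order(values)
  v <- values[ord]; yy <- y[ord]
  # cumulative class-1 and class-2 counts after each sorted sample
  c1 <- cumsum(yy == 1L); c2 <- cumsum(yy == 2L)
  # candidate splits: between consecutive distinct values
  splits <- which(diff(v) > 0)
  if (length(splits) == 0) return(0)
  n1 <- c1[n]; n2 <- c2[n]
  best <- 0
  left1 <- c1[splits]; left2 <- c2[splits]
  nl <- splits; nr <- n - nl
  hl <- vapply(seq_along(splits), function(i)
    entropy_from_counts(c(left1[i], left2[i])), numeric(1))
  hr <- vapply(seq_along(splits), function(i)
    entropy_from_counts(c(n1 - left1[i], n2 - left2[i])), numeric(1))
  gains <- h0 - (nl / n) * hl - (nr / n) * hr
  max(0, max(gains))
}

#' Rank features by information gain and select a compact non-redundant set
#'
#' Features are ranked by information gain for the binary comparison (ties
#' broken lexicographically by feature name so runs are reproducible); a
#' greedy pass then admits a feature only if its absolute Spearman correlation
#' with every already-admitted feature is at most `redundancy_rho`, stopping
#' at `k`. Selecting on all cells before cross-validation leaks information;
#' see `selection_mode` in [run_comparison()].
#'
#' @param table A `feature_table` restricted to exactly two classes (see
#'   [restrict_classes()]).
#' @param k Number of features to select (default 8, a compact set guarding
#'   against overfitting).
#' @param redundancy_rho Absolute Spearman correlation above which a candidate
#'   is considered redundant (default 0.95).
#' @param discretization Passed to [information_gain()].
#' @return Object of class `selection_result`: `comparison`, `ranking`
#'   (data.frame of name + information_gain_bits, nonincreasing), `selected`,
#'   `k`, `discretization`, and `short` flag when fewer than `k` admissible
#'   features exist.
#' @export
rank_and_select <- function(table, k = 8, redundancy_rho = 0.95,
                            discretization = "threshold") {
  classes <- sort(unique(table$group_label))
  if (length(classes) != 2) {
    stop("selection requires a two-class table; got ",
         paste(classes, collapse = ", "))
  }
  feats <- feature_names(table)
  y <- table$group_label
  ig <- vapply(feats, function(f)
    information_gain(table[[f]], y, discretization = discretization),
    numeric(1))
  ord <- order(-ig, feats)
  ranking <- data.frame(name = feats[ord],
                        information_gain_bits = unname(ig[ord]),
                        stringsAsFactors = FALSE)
  selected <- character(0)
  for (f in ranking$name) {
    if (length(selected) >= k) break
    if (length(selected) > 0) {
      rho <- vapply(selected, function(s)
        abs(stats::cor(table[[f]], table[[s]], method = "spearman")),
        numeric(1))
      rho[is.na(rho)] <- 0  # constant columns carry no redundancy signal
      if (any(rho > redundancy_rho)) next
    }
    selected <- c(selected, f)
  }
  short <- length(selected) < k
  if (short) {
    warning("only ", length(selected), " admissible feature(s) for k = ", k)
  }
  structure(list(comparison = classes, ranking = ranking, selected = selected,
                 k = k, redundancy_rho = redundancy_rho,
                 discretization = discretization, short = short),
            class = "selection_result")
}

#' Serialize a selection result to JSON
#' @param sel A `selection_result`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(unclass(sel), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
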