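# Median binarization of the selected features.

#' Median binarization thresholds
#'
#' Computes, per selected feature, the sample median over all pooled
#' records of the analysis subset. At binarization a value less than or
#' equal to its threshold becomes 0 (good health) and anything above
#' becomes 1 (bad health) — except HDL-C, where higher is healthier, so
#' the assignment is reversed. Thresholds are recomputed for every
#' analysis subset: a sub-cohort has its own medians.
#'
#' @param records Data frame with the selected feature columns, all
#'   non-missing.
#' @param feature_order The 6 features, most significant bit first.
#' @param reversed Features whose direction is flipped (default `"HDL_C"`).
#' @return Object of class `ela_thresholds`: named `threshold` vector and
#'   logical `reversed` vector in feature order.
#' @export
compute_thresholds <- function(records, feature_order = ela_features(),
                               reversed = "HDL_C") {
  if (nrow(records) == 0L) stop("cannot compute thresholds on empty input")
  missing_cols <- setdiff(feature_order, names(records))
  if (length(missing_cols) > 0L)
    stop("records lack feature column(s): ",
         paste(missing_cols, collapse = ", "))
  vals <- as.matrix(records[, feature_order, drop = FALSE])
  if (anyNA(vals))
    stop("thresholds require all selected features non-missing")
  thr <- apply(vals, 2, stats::median)
  structure(
    list(threshold = thr,
         reversed = stats::setNames(feature_order %in% reversed,
                                    feature_order),
         feature_order = feature_order),
    class = "ela_thresholds"
  )
}

#' @export
print.ela_thresholds <- function(x, ...) {
  cat("Binarization thresholds (<= threshold -> 0",
      if (any(x$reversed)) paste0("; reversed: ",
        paste(x$feature_order[x$reversed], collapse = ", ")), ")\n", sep = "")
  print(round(x$threshold, 3))
  invisible(x)
}

#' Binarize records against thresholds
#'
#' Standard features: value <= threshold maps to 0, above to 1. Reversed
#' features (HDL-C): value <= threshold maps to 1, above to 0. A value
#' exactly at the threshold therefore binarizes to the "good" side for
#' standard features and the "bad" side for reversed ones.
#'
#' @param records Data frame (or single-row list) with the feature columns.
#' @param thresholds An [compute_thresholds()] result.
#' @return n x 6 integer 0/1 matrix, columns in feature order.
#' @export
binarize <- function(records, thresholds) {
  if (!inherits(thresholds, "ela_thresholds"))
    stop("thresholds must come from compute_thresholds()")
  records <- as.data.frame(records)
  fo <- thresholds$feature_order
  vals <- as.matrix(records[, fo, drop = FALSE])
  if (anyNA(vals)) stop("cannot binarize records with missing feature values")
  low <- sweep(vals, 2, thresholds$threshold, `<=`)
  bits <- ifelse(sweep(low, 2, thresholds$reversed, `==`), 1L, 0L)
  # low == reversed: (low & reversed) -> 1, (high & standard) -> 1
  dimnames(bits) <- list(NULL, fo)
  storage.mode(bits) <- "integer"
  bits
}
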