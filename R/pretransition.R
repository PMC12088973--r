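# Feature comparisons in the year before a state transition.

#' Collect feature values from the year before a given transition
#'
#' For every counted transition of the requested type (from-state ->
#' to-state, consecutive years), takes the from-year record's value of
#' the feature, dropping missing values. An individual with several
#' qualifying transitions contributes one value per transition.
#'
#' @param records Records carrying the feature column.
#' @param states From [assign_states()].
#' @param from,to State labels defining the transition type.
#' @param feature Feature column name.
#' @return Numeric vector (possibly empty).
#' @export
collect_pretransition_values <- function(records, states, from, to, feature) {
  records <- as.data.frame(records)
  if (!feature %in% names(records)) stop("unknown feature: ", feature)
  tp <- transition_pairs(states)
  tp <- tp[tp$from == from & tp$to == to, , drop = FALSE]
  if (nrow(tp) == 0L) return(numeric(0))
  key_r <- paste(records$individual_id, records$year)
  key_t <- paste(tp$individual_id, tp$from_year)
  v <- records[[feature]][match(key_t, key_r)]
  v[!is.na(v)]
}

#' Compare a feature between two transition groups (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with tie handling:
#' exact enumeration for small untied samples, normal approximation with
#' continuity correction otherwise. Reported alongside mean +/- sample SD
#' (n - 1 denominator) per group. p < 0.05 is the conventional
#' significance threshold.
#'
#' @param values_a,values_b Numeric value vectors for the two groups.
#' @return Object of class `feature_comparison`: per-group n, mean, sd,
#'   the U statistic (for group a) and the two-sided `p.value`. If either
#'   group is empty the comparison is skipped with a warning and the
#'   statistic fields are NA.
#' @export
compare_feature <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  out <- list(n_a = length(values_a), mean_a = mean(values_a),
              sd_a = stats::sd(values_a),
              n_b = length(values_b), mean_b = mean(values_b),
              sd_b = stats::sd(values_b),
              statistic = NA_real_, p.value = NA_real_)
  if (length(values_a) == 0L || length(values_b) == 0L) {
    warning("empty group; comparison skipped")
    return(structure(out, class = "feature_comparison"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       correct = TRUE)
  )
  out$statistic <- unname(wt$statistic)  # U for group a
  out$p.value <- wt$p.value
  structure(out, class = "feature_comparison")
}

#' @export
print.feature_comparison <- function(x, ...) {
  cat(sprintf("group a: %.3g +/- %.3g (n=%d) vs group b: %.3g +/- %.3g (n=%d)\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  if (!is.na(x$p.value))
    cat(sprintf("  Mann-Whitney U = %.1f, two-sided p = %.4g\n",
                x$statistic, x$p.value))
  invisible(x)
}

#' Pre-transition feature table
#'
#' For each transition type, n / mean / SD of every feature in the year
#' before the transition; for each requested comparison pair, the
#' two-sided Mann-Whitney p-value. P-values are reported per feature
#' without multiple-testing adjustment (a deliberate caveat: rows are
#' descriptive, not simultaneous inference).
#'
#' @param records Records carrying the feature columns.
#' @param states From [assign_states()].
#' @param features Feature columns to tabulate (default: all biomarkers
#'   present).
#' @param transitions List of `c(from, to)` transition types.
#' @param comparisons List of pairs of transition types to compare, each
#'   `list(c(from, to), c(from, to))`.
#' @return Data frame, one row per feature, with `n_<f>_<t>`,
#'   `mean_<f>_<t>`, `sd_<f>_<t>` columns per transition type and one
#'   `p_<..>` column per comparison.
#' @export
pretransition_table <- function(records, states,
                                features = intersect(checkup_features(),
                                                     names(records)),
                                transitions = list(c(1, 2), c(1, 3),
                                                   c(2, 1), c(2, 3)),
                                comparisons = list(
                                  list(c(1, 2), c(1, 3)),
                                  list(c(1, 3), c(2, 3)),
                                  list(c(2, 1), c(2, 3)))) {
  tname <- function(t) paste0(t[1], "to", t[2])
  out <- data.frame(feature = features)
  vals <- list()
  for (t in transitions) {
    for (f in features)
      vals[[paste(tname(t), f)]] <-
        collect_pretransition_values(records, states, t[1], t[2], f)
    v <- vals[paste(tname(t), features)]
    out[[paste0("n_", tname(t))]] <- vapply(v, length, 1L)
    out[[paste0("mean_", tname(t))]] <-
      vapply(v, function(x) if (length(x)) mean(x) else NA_real_, 1)
    out[[paste0("sd_", tname(t))]] <-
      vapply(v, function(x) if (length(x) > 1) stats::sd(x) else NA_real_, 1)
  }
  for (cmp in comparisons) {
    pa <- tname(cmp[[1]]); pb <- tname(cmp[[2]])
    p <- vapply(features, function(f) {
      a <- vals[[paste(pa, f)]]; b <- vals[[paste(pb, f)]]
      if (is.null(a)) a <- collect_pretransition_values(records, states,
                                cmp[[1]][1], cmp[[1]][2], f)
      if (is.null(b)) b <- collect_pretransition_values(records, states,
                                cmp[[2]][1], cmp[[2]][2], f)
      if (length(a) == 0L || length(b) == 0L) return(NA_real_)
      compare_feature(a, b)$p.value
    }, 1)
    out[[paste0("p_", pa, "_vs_", pb)]] <- p
  }
  out
}
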