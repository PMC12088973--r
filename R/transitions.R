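# Year-to-year state transitions and pathway-preference tests.

#' Assign each record to a landscape state
#'
#' Binarizes each record, encodes its 6-bit pattern, and labels it with
#' the basin state containing that pattern.
#'
#' @param records Records with the 6 selected features non-missing.
#' @param thresholds From [compute_thresholds()].
#' @param basins From [basin_graph()].
#' @return Data frame `individual_id, year, pattern, state`, ordered by
#'   individual then year.
#' @export
assign_states <- function(records, thresholds, basins) {
  records <- as.data.frame(records)
  idx <- pattern_index(binarize(records, thresholds))
  out <- data.frame(individual_id = records$individual_id,
                    year = records$year,
                    pattern = idx,
                    state = basins$state_of[idx + 1L])
  out <- out[order(out$individual_id, out$year), ]
  rownames(out) <- NULL
  out
}

# Consecutive-year (gap exactly 1) transition pairs across individuals.
transition_pairs <- function(states) {
  states <- states[order(states$individual_id, states$year), ]
  n <- nrow(states)
  if (n < 2L)
    return(data.frame(individual_id = character(0), from_year = integer(0),
                      from = integer(0), to = integer(0)))
  same <- states$individual_id[-n] == states$individual_id[-1]
  gap1 <- diff(states$year) == 1
  keep <- same & gap1
  data.frame(individual_id = states$individual_id[-n][keep],
             from_year = states$year[-n][keep],
             from = states$state[-n][keep],
             to = states$state[-1][keep])
}

#' Count year-to-year state transitions
#'
#' Counts a transition for every pair of visits of the same individual in
#' consecutive calendar years (gap exactly 1). Staying in the same state
#' counts as a self-transition; visits separated by two or more years
#' (missed checkups) contribute nothing.
#'
#' @param states Data frame from [assign_states()] (one row per
#'   individual-year).
#' @param n_states Number of states K (default: the largest label seen).
#' @return K x K integer matrix of class `transition_counts`
#'   (rows = from-state, columns = to-state).
#' @export
count_transitions <- function(states, n_states = NULL) {
  if (is.null(n_states)) n_states <- max(states$state, 1L)
  tp <- transition_pairs(states)
  m <- matrix(0L, n_states, n_states,
              dimnames = list(from = paste0("state", seq_len(n_states)),
                              to = paste0("state", seq_len(n_states))))
  if (nrow(tp) > 0L)
    for (r in seq_len(nrow(tp))) m[tp$from[r], tp$to[r]] <- m[tp$from[r], tp$to[r]] + 1L
  class(m) <- c("transition_counts", class(m))
  m
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("State transition counts (", sum(x), " consecutive-year pairs)\n",
      sep = "")
  print(unclass(x))
  invisible(x)
}

#' Chi-squared test of pathway preference between two groups
#'
#' Tests whether two groups (e.g. obese vs non-obese) distribute their
#' transitions differently over two competing pathways, via Pearson's
#' chi-squared test with Yates continuity correction on the 2 x 2 table
#' of transition counts (df = 1).
#'
#' @param table 2 x 2 matrix: rows = groups, columns = pathways.
#' @param correct Apply the continuity correction (default TRUE).
#' @return Object of class `preference_test`: the table, statistic,
#'   `df = 1` and `p.value`.
#' @examples
#' preference_test(matrix(c(78, 210, 191, 782), 2))
#' @export
preference_test <- function(table, correct = TRUE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2 x 2")
  if (anyNA(tab) || any(tab < 0)) stop("table entries must be nonnegative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the 2 x 2 table; use an exact test instead")
  ct <- stats::chisq.test(tab, correct = correct)
  structure(
    list(table = tab, statistic = unname(ct$statistic),
         df = 1L, p.value = ct$p.value, correct = correct),
    class = "preference_test"
  )
}

#' @export
print.preference_test <- function(x, ...) {
  cat("Pathway-preference chi-squared test",
      if (x$correct) "(continuity-corrected)", "\n")
  print(x$table)
  cat(sprintf("  X-squared = %.4f, df = 1, p = %.4g\n",
              x$statistic, x$p.value))
  invisible(x)
}
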