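# Pairwise maximum-entropy (Ising) model over 6 binary features.
#
# E(sigma) = -sum_i h_i s_i - sum_{i<j} J_ij s_i s_j, with s either the raw
# bits (coding "01") or spins 2*bit - 1 (coding "pm1"); P(sigma) =
# exp(-E)/Z. The two codings parameterize the same 64-pattern family, so
# probabilities (not h, J) are the exchangeable quantity.

PAIR_IDX <- t(utils::combn(6L, 2L))  # 15 unordered feature pairs, i < j

# Map bits to the model's state coding.
coded_states <- function(bits, coding) {
  if (coding == "pm1") 2 * bits - 1 else bits
}

# 64 x 21 (or n x 21) sufficient-statistics matrix: the 6 coded states
# followed by the 15 pairwise products.
suff_stats <- function(bits, coding) {
  s <- coded_states(bits, coding)
  cbind(s, s[, PAIR_IDX[, 1], drop = FALSE] * s[, PAIR_IDX[, 2], drop = FALSE])
}

#' Construct a pairwise maximum-entropy (Ising) model
#'
#' @param h Numeric vector of 6 biases (dimensionless).
#' @param J Symmetric 6 x 6 coupling matrix with zero diagonal.
#' @param feature_order Character vector of the 6 feature names, most
#'   significant bit first.
#' @param coding State coding: `"01"` (bits enter the energy as 0/1, the
#'   default) or `"pm1"` (as -1/+1 spins).
#' @return An object of class `ising_model`.
#' @export
ising_model <- function(h, J, feature_order = ela_features(),
                        coding = c("01", "pm1")) {
  coding <- match.arg(coding)
  h <- as.numeric(h)
  J <- as.matrix(J)
  if (length(h) != 6L) stop("h must have length 6")
  if (!all(dim(J) == c(6L, 6L))) stop("J must be 6 x 6")
  if (max(abs(J - t(J))) > 1e-10) stop("J must be symmetric")
  if (max(abs(diag(J))) > 1e-10) stop("J must have zero diagonal")
  if (length(feature_order) != 6L) stop("feature_order must name 6 features")
  structure(
    list(h = stats::setNames(h, feature_order), J = J,
         feature_order = feature_order, coding = coding),
    class = "ising_model"
  )
}

#' @export
print.ising_model <- function(x, ...) {
  cat("Pairwise maximum-entropy model (coding ", x$coding, ") over: ",
      paste(x$feature_order, collapse = ", "), "\n", sep = "")
  cat("h:", format(round(unname(x$h), 3)), "\n")
  cat("J (upper triangle):",
      format(round(x$J[upper.tri(x$J)], 3)), "\n")
  invisible(x)
}

#' Fit a pairwise maximum-entropy model by exact-gradient ascent
#'
#' Maximum-likelihood fit of the 6-feature Ising model to binarized data.
#' Because the pattern space has only 2^6 = 64 states, the likelihood and
#' its gradient (empirical minus model moments) are computed by full
#' enumeration; gradient ascent is run until every moment of the model
#' matches the corresponding empirical moment to within `tol`
#' (moment-matching stationarity is the convergence certificate).
#'
#' @param x n x 6 matrix of 0/1 bits, one row per binarized record.
#' @param weights Optional nonnegative row weights (normalized internally);
#'   passing the 64 exact probabilities of a known model with `x =
#'   all_patterns()` fits in the infinite-sample limit.
#' @param coding State coding, see [ising_model()].
#' @param feature_order Feature names for the 6 columns.
#' @param learning_rate Gradient-ascent step size.
#' @param tol Convergence tolerance on the largest absolute moment mismatch.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   last gradient norm.
#' @return An `ising_model` with a `fit` component (iterations, final
#'   max gradient, empirical moments).
#' @examples
#' m <- ising_model(rep(0, 6), matrix(0, 6, 6))
#' x <- sample_ising(m, 500, seed = 1)
#' fit <- fit_pairwise_maxent(x)
#' @export
fit_pairwise_maxent <- function(x, weights = NULL,
                                coding = c("01", "pm1"),
                                feature_order = ela_features(),
                                learning_rate = 0.1, tol = 1e-6,
                                max_iter = 1e5) {
  coding <- match.arg(coding)
  x <- as.matrix(x)
  if (ncol(x) != 6L) stop("x must have 6 columns")
  if (nrow(x) < 1L) stop("x must have at least one row")
  if (anyNA(x) || !all(x == 0 | x == 1)) stop("x must be a 0/1 matrix")
  if (is.null(weights)) weights <- rep(1, nrow(x))
  if (length(weights) != nrow(x) || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative with positive sum")
  w <- weights / sum(weights)

  col_mean <- drop(crossprod(x, w))
  if (any(col_mean <= 0 | col_mean >= 1))
    stop("degenerate column (all 0 or all 1): feature(s) ",
         paste(feature_order[col_mean <= 0 | col_mean >= 1], collapse = ", "),
         "; regularize or drop the feature before fitting")

  emp <- drop(crossprod(suff_stats(x, coding), w))   # 21 empirical moments
  S <- suff_stats(all_patterns(), coding)            # 64 x 21
  theta <- numeric(21L)
  iter <- 0L
  repeat {
    u <- drop(S %*% theta)                           # -E(sigma)
    u <- u - max(u)
    p <- exp(u); p <- p / sum(p)
    g <- emp - drop(crossprod(S, p))
    gmax <- max(abs(g))
    if (gmax < tol) break
    iter <- iter + 1L
    if (iter > max_iter)
      stop("Ising fit did not converge within ", max_iter,
           " iterations (max gradient ", signif(gmax, 4), ")")
    theta <- theta + learning_rate * g
  }

  J <- matrix(0, 6L, 6L)
  J[PAIR_IDX] <- theta[7:21]
  J <- J + t(J)
  model <- ising_model(theta[1:6], J, feature_order = feature_order,
                       coding = coding)
  model$fit <- list(iterations = iter, max_gradient = gmax,
                    empirical_moments = emp, n = nrow(x))
  model
}

#' Draw exact samples from an Ising model
#'
#' Enumerates the 64 pattern probabilities and samples categorically, so
#' draws are exact (no Monte-Carlo chain).
#'
#' @param model An [ising_model()].
#' @param n Number of samples (>= 1).
#' @param seed Integer RNG seed; identical seeds give identical samples.
#' @return n x 6 integer matrix of 0/1 bits.
#' @export
sample_ising <- function(model, n, seed = 1) {
  if (!inherits(model, "ising_model")) stop("model must be an ising_model")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  p <- energy_landscape(model)$probabilities
  set.seed(seed)
  idx <- sample.int(64L, n, replace = TRUE, prob = p)
  all_patterns()[idx, , drop = FALSE]
}
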