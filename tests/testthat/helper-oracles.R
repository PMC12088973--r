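# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use plain loops and formulas, not package internals.

# MSB-first bits of a pattern index.
oracle_bits <- function(i) (i %/% 2^(5:0)) %% 2

# Hamming-1 neighbours (0-based indices).
oracle_neighbors <- function(i) bitwXor(i, 2^(0:5))

# Brute-force Ising energy/probabilities with explicit double loops.
oracle_energy <- function(i, h, J, coding = "01") {
  s <- oracle_bits(i)
  if (coding == "pm1") s <- 2 * s - 1
  e <- -sum(h * s)
  for (a in 1:5) for (b in (a + 1):6) e <- e - J[a, b] * s[a] * s[b]
  e
}

oracle_probs <- function(h, J, coding = "01") {
  E <- vapply(0:63, oracle_energy, numeric(1), h = h, J = J, coding = coding)
  p <- exp(-(E - min(E)))
  p / sum(p)
}

# Greedy descent to a local minimum under the (energy, index) tie rule.
oracle_descend <- function(i, E) {
  repeat {
    nbs <- oracle_neighbors(i)
    best <- nbs[order(E[nbs + 1], nbs)][1]
    if (E[best + 1] < E[i + 1] || (E[best + 1] == E[i + 1] && best < i)) {
      i <- best
    } else {
      return(i)
    }
  }
}

# Minimax path value between all pattern pairs by Floyd-Warshall on the
# Hamming graph with node-energy max weights, restricted to an allowed set.
oracle_minimax <- function(E, allowed = 0:63) {
  D <- matrix(Inf, 64, 64)
  in_allowed <- (0:63) %in% allowed
  for (u in allowed) {
    D[u + 1, u + 1] <- E[u + 1]
    for (v in oracle_neighbors(u)) {
      if (in_allowed[v + 1]) D[u + 1, v + 1] <- max(E[u + 1], E[v + 1])
    }
  }
  for (k in allowed + 1) {
    D <- pmin(D, pmax(matrix(D[, k], 64, 64),
                      matrix(D[k, ], 64, 64, byrow = TRUE)))
  }
  D
}

# A fixed non-trivial Ising model for sampling/fitting checks.
oracle_test_model <- function(seed = 42, scale = 0.8) {
  set.seed(seed)
  J <- matrix(0, 6, 6)
  J[upper.tri(J)] <- runif(15, -scale, scale)
  J <- J + t(J)
  ising_model(runif(6, -1, 1), J)
}

# One checkup record row with every biomarker present (default value 1);
# override features or set them NA via ...
rec <- function(id, year, sex = "male", fasting = TRUE,
                hist = FALSE, treat = FALSE, ...) {
  feats <- stats::setNames(as.list(rep(1, length(checkup_features()))),
                           checkup_features())
  dots <- list(...)
  feats[names(dots)] <- dots
  cbind(
    data.frame(individual_id = id, year = year, sex = sex, fasting = fasting,
               questionnaire_history = hist, questionnaire_treatment = treat),
    as.data.frame(feats, check.names = FALSE)
  )
}

recs <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

# Yates-corrected chi-squared from first principles; the correction is
# capped at |O - E| so the statistic cannot go negative.
oracle_yates <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  y <- min(0.5, abs(tab - E))
  stat <- sum((abs(tab - E) - y)^2 / E)
  list(statistic = stat, p.value = stats::pchisq(stat, 1, lower.tail = FALSE))
}
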