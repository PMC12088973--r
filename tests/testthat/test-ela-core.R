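# Binarization, Ising fitting, landscape, basins, barriers.

test_that("thresholds are pooled sample medians with HDL-C reversed", {
  r <- recs(rec("A", 2012, PG = 1), rec("A", 2013, PG = 2),
            rec("B", 2012, PG = 3))
  th <- compute_thresholds(r)
  expect_equal(unname(th$threshold["PG"]), 2)

  # even n: midpoint of the central order statistics, against a sort oracle
  vals <- c(4, 1, 3, 2)
  r4 <- recs(rec("A", 2012, PG = 4), rec("A", 2013, PG = 1),
             rec("B", 2012, PG = 3), rec("B", 2013, PG = 2))
  th4 <- compute_thresholds(r4)
  s <- sort(vals)
  expect_equal(unname(th4$threshold["PG"]), (s[2] + s[3]) / 2)

  expect_identical(names(which(th$reversed)), "HDL_C")
  expect_error(compute_thresholds(r[0, ]), "empty")
  r$PG[1] <- NA
  expect_error(compute_thresholds(r), "non-missing")
})

test_that("binarization maps threshold values to 0 and reverses HDL-C", {
  base <- rec("A", 2012, HbA1c = 5.6, PG = 95, HDL_C = 58, BMI = 23.3,
              UA = 6.1, ALT = 22)
  many <- recs(base,
               rec("A", 2013, HbA1c = 5.0, PG = 90, HDL_C = 60, BMI = 22,
                   UA = 5.0, ALT = 15),
               rec("B", 2012, HbA1c = 6.0, PG = 100, HDL_C = 50, BMI = 25,
                   UA = 7.0, ALT = 30))
  th <- compute_thresholds(many)

  # value exactly at its own threshold: 0 for standard, 1 for HDL-C
  at_thr <- rec("Z", 2012, HbA1c = th$threshold["HbA1c"],
                PG = th$threshold["PG"], HDL_C = th$threshold["HDL_C"],
                BMI = th$threshold["BMI"], UA = th$threshold["UA"],
                ALT = th$threshold["ALT"])
  bits <- binarize(at_thr, th)
  expect_equal(as.integer(bits), c(0L, 0L, 1L, 0L, 0L, 0L))

  # worse than every threshold (HDL-C below, the rest above) -> 111111
  worst <- rec("Z", 2012, HbA1c = 99, PG = 999, HDL_C = 1, BMI = 99,
               UA = 99, ALT = 999)
  expect_equal(pattern_index(binarize(worst, th)), 63L)

  # better than every threshold -> 000000
  best <- rec("Z", 2012, HbA1c = 1, PG = 1, HDL_C = 999, BMI = 1,
              UA = 1, ALT = 1)
  expect_equal(pattern_index(binarize(best, th)), 0L)

  miss <- rec("Z", 2012, PG = NA)
  expect_error(binarize(miss, th), "missing")
})

test_that("near-uniform data fit to the uniform maximum-entropy model", {
  set.seed(31)
  x <- matrix(rbinom(50000 * 6, 1, 0.5), ncol = 6)
  fit <- fit_pairwise_maxent(x)
  p <- energy_landscape(fit)$probabilities
  expect_true(all(abs(p - 1 / 64) < 0.005))
})

test_that("weighted fit on an exact distribution recovers it (infinite-sample limit)", {
  m <- oracle_test_model()
  p_true <- oracle_probs(unname(m$h), m$J)
  fit <- fit_pairwise_maxent(all_patterns(), weights = p_true, tol = 1e-8)
  p_fit <- energy_landscape(fit)$probabilities
  expect_lt(max(abs(p_fit - p_true)), 1e-6)
  # moment matching at convergence, the fit's certificate
  expect_lt(fit$fit$max_gradient, 1e-8)
  # and both codings parameterize the same distribution
  fit_pm <- fit_pairwise_maxent(all_patterns(), weights = p_true,
                                coding = "pm1", tol = 1e-8)
  expect_lt(max(abs(energy_landscape(fit_pm)$probabilities - p_true)), 1e-6)
})

test_that("fitting samples from a known model recovers it within Monte-Carlo error", {
  m <- oracle_test_model()
  n <- 1e5
  x <- sample_ising(m, n, seed = 8)
  fit <- fit_pairwise_maxent(x)
  p_true <- oracle_probs(unname(m$h), m$J)
  p_fit <- energy_landscape(fit)$probabilities
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_true(all(abs(p_fit - p_true) < 3 * se))
})

test_that("degenerate columns are rejected with advice", {
  x <- matrix(rbinom(600, 1, 0.5), ncol = 6)
  x[, 3] <- 0
  expect_error(fit_pairwise_maxent(x), "regularize")
})

test_that("energies and probabilities match brute-force enumeration", {
  m0 <- ising_model(rep(0, 6), matrix(0, 6, 6))
  ls0 <- energy_landscape(m0)
  expect_equal(ls0$probabilities, rep(1 / 64, 64))
  expect_equal(diff(range(ls0$energies)), 0)

  for (s in 1:5) {
    m <- oracle_test_model(seed = s)
    ls <- energy_landscape(m)
    E_oracle <- vapply(0:63, oracle_energy, numeric(1),
                       h = unname(m$h), J = m$J)
    expect_equal(ls$energies, E_oracle)
    expect_equal(order(ls$energies), order(E_oracle))
    expect_lt(abs(sum(ls$probabilities) - 1), 1e-12)
    expect_equal(ls$probabilities, oracle_probs(unname(m$h), m$J))
  }
})

test_that("monotone landscape has a single all-encompassing basin", {
  E <- vapply(0:63, function(i) sum(oracle_bits(i)), numeric(1))
  b <- basin_graph(E)
  expect_equal(b$local_minima, 0L)
  expect_equal(b$n_states, 1L)
  expect_true(all(b$state_of == 1L))
})

test_that("double-well landscape splits at the equator", {
  pc <- vapply(0:63, function(i) sum(oracle_bits(i)), numeric(1))
  E <- pmin(pc, 6 - pc)
  b <- basin_graph(E)
  expect_equal(b$local_minima, c(0L, 63L))
  # partition agrees with exhaustive greedy descent from every pattern
  term <- vapply(0:63, oracle_descend, numeric(1), E = E)
  expect_equal(b$state_of, match(term, c(0, 63)))

  d <- disconnectivity(E, b)
  expect_equal(unname(d$barrier[1, 2]), 3)  # must cross popcount 3
  D <- oracle_minimax(E)
  expect_equal(unname(d$barrier[1, 2]), D[1, 64])
})

test_that("basins and barriers equal brute force on random landscapes", {
  n_strict <- 0L
  for (s in 1:100) {
    set.seed(s)
    E <- rnorm(64)
    b <- basin_graph(E)

    # every pattern belongs to the state of its descent terminal
    term <- vapply(0:63, oracle_descend, numeric(1), E = E)
    expect_equal(b$state_of, match(term, b$local_minima))
    # minima are weak minima of their neighbourhood
    for (m in b$local_minima)
      expect_true(all(E[m + 1] <= E[oracle_neighbors(m) + 1]))
    # descent from any pattern reaches the minimum in at most 63 steps
    expect_true(all(!is.na(b$state_of)))

    d <- disconnectivity(E, b)
    D <- oracle_minimax(E)
    K <- b$n_states
    for (a in seq_len(K)) for (bb in seq_len(K)) {
      i <- b$local_minima[a]; j <- b$local_minima[bb]
      expect_equal(unname(d$barrier[a, bb]), D[i + 1, j + 1])
      expect_gte(d$barrier[a, bb], max(E[i + 1], E[j + 1]))
    }
    expect_equal(d$barrier, t(d$barrier))

    if (K >= 2) {
      dm <- modified_disconnectivity(E, b)
      # restriction never lowers a barrier...
      expect_true(all(dm - d$barrier >= -1e-12))
      n_strict <- n_strict + sum(dm > d$barrier + 1e-9 & upper.tri(dm))
      # ...and matches brute force on the restricted pattern set
      if (K >= 3) {
        allowed <- which(b$state_of %in% c(1, 2)) - 1L
        Dr <- oracle_minimax(E, allowed)
        expect_equal(unname(dm[1, 2]),
                     Dr[b$local_minima[1] + 1, b$local_minima[2] + 1])
      }
    }
  }
  # detours through third states exist, and prohibiting them raises barriers
  expect_gt(n_strict, 0L)
})

test_that("barriers are monotone under nested allowed sets", {
  for (s in 1:20) {
    set.seed(s + 500)
    E <- rnorm(64)
    b <- basin_graph(E)
    if (b$n_states < 2) next
    set.seed(s)
    A <- sort(sample(0:63, 40))
    A <- union(A, b$local_minima)  # keep the minima queryable
    B <- sort(union(A, sample(0:63, 12)))
    dA <- disconnectivity(E, b, allowed_patterns = A)$barrier
    dB <- disconnectivity(E, b, allowed_patterns = B)$barrier
    dFull <- disconnectivity(E, b)$barrier
    # (>= rather than subtraction: Inf - Inf on doubly-disconnected pairs)
    expect_true(all(dA >= dB - 1e-12))
    expect_true(all(dB >= dFull - 1e-12))
  }
})

test_that("disconnected minima within the allowed set give infinite barriers", {
  pc <- vapply(0:63, function(i) sum(oracle_bits(i)), numeric(1))
  E <- pmin(pc, 6 - pc)
  b <- basin_graph(E)
  d <- disconnectivity(E, b, allowed_patterns = c(0L, 63L))
  expect_equal(unname(d$barrier[1, 2]), Inf)
})
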