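# Energy landscape, basin decomposition, and minimax barriers.

#' Compute the energy landscape of an Ising model
#'
#' Evaluates the energy E(sigma) of every 6-bit pattern and the Boltzmann
#' probabilities P(sigma) = exp(-E)/Z. Lower energy means a more frequent
#' pattern.
#'
#' @param model An [ising_model()].
#' @return Object of class `energy_landscape`: `energies` and
#'   `probabilities` (length-64, pattern-index order), `bits` (64 x 6),
#'   `feature_order`, `coding`, and the model.
#' @export
energy_landscape <- function(model) {
  if (!inherits(model, "ising_model")) stop("model must be an ising_model")
  S <- suff_stats(all_patterns(), model$coding)
  theta <- c(unname(model$h), model$J[PAIR_IDX])
  u <- drop(S %*% theta)
  energies <- -u
  z <- u - max(u)
  p <- exp(z); p <- p / sum(p)
  structure(
    list(energies = energies, probabilities = p, pattern = 0:63,
         bits = all_patterns(), feature_order = model$feature_order,
         coding = model$coding, model = model),
    class = "energy_landscape"
  )
}

#' @export
print.energy_landscape <- function(x, ...) {
  o <- order(x$energies)[1:3]
  cat("Energy landscape over 64 patterns (", paste(x$feature_order,
      collapse = ", "), ")\n", sep = "")
  cat("lowest-energy patterns:",
      paste0(o - 1, " (E=", round(x$energies[o], 3), ")", collapse = ", "),
      "\n")
  invisible(x)
}

# Lexicographic (energy, index) comparison used for all tie-breaking:
# pattern a "lies below" pattern b if E(a) < E(b), or E(a) == E(b) and
# a < b. Determinism on plateaus follows.
lex_below <- function(e_a, i_a, e_b, i_b) {
  e_a < e_b | (e_a == e_b & i_a < i_b)
}

#' Basin graph: descent edges, local minima, and states
#'
#' From every pattern a directed edge is drawn to the lowest-energy pattern
#' among its six Hamming-1 neighbours; patterns lying below their whole
#' neighbourhood (ties broken toward the lower pattern index) are local
#' minima and receive no edge. The connected components of this graph are
#' the landscape's *states*; states are numbered 1..K in increasing order
#' of their local-minimum pattern index.
#'
#' @param landscape An [energy_landscape()], or a bare numeric vector of 64
#'   energies in pattern-index order.
#' @return Object of class `basin_graph`: `descent_edge` (length-64
#'   0-based target index, NA at minima), `local_minima` (0-based, sorted),
#'   `state_of` (length-64 state label per pattern), `n_states`,
#'   `state_sizes`, and `energies`.
#' @export
basin_graph <- function(landscape) {
  E <- if (inherits(landscape, "energy_landscape")) landscape$energies
       else as.numeric(landscape)
  if (length(E) != 64L || anyNA(E)) stop("need 64 finite energies")
  nb <- pattern_neighbors()

  descent <- rep(NA_integer_, 64L)
  for (i in 0:63) {
    cand <- nb[i + 1L, ]
    # best neighbour under (energy, index) lexicographic order
    best <- cand[order(E[cand + 1L], cand)][1L]
    if (lex_below(E[best + 1L], best, E[i + 1L], i))
      descent[i + 1L] <- best
  }
  minima <- which(is.na(descent)) - 1L

  state_of <- integer(64L)
  terminal <- integer(64L)
  for (i in 0:63) {
    j <- i
    steps <- 0L
    while (!is.na(descent[j + 1L])) {
      j <- descent[j + 1L]
      steps <- steps + 1L
      if (steps > 63L) stop("descent did not terminate")  # cannot happen
    }
    terminal[i + 1L] <- j
  }
  state_of <- match(terminal, minima)  # minima already in increasing index

  structure(
    list(descent_edge = descent, local_minima = minima,
         state_of = state_of, n_states = length(minima),
         state_sizes = tabulate(state_of, length(minima)),
         energies = E),
    class = "basin_graph"
  )
}

#' @export
print.basin_graph <- function(x, ...) {
  cat("Basin graph: ", x$n_states, " state(s)\n", sep = "")
  for (k in seq_along(x$local_minima)) {
    m <- x$local_minima[k]
    cat(sprintf("  state %d: %d patterns, minimum %d (E=%.3f)\n",
                k, x$state_sizes[k], m, x$energies[m + 1L]))
  }
  invisible(x)
}

#' Minimax energy barriers between local minima (disconnectivity graph)
#'
#' For each pair of local minima, the barrier is the lowest achievable
#' maximum energy over all Hamming-1 paths connecting them, optionally
#' restricted to an allowed pattern set (the "modified" variant prohibits
#' visits outside the two states being compared). Computed by a threshold
#' sweep: patterns are activated in increasing (energy, index) order and
#' merged with active neighbours in a union-find; the barrier for a pair of
#' minima is the energy at which their components first join.
#'
#' @param landscape An [energy_landscape()] or 64 energies.
#' @param basins The [basin_graph()] of the same landscape.
#' @param allowed_patterns 0-based pattern indices the path may visit
#'   (default all 64). Minima outside the allowed set, or pairs left
#'   disconnected within it, get an `Inf` barrier.
#' @return Object of class `disconnectivity_result`: `barrier` (K x K
#'   symmetric, diagonal = the minima's own energies), `relative_barrier`
#'   (`barrier[a, b] - E(minimum a)`, the climb out of state a),
#'   `minima`, and `allowed_patterns`.
#' @export
disconnectivity <- function(landscape, basins,
                            allowed_patterns = 0:63) {
  E <- if (inherits(landscape, "energy_landscape")) landscape$energies
       else as.numeric(landscape)
  if (!inherits(basins, "basin_graph")) stop("basins must be a basin_graph")
  allowed <- sort(unique(as.integer(allowed_patterns)))
  if (any(allowed < 0L | allowed > 63L)) stop("allowed_patterns must be in 0..63")
  minima <- basins$local_minima
  K <- length(minima)
  lab <- paste0("state", seq_len(K), ".min", minima)

  barrier <- matrix(Inf, K, K, dimnames = list(lab, lab))
  diag(barrier) <- E[minima + 1L]

  if (K >= 2L && length(allowed) > 0L) {
    parent <- seq_len(64L)
    find <- function(a) {
      while (parent[a] != a) {
        parent[a] <<- parent[parent[a]]
        a <- parent[a]
      }
      a
    }
    nb <- pattern_neighbors()
    active <- logical(64L)
    in_allowed <- logical(64L); in_allowed[allowed + 1L] <- TRUE
    ord <- allowed[order(E[allowed + 1L], allowed)]
    pend <- which(upper.tri(barrier), arr.ind = TRUE)
    pend <- pend[minima[pend[, 1]] %in% allowed &
                 minima[pend[, 2]] %in% allowed, , drop = FALSE]
    for (u in ord) {
      active[u + 1L] <- TRUE
      for (v in nb[u + 1L, ]) {
        if (in_allowed[v + 1L] && active[v + 1L]) {
          ru <- find(u + 1L); rv <- find(v + 1L)
          if (ru != rv) parent[ru] <- rv
        }
      }
      if (nrow(pend) > 0L) {
        joined <- logical(nrow(pend))
        for (r in seq_len(nrow(pend))) {
          a <- minima[pend[r, 1]]; b <- minima[pend[r, 2]]
          if (active[a + 1L] && active[b + 1L] &&
              find(a + 1L) == find(b + 1L)) {
            barrier[pend[r, 1], pend[r, 2]] <- E[u + 1L]
            barrier[pend[r, 2], pend[r, 1]] <- E[u + 1L]
            joined[r] <- TRUE
          }
        }
        pend <- pend[!joined, , drop = FALSE]
        if (nrow(pend) == 0L) break
      }
    }
  }

  rel <- barrier - E[minima + 1L]  # row a: climb out of state a
  diag(rel) <- 0
  structure(
    list(barrier = barrier, relative_barrier = rel, minima = minima,
         allowed_patterns = allowed),
    class = "disconnectivity_result"
  )
}

#' @export
print.disconnectivity_result <- function(x, ...) {
  cat("Minimax energy barriers between",
      length(x$minima), "local minima")
  if (length(x$allowed_patterns) < 64L)
    cat(" (restricted to", length(x$allowed_patterns), "patterns)")
  cat("\n")
  print(round(x$barrier, 3))
  invisible(x)
}

#' Modified disconnectivity: pairwise barriers restricted to the two states
#'
#' For every pair of states, recomputes the barrier between their minima
#' with paths confined to the patterns of those two states. Restricting
#' the path can only raise a barrier; a strict increase means the optimal
#' unrestricted saddle path detoured through a third state.
#'
#' @inheritParams disconnectivity
#' @return K x K symmetric matrix of restricted barriers (diagonal = the
#'   minima's energies; `Inf` if the two states are not adjacent).
#' @export
modified_disconnectivity <- function(landscape, basins) {
  K <- basins$n_states
  E <- if (inherits(landscape, "energy_landscape")) landscape$energies
       else as.numeric(landscape)
  out <- matrix(Inf, K, K)
  diag(out) <- E[basins$local_minima + 1L]
  if (K >= 2L) {
    for (a in 1:(K - 1)) for (b in (a + 1):K) {
      allowed <- which(basins$state_of %in% c(a, b)) - 1L
      d <- disconnectivity(landscape, basins, allowed_patterns = allowed)
      out[a, b] <- out[b, a] <- d$barrier[a, b]
    }
  }
  dimnames(out) <- dimnames(disconnectivity(landscape, basins)$barrier)
  out
}
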