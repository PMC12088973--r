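# Basic figures: basin graph and disconnectivity dendrogram.

#' Plot a basin graph
#'
#' Draws the 64 patterns with their descent edges (each non-minimum
#' pattern points to its lowest-energy Hamming-1 neighbour), nodes shaded
#' by energy and local minima highlighted. Requires the igraph package.
#'
#' @param x A [basin_graph()].
#' @param ... Passed to `igraph::plot.igraph`.
#' @export
plot.basin_graph <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting the basin graph requires the igraph package")
  src <- which(!is.na(x$descent_edge))
  edges <- rbind(src, x$descent_edge[src] + 1L)
  g <- igraph::make_empty_graph(n = 64, directed = TRUE)
  g <- igraph::add_edges(g, as.vector(edges))
  e <- x$energies
  shade <- (e - min(e)) / (diff(range(e)) + 1e-12)
  igraph::V(g)$label <- 0:63
  igraph::V(g)$color <- grDevices::gray(1 - 0.75 * shade)
  igraph::V(g)$frame.color <-
    ifelse(0:63 %in% x$local_minima, "red", "gray40")
  igraph::plot.igraph(g, vertex.size = 11, vertex.label.cex = 0.6,
                      edge.arrow.size = 0.3, ...)
  invisible(x)
}

#' Plot a disconnectivity graph
#'
#' Renders the minimax barrier matrix as a dendrogram: leaves are the
#' local minima at their own energies, and each junction sits at the
#' energy where the two branches' basins first connect. (Minimax barriers
#' form an ultrametric, so single-linkage clustering reconstructs the
#' tree exactly.)
#'
#' @param x A [disconnectivity()] result with at least two minima.
#' @param ... Passed to [plot()].
#' @export
plot.disconnectivity_result <- function(x, ...) {
  K <- length(x$minima)
  if (K < 2L) {
    message("single local minimum; nothing to draw")
    return(invisible(x))
  }
  d <- x$barrier
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  plot(hc, ylab = "energy barrier", xlab = "", sub = "",
       main = "Disconnectivity graph", ...)
  invisible(x)
}
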