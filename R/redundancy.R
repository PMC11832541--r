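#' Density grid for proportional thresholding
#'
#' Ordered connection densities at which each window's correlation matrix is
#' thresholded and binarised. The default grid, 5% to 95% in 5% steps,
#' produces 19 binary graphs per window.
#'
#' @param start,stop,step Grid limits and increment, fractions in (0, 1].
#' @return Numeric vector of strictly increasing densities, class
#'   `density_grid`.
#' @examples
#' length(density_grid())  # 19
#' @export
density_grid <- function(start = 0.05, stop = 0.95, step = 0.05) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step) ||
      start <= 0 || stop > 1 || step <= 0 || start > stop) {
    stop("density grid requires 0 < start <= stop <= 1 and step > 0")
  }
  d <- seq(start, stop, by = step)
  structure(round(d, 10), class = "density_grid")
}

# Rank all off-diagonal pairs of a symmetric matrix: strongest first, ties
# broken by lexicographic (i, j) node-pair order. The fixed ordering makes
# edge sets nested across the density grid and runs deterministic.
edge_ranking <- function(corr, rank_mode = c("signed", "absolute")) {
  rank_mode <- match.arg(rank_mode)
  n <- nrow(corr)
  if (n != ncol(corr)) stop("correlation matrix must be square")
  ut <- upper.tri(corr)
  idx <- which(ut, arr.ind = TRUE)
  vals <- corr[ut]
  if (rank_mode == "absolute") vals <- abs(vals)
  ord <- order(-vals, idx[, 1L], idx[, 2L])
  idx[ord, , drop = FALSE]
}

#' Proportionally threshold a correlation matrix
#'
#' Keeps the `round(density * P)` strongest off-diagonal edges, where
#' `P = n(n-1)/2` and rounding is half away from zero, then binarises. By
#' default edges are ranked by signed correlation (strongest positive
#' first); `rank_mode = "absolute"` ranks by magnitude instead. Ties are
#' broken by lexicographic node-pair order, so edge sets are nested across
#' densities.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @param density Fraction of edges to keep, in (0, 1].
#' @param rank_mode `"signed"` (default) or `"absolute"`.
#' @return A `binary_graph`: list with `n_nodes`, `edges` (2-column matrix
#'   of node indices, one row per kept edge) and `density`.
#' @export
proportional_threshold <- function(corr, density,
                                   rank_mode = c("signed", "absolute")) {
  rank_mode <- match.arg(rank_mode)
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1) {
    stop("'density' must be a single fraction in (0, 1]")
  }
  ranking <- edge_ranking(corr, rank_mode)
  binary_graph_from_ranking(ranking, nrow(corr), density)
}

# Take the top-m prefix of a precomputed ranking.
binary_graph_from_ranking <- function(ranking, n_nodes, density) {
  p_max <- n_nodes * (n_nodes - 1L) / 2
  m <- round_half_up(density * p_max)
  m <- min(m, nrow(ranking))
  structure(
    list(n_nodes = as.integer(n_nodes),
         edges = ranking[seq_len(m), , drop = FALSE],
         density = density),
    class = "binary_graph"
  )
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("Binary graph: %d nodes, %d edges (density %.3g)\n",
              x$n_nodes, nrow(x$edges), x$density))
  invisible(x)
}

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n_nodes, directed = FALSE)
  if (nrow(g$edges) > 0L) {
    ig <- igraph::add_edges(ig, t(g$edges))
  }
  ig
}

#' Count independent pathways between two regions
#'
#' Maximum number of independent paths between nodes `u` and `v`:
#' internally vertex-disjoint paths by default (Menger's theorem), or
#' edge-disjoint paths with `mode = "edge"`. Computed as unit-capacity
#' maximum flow; in vertex mode each internal node is split into an in/out
#' pair joined by a capacity-one arc. For an adjacent pair the direct edge
#' contributes one path and the remainder is counted with that edge removed.
#'
#' @param g A `binary_graph`.
#' @param u,v Distinct node indices.
#' @param mode `"vertex"` (default) or `"edge"` disjointness.
#' @return Integer path count.
#' @examples
#' tri <- structure(list(n_nodes = 3L,
#'                       edges = rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)),
#'                       density = 1), class = "binary_graph")
#' count_independent_paths(tri, 1, 3)  # 2
#' @export
count_independent_paths <- function(g, u, v, mode = c("vertex", "edge")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "binary_graph"))
  u <- as.integer(u); v <- as.integer(v)
  if (u == v) stop("'u' and 'v' must be distinct nodes")
  if (u < 1L || v < 1L || u > g$n_nodes || v > g$n_nodes) {
    stop("node index out of range")
  }
  edges <- g$edges
  if (nrow(edges) == 0L) return(0L)

  if (mode == "edge") {
    ig <- igraph::make_empty_graph(n = g$n_nodes, directed = TRUE)
    both <- rbind(edges, edges[, 2:1, drop = FALSE])
    ig <- igraph::add_edges(ig, t(both))
    fl <- igraph::max_flow(ig, source = u, target = v,
                           capacity = rep(1, nrow(both)))
    return(as.integer(round(fl$value)))
  }

  # vertex mode: count the direct edge separately, then split-node max-flow
  is_direct <- (edges[, 1L] == min(u, v)) & (edges[, 2L] == max(u, v))
  direct <- any(is_direct)
  edges <- edges[!is_direct, , drop = FALSE]
  if (nrow(edges) == 0L) return(as.integer(direct))

  n <- g$n_nodes
  # node i -> in-node i, out-node n + i; internal arcs capacity 1
  from <- c(seq_len(n) , rep(0L, 0L))
  arcs_from <- seq_len(n)
  arcs_to <- n + seq_len(n)
  cap_internal <- rep(1, n)
  cap_internal[c(u, v)] <- Inf
  # undirected edge (a, b) -> out_a -> in_b and out_b -> in_a, capacity 1
  e_from <- c(n + edges[, 1L], n + edges[, 2L])
  e_to <- c(edges[, 2L], edges[, 1L])
  ig <- igraph::make_empty_graph(n = 2L * n, directed = TRUE)
  ig <- igraph::add_edges(ig, rbind(c(arcs_from, e_from), c(arcs_to, e_to)))
  caps <- c(cap_internal, rep(1, length(e_from)))
  fl <- igraph::max_flow(ig, source = n + u, target = v, capacity = caps)
  as.integer(round(fl$value)) + as.integer(direct)
}

#' Test whether every region pair has at least k independent pathways
#'
#' `k = 1` asks that the network is one-connected (every pair joined by at
#' least one pathway), which is graph connectedness. `k = 2` asks for at
#' least two independent pathways between every pair; under vertex-disjoint
#' semantics this is biconnectivity (connected with no cut vertex), and
#' under edge-disjoint semantics two-edge-connectivity (connected with no
#' bridge). Both reduce to linear-time checks instead of all-pairs flow.
#'
#' @param g A `binary_graph`.
#' @param k 1 or 2.
#' @param mode `"vertex"` (default) or `"edge"` path disjointness.
#' @return Logical scalar.
#' @export
is_k_connected <- function(g, k, mode = c("vertex", "edge")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "binary_graph"))
  if (!k %in% c(1L, 2L)) stop("only k = 1 or k = 2 is supported")
  if (g$n_nodes < k + 1L) stop("graph too small for requested k")
  ig <- as_igraph(g)
  if (!igraph::is_connected(ig)) return(FALSE)
  if (k == 1L) return(TRUE)
  if (mode == "vertex") {
    length(igraph::articulation_points(ig)) == 0L
  } else {
    length(igraph::bridges(ig)) == 0L
  }
}

#' Minimal density at which the thresholded network is k-connected
#'
#' Scans the density grid from sparse to dense and returns the first density
#' whose thresholded binary graph is k-connected, or `NA` if none is by the
#' top of the grid. Because the fixed edge ranking makes edge sets nested
#' across the grid, k-connectedness is monotone in density; the `start_at`
#' argument lets the k = 2 scan resume from the one-connected density
#' without changing the result.
#'
#' @param corr Symmetric correlation matrix.
#' @param grid A [density_grid()].
#' @param k 1 or 2.
#' @param rank_mode,mode Passed to [proportional_threshold()] and
#'   [is_k_connected()].
#' @param start_at Lowest density to examine (default: start of grid).
#' @return The minimal density, or `NA_real_` if the network never reaches
#'   k-connectedness on the grid.
#' @export
min_density_k_connected <- function(corr, grid = density_grid(), k,
                                    rank_mode = c("signed", "absolute"),
                                    mode = c("vertex", "edge"),
                                    start_at = NULL) {
  rank_mode <- match.arg(rank_mode)
  mode <- match.arg(mode)
  ranking <- edge_ranking(corr, rank_mode)
  scan_grid(ranking, nrow(corr), grid, k, mode, start_at)
}

scan_grid <- function(ranking, n_nodes, grid, k, mode, start_at = NULL) {
  for (d in grid) {
    if (!is.null(start_at) && d < start_at) next
    g <- binary_graph_from_ranking(ranking, n_nodes, d)
    if (is_k_connected(g, k, mode)) return(d)
  }
  NA_real_
}

#' Label one window as redundant or not
#'
#' Finds the minimal grid density at which the window's network is
#' one-connected and the minimal density at which it is two-connected. The
#' window is redundant (label 1) when the two densities coincide — the
#' network already has two independent pathways between every region pair
#' at the density where it first becomes fully connected — and 0 otherwise,
#' including when either density is absent from the grid.
#'
#' @inheritParams min_density_k_connected
#' @return List with `label` (0/1), `d_one`, `d_two` (densities or `NA`).
#' @export
label_window <- function(corr, grid = density_grid(),
                         rank_mode = c("signed", "absolute"),
                         mode = c("vertex", "edge")) {
  rank_mode <- match.arg(rank_mode)
  mode <- match.arg(mode)
  ranking <- edge_ranking(corr, rank_mode)
  d_one <- scan_grid(ranking, nrow(corr), grid, 1L, mode)
  d_two <- NA_real_
  if (!is.na(d_one)) {
    # nested edge sets: the k=2 scan can start at d_one
    d_two <- scan_grid(ranking, nrow(corr), grid, 2L, mode, start_at = d_one)
  }
  label <- as.integer(!is.na(d_one) && !is.na(d_two) && d_one == d_two)
  list(label = label, d_one = d_one, d_two = d_two)
}

#' Brain functional redundancy score across sessions
#'
#' Labels every window of every session with [label_window()], concatenates
#' the label vectors in session order, and defines the BFR score as the
#' proportion of windows in the redundant state.
#'
#' @param stacks A single `dynfc_stack` or a list of them (one per session).
#' @param grid A [density_grid()].
#' @inheritParams min_density_k_connected
#' @return An object of class `redundancy_profile`: `labels`, `d_one`,
#'   `d_two` (per window, concatenated across sessions), `session` (session
#'   index per window), `bfr`, `n_windows`.
#' @export
bfr_score <- function(stacks, grid = density_grid(),
                      rank_mode = c("signed", "absolute"),
                      mode = c("vertex", "edge")) {
  rank_mode <- match.arg(rank_mode)
  mode <- match.arg(mode)
  if (inherits(stacks, "dynfc_stack")) stacks <- list(stacks)
  if (length(stacks) == 0L) stop("at least one session stack is required")
  if (!all(vapply(stacks, inherits, logical(1), "dynfc_stack"))) {
    stop("'stacks' must be dynfc_stack objects")
  }
  if (any(vapply(stacks, length, integer(1)) == 0L)) {
    stop("empty dynamic FC stack")
  }
  labels <- integer(0); d_one <- numeric(0); d_two <- numeric(0)
  session <- integer(0)
  n_unreached <- 0L
  for (si in seq_along(stacks)) {
    for (m in stacks[[si]]$matrices) {
      lw <- label_window(m, grid, rank_mode, mode)
      labels <- c(labels, lw$label)
      d_one <- c(d_one, lw$d_one)
      d_two <- c(d_two, lw$d_two)
      session <- c(session, si)
      if (is.na(lw$d_one)) n_unreached <- n_unreached + 1L
    }
  }
  if (n_unreached > 0L) {
    warning(sprintf(
      "%d window(s) never reached one-connectedness on the grid; labeled 0",
      n_unreached))
  }
  structure(
    list(labels = labels, d_one = d_one, d_two = d_two, session = session,
         bfr = mean(labels), n_windows = length(labels),
         subject_id = stacks[[1]]$subject_id),
    class = "redundancy_profile"
  )
}

#' @export
print.redundancy_profile <- function(x, ...) {
  cat(sprintf(
    "Redundancy profile: %d windows over %d session(s), BFR = %.3f\n",
    x$n_windows, length(unique(x$session)), x$bfr))
  invisible(x)
}
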