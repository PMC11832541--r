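# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (enumeration, textbook formulas) so they share no code
# path with the implementation they check.

# binary_graph construction without proportional_threshold
make_binary_graph <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  structure(list(n_nodes = as.integer(n), edges = edges,
                 density = nrow(edges) / (n * (n - 1) / 2)),
            class = "binary_graph")
}

random_binary_graph <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  make_binary_graph(n, pairs[keep, , drop = FALSE])
}

graph_adjacency <- function(g) {
  A <- matrix(FALSE, g$n_nodes, g$n_nodes)
  if (nrow(g$edges)) {
    A[g$edges] <- TRUE
    A[g$edges[, 2:1, drop = FALSE]] <- TRUE
  }
  A
}

# connectivity by breadth-first search on the adjacency matrix
oracle_connected_avoiding <- function(A, u, v, removed = integer(0)) {
  n <- nrow(A)
  alive <- setdiff(seq_len(n), removed)
  if (!(u %in% alive) || !(v %in% alive)) return(FALSE)
  seen <- rep(FALSE, n)
  seen[u] <- TRUE
  frontier <- u
  while (length(frontier)) {
    nxt <- integer(0)
    for (w in frontier) {
      nb <- intersect(which(A[w, ]), alive)
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      nxt <- c(nxt, nb)
    }
    if (seen[v]) return(TRUE)
    frontier <- nxt
  }
  seen[v]
}

# Menger oracle: max number of internally vertex-disjoint u-v paths equals
# the minimum vertex cut, found by exhaustive subset enumeration (plus the
# direct-edge recursion for adjacent pairs). Only viable for small n.
oracle_vertex_disjoint_paths <- function(g, u, v) {
  A <- graph_adjacency(g)
  if (A[u, v]) {
    g2 <- g
    drop <- (pmin(g$edges[, 1], g$edges[, 2]) == min(u, v)) &
      (pmax(g$edges[, 1], g$edges[, 2]) == max(u, v))
    g2$edges <- g$edges[!drop, , drop = FALSE]
    return(1L + oracle_vertex_disjoint_paths(g2, u, v))
  }
  if (!oracle_connected_avoiding(A, u, v)) return(0L)
  internal <- setdiff(seq_len(g$n_nodes), c(u, v))
  for (k in 0:length(internal)) {
    if (k == 0L) next
    subsets <- combn(internal, k, simplify = FALSE)
    for (S in subsets) {
      if (!oracle_connected_avoiding(A, u, v, removed = S)) return(k)
    }
  }
  length(internal) + 1L  # unreachable for simple graphs, kept for safety
}

# correlation matrix whose top edges form a prescribed structure: listed
# edges get strong weights (descending in list order), everything else a
# weak background value
structured_corr <- function(n, edges, strong = 0.9, weak = 0.1) {
  C <- matrix(weak, n, n)
  edges <- matrix(as.integer(edges), ncol = 2L)
  w <- strong - (seq_len(nrow(edges)) - 1L) * 1e-4
  for (i in seq_len(nrow(edges))) {
    C[edges[i, 1], edges[i, 2]] <- w[i]
    C[edges[i, 2], edges[i, 1]] <- w[i]
  }
  diag(C) <- 1
  C
}

ring_edges <- function(n) cbind(seq_len(n), c(seq_len(n)[-1], 1L))
star_edges <- function(n) cbind(1L, 2:n)

# point-to-line distance via the vector projection formula (independent of
# find_elbow's cross-product form)
oracle_elbow <- function(y) {
  n <- length(y)
  p1 <- c(1, y[1]); p2 <- c(n, y[n])
  dir <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  d <- vapply(seq_len(n), function(i) {
    v <- c(i, y[i]) - p1
    sqrt(max(sum(v^2) - sum(v * dir)^2, 0))
  }, numeric(1))
  which.max(d)
}

# random decreasing convex-ish scree curve
random_concave_curve <- function(len, seed) {
  set.seed(seed)
  drops <- sort(rexp(len - 1, rate = runif(1, 0.5, 2)), decreasing = TRUE)
  c(sum(drops), sum(drops) - cumsum(drops)) + runif(1, 0, 2)
}
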