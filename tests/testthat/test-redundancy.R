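test_that("density grid has 19 steps at defaults and validates input", {
  g <- density_grid()
  expect_length(g, 19L)
  expect_equal(g[1], 0.05)
  expect_equal(g[19], 0.95)
  expect_true(all(diff(g) > 0))
  expect_error(density_grid(0, 0.95, 0.05))
  expect_error(density_grid(0.5, 0.1, 0.05))
})

test_that("proportional threshold keeps the round(density * P) strongest edges", {
  set.seed(1)
  C4 <- structured_corr(4, rbind(c(1, 2)))
  g <- proportional_threshold(C4, 0.5)        # P = 6 -> 3 edges
  expect_equal(nrow(g$edges), 3L)
  g_full <- proportional_threshold(C4, 1.0)
  expect_equal(nrow(g_full$edges), 6L)

  # 5 nodes, distinct entries: density 0.2 keeps only the global maximum
  C5 <- matrix(0, 5, 5)
  C5[upper.tri(C5)] <- seq(0.1, 0.55, length.out = 10)
  C5 <- C5 + t(C5); diag(C5) <- 1
  top <- proportional_threshold(C5, 0.2)       # round(2) = 2... P=10 -> 2
  expect_equal(nrow(top$edges), 2L)
  single <- proportional_threshold(C5, 0.1)    # round(1) = 1 edge
  expect_equal(nrow(single$edges), 1L)
  expect_equal(C5[single$edges], max(C5[upper.tri(C5)]))

  # quota rounds half away from zero: n = 20 gives P = 190, 5% -> 10 edges
  C20 <- matrix(runif(400), 20, 20); C20 <- (C20 + t(C20)) / 2; diag(C20) <- 1
  expect_equal(nrow(proportional_threshold(C20, 0.05)$edges), 10L)

  expect_error(proportional_threshold(C4, 0), "fraction")
  expect_error(proportional_threshold(C4, 1.2), "fraction")
})

test_that("absolute ranking can promote strong negative correlations", {
  C <- structured_corr(4, rbind(c(1, 2)), strong = 0.5, weak = 0.05)
  C[3, 4] <- C[4, 3] <- -0.9
  signed <- proportional_threshold(C, 1 / 6)
  absolute <- proportional_threshold(C, 1 / 6, rank_mode = "absolute")
  expect_equal(unname(signed$edges[1, ]), c(1L, 2L))
  expect_equal(unname(absolute$edges[1, ]), c(3L, 4L))
})

test_that("independent-path counts match Menger's theorem on small graphs", {
  tri <- make_binary_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(count_independent_paths(tri, 1, 3), 2L)
  expect_equal(count_independent_paths(tri, 1, 2), 2L)

  path <- make_binary_graph(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(count_independent_paths(path, 1, 3), 1L)

  expect_error(count_independent_paths(tri, 2, 2), "distinct")

  # seeded random graphs against the exhaustive minimum-vertex-cut oracle
  for (seed in 1:12) {
    g <- random_binary_graph(sample(5:9, 1), runif(1, 0.25, 0.7), seed)
    pairs <- t(combn(g$n_nodes, 2))
    idx <- sample(nrow(pairs), 6)
    for (r in idx) {
      u <- pairs[r, 1]; v <- pairs[r, 2]
      expect_equal(count_independent_paths(g, u, v),
                   oracle_vertex_disjoint_paths(g, u, v),
                   info = sprintf("seed %d pair (%d,%d)", seed, u, v))
    }
  }
})

test_that("edge-disjoint mode counts at least as many paths as vertex mode", {
  # bowtie: two triangles sharing node 3 -> 1 vertex-disjoint path across,
  # but 2 edge-disjoint paths
  bow <- make_binary_graph(5, rbind(c(1, 2), c(1, 3), c(2, 3),
                                    c(3, 4), c(3, 5), c(4, 5)))
  expect_equal(count_independent_paths(bow, 1, 4, mode = "vertex"), 1L)
  expect_equal(count_independent_paths(bow, 1, 4, mode = "edge"), 2L)
})

test_that("k-connectedness matches all-pairs path counting", {
  cyc <- make_binary_graph(6, ring_edges(6))
  expect_true(is_k_connected(cyc, 1))
  expect_true(is_k_connected(cyc, 2))
  star <- make_binary_graph(6, star_edges(6))
  expect_true(is_k_connected(star, 1))
  expect_false(is_k_connected(star, 2))
  expect_error(is_k_connected(cyc, 3), "k = 1 or k = 2")

  for (seed in 1:50) {
    g <- random_binary_graph(sample(4:12, 1), runif(1, 0.15, 0.8), seed + 100)
    pairs <- t(combn(g$n_nodes, 2))
    counts <- apply(pairs, 1, function(p)
      count_independent_paths(g, p[1], p[2]))
    expect_identical(is_k_connected(g, 1), all(counts >= 1),
                     info = paste("k=1 seed", seed))
    expect_identical(is_k_connected(g, 2), all(counts >= 2),
                     info = paste("k=2 seed", seed))
  }
})

test_that("minimal k-connected density is found on crafted structures", {
  # 41 nodes: round(0.05 * 820) = 41 = exactly one spanning ring
  n <- 41
  Cring <- structured_corr(n, ring_edges(n), strong = 0.9, weak = 0.1)
  expect_equal(min_density_k_connected(Cring, k = 1), 0.05)
  expect_equal(min_density_k_connected(Cring, k = 2), 0.05)

  # star: one-connected as soon as its 40 edges fit (density 0.05), but a
  # hub cut vertex keeps it from two-connectedness until much later
  Cstar <- structured_corr(n, star_edges(n), strong = 0.9, weak = 0.1)
  expect_equal(min_density_k_connected(Cstar, k = 1), 0.05)
  expect_gt(min_density_k_connected(Cstar, k = 2), 0.05)
})

test_that("total ties resolve deterministically via lexicographic order", {
  C <- matrix(0.5, 8, 8); diag(C) <- 1
  runs <- replicate(3, unlist(label_window(C)), simplify = FALSE)
  expect_identical(runs[[1]], runs[[2]])
  expect_identical(runs[[2]], runs[[3]])
  g1 <- proportional_threshold(C, 0.25)
  g2 <- proportional_threshold(C, 0.25)
  expect_identical(g1$edges, g2$edges)
  # under total ties the first edges are the lexicographically smallest pairs
  expect_equal(unname(g1$edges[1, ]), c(1L, 2L))
})

test_that("window labels follow the d_one = d_two rule", {
  n <- 41
  ring <- label_window(structured_corr(n, ring_edges(n)))
  expect_equal(ring$label, 1L)
  expect_equal(ring$d_one, ring$d_two)

  star <- label_window(structured_corr(n, star_edges(n)))
  expect_equal(star$label, 0L)
  expect_gt(star$d_two, star$d_one)

  # a grid truncated below the connection density exercises the ABSENT path
  short_grid <- density_grid(0.01, 0.02, 0.01)
  absent <- label_window(structured_corr(n, ring_edges(n)), grid = short_grid)
  expect_true(is.na(absent$d_one))
  expect_true(is.na(absent$d_two))
  expect_equal(absent$label, 0L)
})

test_that("edge sets are nested across the grid and d_two >= d_one", {
  grid <- density_grid()
  mats <- c(
    build_stack(gen_timeseries(14, 100, "REDUNDANT", 10, seed = 2),
                50, 10)$matrices,
    build_stack(gen_timeseries(14, 100, "FRAGILE", 10, seed = 2),
                50, 10)$matrices)
  for (m in mats) {
    prev <- character(0)
    for (d in grid) {
      g <- proportional_threshold(m, d)
      keys <- paste(g$edges[, 1], g$edges[, 2])
      expect_true(all(prev %in% keys))
      prev <- keys
    }
    lw <- label_window(m, grid)
    if (!is.na(lw$d_one) && !is.na(lw$d_two)) {
      expect_gte(lw$d_two, lw$d_one)
    }
  }
})

test_that("BFR is the label mean, concatenated across sessions", {
  n <- 41
  ring_m <- structured_corr(n, ring_edges(n))
  star_m <- structured_corr(n, star_edges(n))
  fake_stack <- function(mats) {
    structure(list(matrices = mats, window_volumes = 50L, step_volumes = 1L,
                   window_start_indices = seq_along(mats),
                   window_seconds = 150, tr_seconds = 3,
                   subject_id = "s", session_id = "1"),
              class = "dynfc_stack")
  }
  prof <- bfr_score(list(fake_stack(list(ring_m, star_m)),
                         fake_stack(list(ring_m, ring_m))))
  expect_equal(prof$labels, c(1L, 0L, 1L, 1L))
  expect_equal(prof$bfr, 0.75)
  expect_equal(prof$n_windows, 4L)
  expect_equal(prof$session, c(1L, 1L, 2L, 2L))
  # order-free score
  expect_equal(mean(sample(prof$labels)), prof$bfr)
  expect_error(bfr_score(list()), "at least one")

  # never-connected windows produce an aggregated warning and zeros
  expect_warning(
    prof0 <- bfr_score(fake_stack(list(ring_m)),
                       grid = density_grid(0.01, 0.02, 0.01)),
    "never reached")
  expect_equal(prof0$bfr, 0)
})
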