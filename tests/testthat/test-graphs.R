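test_that("cosine graph handles identical, orthogonal and random rows", {
  X <- rbind(c(1, 1, 0), c(2, 2, 0), c(0, 0, 3))
  g <- build_cosine_graph(X, 0.3)
  expect_equal(g$adjacency[1, 2], 1)          # parallel vectors
  expect_equal(g$adjacency[1, 3], 0)          # orthogonal, below threshold
  set.seed(1)
  X <- matrix(runif(5 * 4), 5, 4)
  g <- build_cosine_graph(X, 0.3)
  expect_lt(max(abs(g$adjacency - oracle_cosine_graph(X, 0.3))), 1e-12)
})

test_that("zero-norm rows get zero similarity with a warning", {
  X <- rbind(c(0, 0), c(1, 1), c(1, 0))
  expect_warning(g <- build_cosine_graph(X, 0.3), "zero-norm")
  expect_equal(g$adjacency[1, ], c(0, 0, 0))
})

test_that("euclidean kernel graph matches its analytic form", {
  X <- rbind(c(0, 0), c(0, 0), c(1, 0))
  g <- build_euclidean_graph(X, 0.3)
  expect_equal(g$adjacency[1, 2], 1) # zero distance
  set.seed(2)
  X <- matrix(runif(6 * 3), 6, 3)
  g <- build_euclidean_graph(X, 0.3)
  expect_lt(max(abs(g$adjacency - oracle_euclidean_graph(X, 0.3))), 1e-12)
})

test_that("a pair exactly at the kernel threshold is retained", {
  # collinear points 0, 1, t with t chosen so sigma = median distance = 1
  # and the longest pair sits exactly at weight 0.3
  t <- sqrt(2 * log(1 / 0.3))
  X <- cbind(c(0, 1, t))
  g <- build_euclidean_graph(X, 0.3)
  expect_equal(g$adjacency[1, 3], 0.3, tolerance = 1e-12)
  expect_gt(g$adjacency[1, 3], 0) # kept under closed threshold semantics
})

test_that("style graph enumerates shared-style pairs exactly", {
  g <- build_style_graph(c("A", "A", "B"))
  expect_equal(sum(g$adjacency > 0) / 2, 1)
  expect_equal(g$adjacency[1, 2], 1)
  g4 <- build_style_graph(rep("A", 4))
  expect_equal(sum(g4$adjacency > 0) / 2, 6)
  gd <- build_style_graph(letters[1:5])
  expect_equal(sum(gd$adjacency), 0)
  # edge count identity over mixed styles
  styles <- c("a", "a", "a", "b", "b", "c")
  ns <- table(styles)
  g <- build_style_graph(styles)
  expect_equal(sum(g$adjacency > 0) / 2, sum(ns * (ns - 1) / 2))
})

test_that("PERMA-weighted graph reduces to and extends clipped cosine", {
  sch <- default_schema(8L)
  prior <- default_perma_prior(sch)
  set.seed(3)
  X <- matrix(runif(6 * 8), 6, 8)
  # identical students: weight sums to exactly 1
  Xdup <- rbind(X[1, ], X[1, ], X[3:6, ])
  g <- build_perma_graph(Xdup, prior, 0.3)
  expect_equal(g$adjacency[1, 2], 1, tolerance = 1e-12)
  # all dimension mass on one column reduces to cosine on masked features
  prior1 <- perma_prior(prior$weights, c(1, 0, 0, 0, 0))
  g1 <- build_perma_graph(X, prior1, 0.3)
  gc <- build_cosine_graph(sweep(X, 2, prior$weights[, 1], "*"), 0.3)
  expect_lt(max(abs(g1$adjacency - gc$adjacency)), 1e-12)
  # brute-force double loop over dimensions and pairs
  g <- build_perma_graph(X, prior, 0.3)
  expect_lt(max(abs(g$adjacency -
                      oracle_perma_graph(X, prior$weights,
                                         prior$dim_weights, 0.3))), 1e-12)
})

test_that("normalized adjacency matches the dense formula", {
  # empty graph: identity
  empty <- perma_topology("cosine", matrix(0, 3, 3))
  expect_equal(normalize_adjacency(empty), diag(3))
  # two nodes, one unit edge: all entries 0.5
  two <- perma_topology("cosine", matrix(c(0, 1, 1, 0), 2))
  expect_equal(normalize_adjacency(two), matrix(0.5, 2, 2))
  # random 8-node graph vs explicit D^{-1/2}(A+I)D^{-1/2}
  set.seed(4)
  X <- matrix(runif(8 * 5), 8, 5)
  g <- build_cosine_graph(X, 0.3)
  N <- normalize_adjacency(g)
  expect_lt(max(abs(N - oracle_normalize(g$adjacency))), 1e-12)
  ev <- eigen(N, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1 - 1e-9 & ev <= 1 + 1e-9))
})

test_that("all topology invariants hold on a synthetic cohort", {
  co <- generate_cohort(synthetic_spec(n = 50, seed = 9))
  ts <- build_topology_set(co)
  expect_named(ts, c("cosine", "euclidean", "learning", "perma"))
  for (g in ts) {
    A <- g$adjacency
    expect_equal(A, t(A))
    expect_true(all(diag(A) == 0))
    nz <- A[A != 0]
    if (length(nz)) {
      expect_gte(min(nz), 0.3 - 1e-12)
      expect_lte(max(nz), 1 + 1e-12)
    }
  }
})

test_that("permuting the cohort permutes every adjacency consistently", {
  co <- generate_cohort(synthetic_spec(n = 20, seed = 10))
  ts <- build_topology_set(co)
  set.seed(11)
  perm <- sample(co$n)
  co2 <- perma_cohort(co$schema, co$features[perm, ], co$wellbeing[perm],
                      co$perma[perm, ], co$culture[perm],
                      co$learning_style[perm], co$stress_level[perm])
  ts2 <- build_topology_set(co2)
  for (k in names(ts)) {
    expect_lt(max(abs(ts2[[k]]$adjacency - ts[[k]]$adjacency[perm, perm])),
              1e-12)
  }
})

test_that("a threshold above 1 empties every graph", {
  co <- generate_cohort(synthetic_spec(n = 10, seed = 12))
  ts <- build_topology_set(co, threshold = 1 + 1e-9)
  for (g in ts) expect_equal(sum(g$adjacency), 0)
})

test_that("n = 2 identical students share a unit edge in all four graphs", {
  sch <- default_schema(8L)
  X <- matrix(rep(runif(8, 0.2, 0.8), each = 2), 2, 8)
  co <- perma_cohort(sch, X, c(0.5, 0.5),
                     matrix(0.5, 2, 5), c("a", "a"),
                     c("style_1", "style_1"), c("low", "low"))
  # identical students degenerate the distance kernel to the complete graph
  expect_message(ts <- build_topology_set(co), "complete graph")
  for (g in ts) expect_equal(g$adjacency[1, 2], 1, tolerance = 1e-12)
})

test_that("edge-list export is 0-based upper-triangular", {
  g <- build_style_graph(c("A", "A", "B", "A"))
  el <- topology_edge_list(g)
  expect_equal(el$i, c(0, 0, 1))
  expect_equal(el$j, c(1, 3, 3))
  expect_true(all(el$weight == 1))
})

test_that("MTX export round-trips the normalized adjacency", {
  skip_if_not_installed("Matrix")
  set.seed(13)
  g <- build_cosine_graph(matrix(runif(6 * 4), 6), 0.3)
  path <- tempfile(fileext = ".mtx")
  write_normalized_mtx(g, path)
  back <- as.matrix(Matrix::readMM(path))
  expect_lt(max(abs(back - normalize_adjacency(g))), 1e-6)
})
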