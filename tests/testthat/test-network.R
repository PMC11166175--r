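mk_group_z <- function(m, ids = seq_len(nrow(m))) {
  m <- (m + t(m)) / 2
  diag(m) <- 0
  connectivity_matrix(m, kind = "group_z", node_ids = ids)
}

test_that("thresholding keeps absolute values and zero elsewhere", {
  set.seed(10)
  n <- 8
  m <- matrix(rnorm(n * n, sd = 2), n, n)
  cm <- mk_group_z(m)
  gr <- threshold_graph(cm, z_cut = 2.3)
  # exhaustive oracle over every pair
  for (i in 1:n) for (j in 1:n) {
    expected <- if (i != j && abs(cm$mat[i, j]) >= 2.3) abs(cm$mat[i, j])
                else 0
    expect_identical(gr$adjacency[i, j], expected)
  }
  grb <- threshold_graph(cm, z_cut = 2.3, binarize = TRUE)
  expect_setequal(unique(as.vector(grb$adjacency)), c(0, 1))

  # all sub-threshold -> empty graph, all degrees 0
  weak <- mk_group_z(matrix(0.5, 3, 3))
  gw <- threshold_graph(weak, 2.3)
  expect_true(all(gw$adjacency == 0))
  expect_equal(degree_centrality(gw)$degree, setNames(rep(0L, 3), 1:3))

  # single negative edge retains its magnitude
  one <- matrix(0, 3, 3); one[1, 2] <- one[2, 1] <- -3.1
  g1 <- threshold_graph(mk_group_z(one), 2.3)
  expect_equal(g1$adjacency[1, 2], 3.1)
  expect_equal(threshold_graph(mk_group_z(one), 2.3,
                               binarize = TRUE)$adjacency[1, 2], 1)
})

test_that("degree centrality counts incident edges; handshake lemma holds", {
  # 5-node ring
  ring <- matrix(0, 5, 5)
  for (i in 1:5) {
    j <- i %% 5 + 1
    ring[i, j] <- ring[j, i] <- 3
  }
  gr <- network_graph(ring)
  expect_equal(unname(degree_centrality(gr)$degree), rep(2L, 5))

  # star with 4 leaves
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 2.5
  gs <- network_graph(star)
  expect_equal(unname(degree_centrality(gs)$degree), c(4L, 1L, 1L, 1L, 1L))
  expect_equal(unname(degree_centrality(gs)$strength),
               c(10, 2.5, 2.5, 2.5, 2.5))

  # random thresholded graph: degree equals a per-node edge tally, and
  # total degree = 2 x edge count
  set.seed(11)
  gr2 <- threshold_graph(mk_group_z(matrix(rnorm(100, sd = 2), 10, 10)), 2)
  deg <- degree_centrality(gr2)$degree
  for (i in 1:10) {
    expect_equal(unname(deg[i]), sum(gr2$adjacency[i, ] > 0))
  }
  expect_equal(sum(deg), 2 * sum(gr2$adjacency[upper.tri(gr2$adjacency)] > 0))
})

test_that("raising the threshold never increases any degree", {
  set.seed(12)
  cm <- mk_group_z(matrix(rnorm(144, sd = 2.5), 12, 12))
  cuts <- c(0.5, 1.5, 2.3, 3.5)
  degs <- sapply(cuts, function(z) {
    degree_centrality(threshold_graph(cm, z))$degree
  })
  for (k in 2:length(cuts)) expect_true(all(degs[, k] <= degs[, k - 1]))
})

test_that("mutual-kNN clustering separates planted blocks deterministically", {
  blockmat <- function(within, between, sizes) {
    n <- sum(sizes)
    lab <- rep(seq_along(sizes), sizes)
    m <- matrix(between, n, n)
    for (b in seq_along(sizes)) m[lab == b, lab == b] <- within
    diag(m) <- 1
    m
  }
  # two clean 5-node blocks at k = 3
  cm <- connectivity_matrix(blockmat(0.9, 0, c(5, 5)), kind = "pearson_r")
  cl <- knn_cluster(cm, k = 3)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(length(unique(cl[1:5])), 1L)
  expect_equal(length(unique(cl[6:10])), 1L)

  # identical rows -> a single cluster at any k
  cm1 <- connectivity_matrix(blockmat(0.4, 0.4, c(3, 3)), kind = "pearson_r")
  expect_equal(length(unique(knn_cluster(cm1, k = 2))), 1L)

  # n = 2, k = 1: mutually nearest -> one cluster
  cm2 <- connectivity_matrix(matrix(c(1, 0.2, 0.2, 1), 2),
                             kind = "pearson_r")
  expect_equal(length(unique(knn_cluster(cm2, k = 1))), 1L)

  expect_error(knn_cluster(cm2, k = 2), "k must satisfy")

  # determinism
  expect_identical(knn_cluster(cm, k = 3), knn_cluster(cm, k = 3))
})

test_that("planted 3-block partitions are recovered from sampled data", {
  rand_index <- function(a, b) {
    n <- length(a)
    agree <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
    agree / choose(n, 2)
  }
  C <- matrix(0.1, 18, 18)
  truth <- rep(1:3, each = 6)
  for (b in 1:3) C[truth == b, truth == b] <- 0.8
  diag(C) <- 1
  ris <- vapply(1:50, function(s) {
    set.seed(s)
    X <- t(chol(C)) %*% matrix(rnorm(18 * 200), 18, 200)
    cm <- connectivity(node_series(X, 1:18, 1))
    rand_index(knn_cluster(cm, k = 4), truth)
  }, numeric(1))
  expect_gte(mean(ris), 0.95)
})

test_that("subnetwork analysis counts cross edges and first neighbours", {
  # empty graph -> nothing anywhere
  empty <- network_graph(matrix(0, 6, 6), node_ids = 11:16)
  expect_equal(subnetwork_analysis(empty, 11:12, 13:14)$n_edges, 0L)
  fb <- subnetwork_analysis(empty, 11:12, union_nodes = 13:16)
  expect_equal(fb$n_connected, 0L)
  expect_equal(fb$fraction, 0)

  # hand-built graph: seeds {1,2}; node 5 wired to both seeds; 6 to seed 2
  A <- matrix(0, 6, 6)
  A[1, 5] <- A[5, 1] <- 3
  A[2, 5] <- A[5, 2] <- 2.5
  A[2, 6] <- A[6, 2] <- 2.4
  A[3, 4] <- A[4, 3] <- 4     # unrelated edge
  gr <- network_graph(A)
  ss <- subnetwork_analysis(gr, c(1, 2), c(5, 6))
  expect_equal(ss$n_edges, 3L)
  # set semantics: node 5 listed once although wired to both seeds
  fn <- subnetwork_analysis(gr, c(1, 2), union_nodes = c(4, 5, 6))
  expect_setequal(fn$neighbours, c(5, 6))
  expect_equal(fn$n_connected, 2L)
  expect_equal(fn$fraction, 2 / 3)

  expect_error(subnetwork_analysis(gr, c(1, 99)), "unknown seed")
  expect_error(subnetwork_analysis(gr, 1:2, 2:3), "disjoint")
})

test_that("compare_degree picks the documented branch and p-values", {
  # identical vectors -> degenerate, p = 1
  r0 <- compare_degree(rep(3, 10), rep(3, 10))
  expect_equal(r0$branch, "degenerate")
  expect_equal(r0$p_value, 1)

  # constant shift + small Gaussian jitter: paired t branch, significant
  set.seed(14)
  a <- rnorm(20, 10, 1)
  b <- a + 5 + rnorm(20, 0, 0.5)
  rt <- compare_degree(a, b)
  expect_equal(rt$branch, "paired_t")
  expect_lt(rt$p_value, 0.05)
  ref <- t.test(b, a, paired = TRUE)
  expect_equal(rt$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(rt$statistic, unname(ref$statistic), tolerance = 1e-12)

  # heavy-tailed differences: normality rejected -> Wilcoxon
  set.seed(15)
  d <- rcauchy(25, scale = 4)
  rw <- compare_degree(rep(0, 25), d)
  expect_equal(rw$branch, "wilcoxon")
  expect_lt(rw$shapiro_p, 0.05)
})
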