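#' Threshold a group Z matrix into an undirected network
#'
#' Applies the fixed score threshold used to prune spurious or weak
#' connections: edge weight `A_ij = |Z_ij|` wherever `|Z_ij| >= z_cut`, else
#' 0 (negative couplings are retained through their absolute value, as in
#' undirected network analyses of connectivity matrices). With
#' `binarize = TRUE` surviving edges get weight 1. Diagonal is forced to 0.
#'
#' @param cm A `connectivity_matrix` (typically kind "group_z").
#' @param z_cut Threshold on |Z| (default 2.3).
#' @param binarize Replace surviving weights by 1.
#' @return A `network_graph`: `adjacency` (symmetric, zero diagonal),
#'   `binarized` flag, `degree` (per-node incident-edge counts) and
#'   `node_ids`.
#' @export
threshold_graph <- function(cm, z_cut = 2.3, binarize = FALSE) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  assert_that(z_cut >= 0, "z_cut must be non-negative")
  A <- abs(cm$mat)
  A[is.na(A)] <- 0
  A[A < z_cut] <- 0
  if (binarize) A[A > 0] <- 1
  diag(A) <- 0
  network_graph(A, binarized = binarize, node_ids = cm$node_ids)
}

#' Undirected network container
#'
#' @param adjacency Symmetric non-negative matrix with zero diagonal.
#' @param binarized Whether weights are 0/1.
#' @param node_ids Region ids for the nodes.
#' @return A `network_graph` with the binarized degree vector precomputed.
#' @export
network_graph <- function(adjacency, binarized = FALSE,
                          node_ids = seq_len(nrow(adjacency))) {
  assert_that(is.matrix(adjacency) && nrow(adjacency) == ncol(adjacency),
              "adjacency must be square")
  assert_that(max(abs(adjacency - t(adjacency))) < 1e-12,
              "adjacency must be symmetric")
  assert_that(all(adjacency >= 0), "adjacency must be non-negative")
  assert_that(all(diag(adjacency) == 0), "diagonal must be zero")
  structure(list(adjacency = adjacency, binarized = binarized,
                 node_ids = as.integer(node_ids),
                 degree = as.integer(rowSums(adjacency > 0))),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("Undirected network: %d nodes, %d edges%s\n",
              nrow(x$adjacency), sum(x$adjacency > 0) / 2,
              if (x$binarized) " (binarized)" else ""))
  invisible(x)
}

#' Degree centrality
#'
#' The number of edges incident to each node, `C_D(j) = sum_i A_ij` on the
#' binarized adjacency — the "number of connections" semantics of
#' thresholded connectivity networks. The weighted row sum (strength, sum of
#' surviving |Z|) is returned as a secondary output.
#'
#' @param graph A [network_graph()].
#' @return List with `degree` (integer, named by node id) and `strength`
#'   (numeric row sums of the weighted adjacency).
#' @export
degree_centrality <- function(graph) {
  stopifnot(inherits(graph, "network_graph"))
  deg <- as.integer(rowSums(graph$adjacency > 0))
  list(degree = stats::setNames(deg, graph$node_ids),
       strength = stats::setNames(rowSums(graph$adjacency), graph$node_ids))
}

#' Mutual k-nearest-neighbour clustering of network nodes
#'
#' Deterministic clustering of nodes by the similarity of their connectivity
#' profiles: each node's matrix row (diagonal zeroed) is its feature vector;
#' cosine similarity ranks neighbours; an undirected graph keeps an edge
#' only where both endpoints list each other among their `k` nearest; the
#' clusters are that graph's connected components.
#'
#' @param cm A `connectivity_matrix`.
#' @param k Neighbour count, `1 <= k < n` (default `ceiling(sqrt(n))`).
#' @return Integer cluster labels (1-based), named by node id.
#' @export
knn_cluster <- function(cm, k = NULL) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  n <- cm$n_nodes
  k <- as.integer(k %||% ceiling(sqrt(n)))
  assert_that(k >= 1 && k < n, "k must satisfy 1 <= k < n (got k=%d, n=%d)",
              k, n)
  X <- cm$mat
  diag(X) <- 0
  X[is.na(X)] <- 0
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  S <- (X / nrm) %*% t(X / nrm)
  diag(S) <- -Inf
  # neighbour set = everything at or above the k-th largest similarity
  # (ties included), so the result is deterministic and tie-stable
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    thr <- sort(S[i, ], decreasing = TRUE)[k]
    A[i, S[i, ] >= thr - 1e-12] <- TRUE
  }
  diag(A) <- FALSE
  M <- A & t(A)
  g <- igraph::graph_from_adjacency_matrix(M, mode = "undirected")
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp), cm$node_ids)
}

#' Subnetwork edge counts and first-neighbour sets
#'
#' Two modes matching the published subnetwork figures: with two disjoint
#' node sets (e.g. thalamic nuclei vs sensory cortices), counts the edges
#' with one endpoint in each set; with `partner_nodes = "first_neighbours"`,
#' returns every node with at least one edge to a seed node (set semantics:
#' a partner wired to several seeds is listed once) and, when `union_nodes`
#' is supplied, the fraction of that list connected to the seeds (the
#' "33/39 nodes" style summary).
#'
#' @param graph A [network_graph()].
#' @param seed_nodes Region ids of the seed set.
#' @param partner_nodes Region ids of the partner set, or the string
#'   "first_neighbours".
#' @param union_nodes Optional region id list the neighbour fraction is
#'   reported over.
#' @return For set-to-set mode: list with `mode`, `edges` (data frame from,
#'   to, weight) and `n_edges`. For first-neighbour mode: list with `mode`,
#'   `neighbours` (region ids), `n_neighbours`, and when `union_nodes` is
#'   given `fraction` plus its numerator/denominator.
#' @export
subnetwork_analysis <- function(graph, seed_nodes,
                                partner_nodes = "first_neighbours",
                                union_nodes = NULL) {
  stopifnot(inherits(graph, "network_graph"))
  ids <- graph$node_ids
  bad <- setdiff(seed_nodes, ids)
  assert_that(length(bad) == 0, "unknown seed regions: %s",
              paste(bad, collapse = ", "))
  si <- match(seed_nodes, ids)
  A <- graph$adjacency
  if (identical(partner_nodes, "first_neighbours")) {
    nb <- which(colSums(A[si, , drop = FALSE] > 0) > 0)
    nb <- setdiff(nb, si)
    neighbours <- ids[nb]
    out <- list(mode = "first_neighbours", neighbours = neighbours,
                n_neighbours = length(neighbours))
    if (!is.null(union_nodes)) {
      bad <- setdiff(union_nodes, ids)
      assert_that(length(bad) == 0, "unknown union regions: %s",
                  paste(bad, collapse = ", "))
      hit <- intersect(neighbours, union_nodes)
      out$n_connected <- length(hit)
      out$n_union <- length(union_nodes)
      out$fraction <- length(hit) / length(union_nodes)
      out$connected <- hit
    }
    return(out)
  }
  bad <- setdiff(partner_nodes, ids)
  assert_that(length(bad) == 0, "unknown partner regions: %s",
              paste(bad, collapse = ", "))
  assert_that(length(intersect(seed_nodes, partner_nodes)) == 0,
              "seed and partner sets must be disjoint")
  pi_ <- match(partner_nodes, ids)
  sub <- A[si, pi_, drop = FALSE]
  ij <- which(sub > 0, arr.ind = TRUE)
  edges <- data.frame(from = ids[si][ij[, 1]], to = ids[pi_][ij[, 2]],
                      weight = sub[ij])
  list(mode = "set_to_set", edges = edges, n_edges = nrow(edges))
}

#' Compare paired degree-centrality vectors between two conditions
#'
#' The parametric-or-nonparametric branch used for regional degree
#' comparisons: a Shapiro-Wilk test on the paired differences gates the
#' choice — normality not rejected (p > 0.05) leads to a paired t-test,
#' otherwise a Wilcoxon signed-rank test (exact for n <= 25 after dropping
#' zero differences, normal approximation with continuity correction
#' beyond). Regions are matched across conditions (pairing is by region:
#' the groups are independent animals, so subject-wise pairing is not
#' available).
#'
#' @param values_a,values_b Equal-length degree vectors paired by region.
#' @param alpha Significance level recorded in the report.
#' @return List with `branch` ("paired_t", "wilcoxon" or "degenerate"),
#'   `statistic`, `p_value`, `shapiro_p`, `n`, `alpha`, `significant`.
#' @export
compare_degree <- function(values_a, values_b, alpha = 0.05) {
  assert_that(length(values_a) == length(values_b),
              "degree vectors must be paired (equal length)")
  d <- values_b - values_a
  n <- length(d)
  if (all(d == 0)) {
    return(list(branch = "degenerate", statistic = NA_real_, p_value = 1,
                shapiro_p = NA_real_, n = n, alpha = alpha,
                significant = FALSE))
  }
  sw <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) 0)
  if (sw > 0.05) {
    ht <- stats::t.test(values_b, values_a, paired = TRUE)
    branch <- "paired_t"
  } else {
    nz <- d[d != 0]
    ht <- suppressWarnings(stats::wilcox.test(
      values_b, values_a, paired = TRUE,
      exact = length(nz) <= 25, correct = TRUE))
    branch <- "wilcoxon"
  }
  list(branch = branch, statistic = unname(ht$statistic),
       p_value = ht$p.value, shapiro_p = sw, n = n, alpha = alpha,
       significant = ht$p.value < alpha)
}
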