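# Growing-neural-gas graph: nearest-node search, update arithmetic, the
# node/edge lifecycle, component labelling and stream clustering.

make_graph <- function(positions, max_nodes = 32, ...) {
  positions <- as.matrix(positions)
  g <- gng_new(gng_params(max_nodes = max_nodes, ...), ncol(positions))
  for (i in seq_len(nrow(positions))) {
    gemsort:::.gng_add_node(g, positions[i, ])
  }
  g
}

test_that("gng_nearest_two matches an exhaustive-scan oracle", {
  set.seed(30)
  pos <- matrix(runif(50 * 3, 0, 10), ncol = 3)
  g <- make_graph(pos, max_nodes = 64)
  for (q in 1:100) {
    x <- runif(3, 0, 10)
    d <- sqrt(colSums((t(pos) - x)^2))
    o <- order(d)  # node ids equal insertion order here
    nn <- gng_nearest_two(g, x)
    expect_equal(nn$w1, o[1])
    expect_equal(nn$w2, o[2])
    expect_equal(nn$d1, d[o[1]], tolerance = 1e-12)
    expect_equal(nn$d2, d[o[2]], tolerance = 1e-12)
  }
  expect_error(gng_nearest_two(make_graph(matrix(0, 1, 3)), c(0, 0, 0)),
               "two live nodes")
})

test_that("nearest-node search on a query exactly on a node gives d1 = 0", {
  g <- make_graph(rbind(c(0, 0), c(10, 0)))
  nn <- gng_nearest_two(g, c(10, 0))
  expect_equal(nn$d1, 0)
  expect_equal(nn$w1, 2L)
})

test_that("winner and neighbour updates use the configured movement rates", {
  g <- gng_new(gng_params(max_nodes = 8), 1)
  gng_adapt(g, 0)    # init node 1
  gng_adapt(g, 0.5)  # init node 2
  gng_adapt(g, 1)    # winner = node at 0.5 -> moves by 0.8 of the gap
  expect_equal(g$pos[2, 1], 0.5 + 0.8 * (1 - 0.5), tolerance = 1e-12)
  expect_equal(g$pos[1, 1], 0, tolerance = 1e-12)  # no edge yet, no move
  gng_adapt(g, 1)    # now node 1 is an edge-neighbour of the winner
  expect_equal(g$pos[2, 1], 0.9 + 0.8 * (1 - 0.9), tolerance = 1e-12)
  expect_equal(g$pos[1, 1], 0 + 0.001 * (1 - 0), tolerance = 1e-12)
})

test_that("winner update is an exact contraction toward the spike", {
  set.seed(31)
  g <- make_graph(matrix(c(0, 0, 5, 5), 2, byrow = TRUE), max_nodes = 4)
  g$scale <- 10  # wide scale so the update path is taken
  x <- c(1, 1)
  before <- g$pos[1, ]
  gng_adapt(g, x)
  after <- g$pos[1, ]
  expect_equal(sqrt(sum((after - x)^2)),
               (1 - 0.8) * sqrt(sum((before - x)^2)), tolerance = 1e-12)
})

test_that("gng_components matches an igraph reachability oracle", {
  skip_if_not_installed("igraph")
  set.seed(32)
  canon <- function(lab) match(lab, unique(lab))
  for (trial in 1:60) {
    n <- sample(3:30, 1)
    g <- make_graph(matrix(runif(n * 2), ncol = 2), max_nodes = 40)
    adj <- matrix(FALSE, n, n)
    n_edges <- sample(0:(2 * n), 1)
    for (e in seq_len(n_edges)) {
      ij <- sample(n, 2)
      adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- TRUE
      g$age[ij[1], ij[2]] <- g$age[ij[2], ij[1]] <- 0L
    }
    g$comp_dirty <- TRUE
    got <- gng_components(g)
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    want <- igraph::components(ig)$membership
    expect_equal(canon(unname(got)), canon(unname(want)))
  }
})

test_that("component identities are stable across repeated calls", {
  g <- make_graph(matrix(runif(12 * 2), ncol = 2), max_nodes = 16)
  for (i in 1:5) g$age[i, i + 1] <- g$age[i + 1, i] <- 0L
  g$comp_dirty <- TRUE
  first <- gng_components(g)
  again <- gng_components(g)
  expect_identical(first, again)
  g$comp_dirty <- TRUE
  expect_identical(gng_components(g), first)
})

test_that("two well-separated blobs are sorted with high purity", {
  s <- blob_stream(500, rbind(c(0, 0), c(10, 0)), sd = 0.3, seed = 33)
  res <- sort_stream(s$X, gng_params(max_nodes = 16))
  expect_gt(label_accuracy(res$records$cluster_id, s$id), 0.95)
})

test_that("an eight-blob stream reaches high purity after warm-up", {
  s <- blob_stream(3000, cbind(seq(0, 28, 4), 0, 0), sd = 0.3, seed = 34)
  res <- sort_stream(s$X, gng_params(max_nodes = 48))
  late <- 1001:3000
  expect_gt(label_accuracy(res$records$cluster_id[late], s$id[late]), 0.90)
})

test_that("node count never exceeds the budget", {
  s <- blob_stream(800, rbind(c(0, 0), c(6, 0), c(0, 6)), sd = 0.4, seed = 35)
  res <- sort_stream(s$X, gng_params(max_nodes = 12))
  g <- res$graph
  expect_lte(sum(g$alive), 12)
  expect_lte(nrow(g$pos), 12)  # state size fixed by the budget
  expect_gte(sum(g$alive), 1)
})

test_that("sort_stream is deterministic and handles an empty stream", {
  s <- blob_stream(300, rbind(c(0, 0), c(8, 0)), sd = 0.3, seed = 36)
  r1 <- sort_stream(s$X, gng_params(max_nodes = 16))
  r2 <- sort_stream(s$X, gng_params(max_nodes = 16))
  expect_identical(r1$records, r2$records)
  r0 <- sort_stream(matrix(numeric(0), ncol = 3), gng_params(max_nodes = 8))
  expect_equal(nrow(r0$records), 0)
})

test_that("cluster ids are dense integers in order of first appearance", {
  s <- blob_stream(400, rbind(c(0, 0), c(9, 0)), sd = 0.3, seed = 37)
  res <- sort_stream(s$X, gng_params(max_nodes = 16))
  ids <- res$records$cluster_id
  expect_equal(sort(unique(ids)), seq_along(unique(ids)))
  expect_equal(ids[1], 1L)
})

test_that("clusters re-form after a mid-stream translation of all centers", {
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8))
  pre <- blob_stream(900, centers, sd = 0.35, seed = 38)
  post <- blob_stream(1500, centers + 30, sd = 0.35, seed = 39)
  X <- rbind(pre$X, post$X)
  id <- c(pre$id, post$id)
  res <- sort_stream(X, gng_params(max_nodes = 24))
  cl <- res$records$cluster_id
  pre_idx <- 301:900           # pre-shift, after warm-up
  rec_idx <- (900 + 601):2400  # post-shift, after 5x warm-up allowance
  acc_pre <- label_accuracy(cl[pre_idx], id[pre_idx])
  acc_rec <- label_accuracy(cl[rec_idx], id[rec_idx])
  expect_gt(acc_pre, 0.8)
  expect_gt(acc_rec, acc_pre - 0.05)
})
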