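# Assignment solver, ground-truth scoring, sorter agreement and
# autocorrelograms.

test_that("solve_assignment matches brute-force enumeration", {
  set.seed(40)
  # all ordered selections of n columns out of `cols`
  ordered_selections <- function(cols, n) {
    if (n == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
    out <- NULL
    for (i in seq_along(cols)) {
      sub <- ordered_selections(cols[-i], n - 1)
      out <- rbind(out, cbind(cols[i], sub))
    }
    out
  }
  brute <- function(score) {
    n <- nrow(score); m <- ncol(score)
    stopifnot(n <= m)
    sel <- ordered_selections(seq_len(m), n)
    vals <- apply(sel, 1, function(p) sum(score[cbind(seq_len(n), p)]))
    list(value = max(vals), assign = sel[which.max(vals), ])
  }
  for (trial in 1:20) {
    n <- sample(2:4, 1); m <- sample(n:5, 1)
    score <- matrix(sample(0:20, n * m, replace = TRUE), n, m)
    a <- solve_assignment(score)
    got <- sum(score[cbind(which(a > 0), a[a > 0])])
    expect_equal(got, brute(score)$value)
  }
  # hand case from a 3-cluster confusion table
  conf <- matrix(c(9, 1, 0,
                   0, 8, 2,
                   1, 0, 7), 3, 3, byrow = TRUE)
  a <- solve_assignment(conf)
  expect_equal(a, c(1L, 2L, 3L))
})

test_that("solve_assignment handles surplus rows (more clusters than neurons)", {
  score <- matrix(c(10, 0,
                    0, 10,
                    5, 5), 3, 2, byrow = TRUE)
  a <- solve_assignment(score)
  expect_equal(a[1:2], c(1L, 2L))
  expect_equal(a[3], 0L)  # surplus cluster left unassigned
})

make_result <- function(peak_sample, cluster_id, channel = 0L) {
  structure(list(records = data.frame(peak_sample = peak_sample,
                                      cluster_id = cluster_id,
                                      channel = channel)),
            class = "sort_result")
}

make_truth <- function(neuron_id, spike_sample, home_channel = 0L) {
  structure(list(events = data.frame(
    neuron_id = neuron_id, spike_sample = spike_sample,
    home_channel = rep(home_channel, length.out = length(neuron_id)))),
    class = "ground_truth")
}

test_that("a perfect sorter scores accuracy 1 with per-neuron 1", {
  t <- sort(sample(1e5, 300))
  id <- rep(1:3, each = 100)
  truth <- make_truth(id, t)
  res <- make_result(t, id)
  m <- match_to_ground_truth(res, truth)
  expect_equal(m$accuracy, 1)
  expect_equal(unname(m$per_neuron), rep(1, 3))
  expect_equal(m$n_matched, 300)
})

test_that("random labels over 8 clusters score about 1/8", {
  set.seed(41)
  t <- sort(sample(1e6, 4000))
  truth <- make_truth(sample(1:8, 4000, replace = TRUE), t)
  res <- make_result(t, sample(1:8, 4000, replace = TRUE))
  m <- match_to_ground_truth(res, truth)
  expect_lt(abs(m$accuracy - 1 / 8), 0.03)
})

test_that("accuracy is invariant under cluster-id permutation", {
  set.seed(42)
  t <- sort(sample(1e5, 500))
  id <- sample(1:4, 500, replace = TRUE)
  cl <- sample(1:5, 500, replace = TRUE)
  truth <- make_truth(id, t)
  m1 <- match_to_ground_truth(make_result(t, cl), truth)
  perm <- sample(5)
  m2 <- match_to_ground_truth(make_result(t, perm[cl]), truth)
  expect_equal(m1$accuracy, m2$accuracy)
  expect_true(m1$accuracy >= 0 && m1$accuracy <= 1)
})

test_that("missed detections count against the headline accuracy", {
  t <- seq(1000, 100000, by = 1000)
  truth <- make_truth(rep(1L, length(t)), t)
  res <- make_result(t[1:50], rep(1L, 50))  # half the spikes missing
  m <- match_to_ground_truth(res, truth)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$accuracy_detected, 1)
  expect_error(match_to_ground_truth(res, make_truth(integer(0), integer(0))),
               "empty")
})

test_that("pairing respects the time tolerance", {
  truth <- make_truth(c(1L, 1L), c(1000L, 2000L))
  res <- make_result(c(1014L, 2016L), c(1L, 1L))
  m <- match_to_ground_truth(res, truth, time_tol_samples = 15)
  expect_equal(m$n_matched, 1L)  # only the first is within tolerance
})

test_that("agreement of a result with itself is 100% and diagonal", {
  set.seed(43)
  t <- sort(sample(1e5, 400))
  cl <- sample(1:4, 400, replace = TRUE)
  res <- make_result(t, cl)
  ag <- agreement_matrix(res, res)
  expect_equal(ag$agreement, 100)
  off <- ag$matrix; diag(off) <- 0
  expect_true(all(off == 0))
  expect_true(all(ag$unmatched_a == 0))
})

test_that("shifting all spikes beyond tolerance destroys the agreement", {
  t <- seq(1000, by = 1000, length.out = 200)
  res_a <- make_result(t, rep(1L, 200))
  res_b <- make_result(t + 100, rep(1L, 200))
  ag <- agreement_matrix(res_a, res_b, time_tol_samples = 15)
  expect_equal(sum(ag$matrix), 0)
  expect_equal(ag$agreement, 0)
  expect_equal(sum(ag$unmatched_a), 200)
})

test_that("agreement matrix matches a hand-counted coincidence case", {
  # A: cluster 1 at 100,200,300; cluster 2 at 1000,1100
  # B: cluster 1 at 102,199;     cluster 2 at 1003,1104,5000
  res_a <- make_result(c(100, 200, 300, 1000, 1100), c(1, 1, 1, 2, 2))
  res_b <- make_result(c(102, 199, 1003, 1104, 5000), c(1, 1, 2, 2, 2))
  ag <- agreement_matrix(res_a, res_b, time_tol_samples = 15)
  expect_equal(unname(ag$matrix["1", "1"]), 2)
  expect_equal(unname(ag$matrix["2", "2"]), 2)
  expect_equal(sum(ag$matrix), 4)
  expect_equal(unname(ag$unmatched_a["1"]), 1)  # A's spike at 300
  expect_equal(unname(ag$unmatched_b["2"]), 1)  # B's spike at 5000
  expect_equal(ag$agreement, 100 * 4 / 5)
})

test_that("autocorrelogram is symmetric with the expected structure", {
  # single spike: all-zero histogram
  a <- autocorrelogram(0.5, bin_ms = 1, window_ms = 20)
  expect_true(all(a$count == 0))
  # regular 10 ms train: peaks only at multiples of 10 ms
  t <- seq(0, 1, by = 0.01)
  a <- autocorrelogram(t, bin_ms = 1, window_ms = 35)
  hot <- a$lag_ms[a$count > 0]
  expect_true(all(abs(hot %% 10) <= 0.5 | abs(hot %% 10 - 10) <= 0.5))
  expect_equal(a$count, rev(a$count))  # symmetry
  # refractory train: empty centre
  tr <- poisson_spike_train(50, 30, refractory_s = 0.002, seed = 44) / 30000
  a <- autocorrelogram(tr, bin_ms = 0.5, window_ms = 10)
  expect_true(all(a$count[abs(a$lag_ms) < 2] == 0))
  expect_gt(sum(a$count), 0)
})
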