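# Optimal one-to-one assignment (Hungarian algorithm, potentials /
# shortest-augmenting-path form, O(n^2 m)). Used to map sorter clusters to
# ground-truth neurons (or to another sorter's clusters) so that the total
# number of matched spikes is maximised.

# Minimum-cost assignment of rows to columns; requires nrow <= ncol.
# Returns the assigned column for each row.
.hungarian_min <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)    # p[j+1]: row matched to column j (0 = free); j = 0 virtual
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0
      free_j <- which(!used[-1])  # columns 1..m not yet in the tree
      if (length(free_j)) {
        cur <- cost[i0, free_j] - u[i0 + 1] - v[free_j + 1]
        upd <- cur < minv[free_j + 1]
        minv[free_j + 1][upd] <- cur[upd]
        way[free_j + 1][upd] <- j0
        k <- which.min(minv[free_j + 1])
        delta <- minv[free_j + 1][k]
        j1 <- free_j[k]
      }
      iu <- which(used)
      u[p[iu] + 1] <- u[p[iu] + 1] + delta
      v[iu] <- v[iu] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign_col <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assign_col[p[j + 1]] <- j
  assign_col
}

#' Optimal one-to-one assignment maximising a score matrix
#'
#' Solves the rectangular assignment problem: selects at most
#' `min(nrow, ncol)` cell positions, no two sharing a row or column, with
#' maximum total score. Surplus rows (or columns) stay unassigned.
#'
#' @param score numeric matrix (e.g. cluster-by-neuron matched-spike
#'   counts).
#' @return integer vector of length `nrow(score)`: assigned column per row,
#'   0 for unassigned rows.
#' @export
solve_assignment <- function(score) {
  score <- as.matrix(score)
  n <- nrow(score); m <- ncol(score)
  if (n == 0 || m == 0) return(integer(n))
  transposed <- n > m
  if (transposed) score <- t(score)
  cost <- max(score) - score
  a <- .hungarian_min(cost)
  if (transposed) {
    out <- integer(n)  # a[r]: original row assigned to original column r
    for (r in seq_along(a)) out[a[r]] <- r
    a <- out
  }
  a
}
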