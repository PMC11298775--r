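# Streaming growing-neural-gas clustering. Nodes carry positions in feature
# space; edges carry integer ages. Each incoming spike moves the nearest
# node (and, more gently, its graph neighbours) toward itself, refreshes the
# edge between the two nearest nodes, ages and prunes stale edges, and is
# classified to the connected component of the nearest node. Node insertion
# follows the canonical growing-neural-gas rule: periodically split the
# highest-error region. Memory use is bounded by the node budget; past
# spikes are never retained.

#' Growing-neural-gas parameters
#'
#' @param max_nodes node budget N. `NULL` means "choose at sort time" as
#'   `nodes_per_channel` times the number of active channels in the stream.
#' @param edge_prune_age edges older than this (in adaptation steps since
#'   last refresh) are deleted; nodes left edgeless are removed.
#' @param n_init number of initial nodes (placed at the first distinct
#'   feature vectors).
#' @param e_s1 movement rate of the nearest node toward each spike.
#' @param e_nbr movement rate of the nearest node's graph neighbours
#'   (must satisfy `0 < e_nbr < e_s1 < 1`).
#' @param alpha error reduction factor applied to the split node and its
#'   worst neighbour at insertion.
#' @param beta error decay rate applied to all nodes at each insertion
#'   cycle (errors are multiplied by `1 - beta`).
#' @param lambda number of adaptation steps between node insertions.
#' @param nodes_per_channel used to derive `max_nodes` when it is `NULL`.
#' @param novelty_theta a spike farther than `novelty_theta` times the
#'   running winner-distance scale from every node spawns a new node at its
#'   own position (budget permitting) instead of dragging the nearest node
#'   across the gap; this is what lets well-separated clusters form without
#'   stranding nodes between them.
#' @param edge_gate_kappa the winner-runner edge is only created/refreshed
#'   when the runner-up distance is within `edge_gate_kappa` times the
#'   running scale, so nodes of distinct distant clusters are never linked.
#' @param utility_max_idle nodes that have not won for this many adaptation
#'   steps are removed at the next insertion cycle (outlier and stale-drift
#'   cleanup); `Inf` disables.
#' @return An object of class `gng_params`.
#' @export
gng_params <- function(max_nodes = NULL, edge_prune_age = 8, n_init = 2,
                       e_s1 = 0.8, e_nbr = 0.001, alpha = 0.5, beta = 0.01,
                       lambda = 10, nodes_per_channel = 6,
                       novelty_theta = 4, edge_gate_kappa = 6,
                       utility_max_idle = 500) {
  if (!(0 < e_nbr && e_nbr < e_s1 && e_s1 < 1))
    stop("need 0 < e_nbr < e_s1 < 1")
  if (lambda < 1) stop("lambda must be >= 1")
  if (!is.null(max_nodes) && max_nodes < n_init)
    stop("max_nodes must be >= n_init")
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    stop("alpha and beta must be in (0, 1)")
  if (novelty_theta <= 1 || edge_gate_kappa <= 1)
    stop("novelty_theta and edge_gate_kappa must be > 1")
  structure(list(max_nodes = max_nodes, edge_prune_age = edge_prune_age,
                 n_init = as.integer(n_init), e_s1 = e_s1, e_nbr = e_nbr,
                 alpha = alpha, beta = beta, lambda = as.integer(lambda),
                 nodes_per_channel = nodes_per_channel,
                 novelty_theta = novelty_theta,
                 edge_gate_kappa = edge_gate_kappa,
                 utility_max_idle = utility_max_idle),
            class = "gng_params")
}

#' Create an empty growing-neural-gas graph
#'
#' @param params a [gng_params()] with a concrete `max_nodes`.
#' @param dim feature-space dimension.
#' @return A mutable graph object (environment) of class `gng`.
#' @export
gng_new <- function(params, dim) {
  stopifnot(inherits(params, "gng_params"))
  if (is.null(params$max_nodes))
    stop("max_nodes must be set (sort_stream derives it from the stream)")
  N <- as.integer(params$max_nodes)
  g <- new.env(parent = emptyenv())
  g$params <- params
  g$dim <- as.integer(dim)
  g$pos <- matrix(NA_real_, nrow = N, ncol = dim)
  g$alive <- rep(FALSE, N)
  g$err <- numeric(N)
  g$birth <- rep(NA_integer_, N)
  g$birth_counter <- 0L
  g$age <- matrix(-1L, nrow = N, ncol = N)  # -1 = no edge
  g$step <- 0L
  g$comp <- rep(NA_integer_, N)
  g$comp_dirty <- TRUE
  g$node_label <- rep(NA_integer_, N)  # persistent cluster identity per node
  g$label_counter <- 0L
  g$last_win <- rep(0L, N)
  g$scale <- NA_real_  # running winner-distance scale
  # pending novelty seeds: a far-from-everything spike is only turned into
  # a node once a second far spike confirms the region (outlier buffering)
  g$pend_pos <- matrix(NA_real_, nrow = 32, ncol = dim)
  g$pend_step <- rep(NA_integer_, 32)
  g$label_mismatch <- rep(0L, N)  # reconciliations spent under another label
  class(g) <- "gng"
  g
}

#' @export
print.gng <- function(x, ...) {
  n_edges <- sum(x$age[upper.tri(x$age)] >= 0L)
  comp <- gng_components(x)
  cat(sprintf("gng graph: %d/%d nodes, %d edges, %d components, step %d\n",
              sum(x$alive), nrow(x$pos), n_edges,
              length(unique(comp)), x$step))
  invisible(x)
}

.gng_add_node <- function(g, x, error = 0, label = NA_integer_) {
  slot <- which(!g$alive)[1]
  if (is.na(slot)) stop("node budget exhausted")
  g$alive[slot] <- TRUE
  g$pos[slot, ] <- x
  g$err[slot] <- error
  g$birth_counter <- g$birth_counter + 1L
  g$birth[slot] <- g$birth_counter
  if (is.na(label)) label <- .gng_fresh_label(g)
  g$node_label[slot] <- label
  g$last_win[slot] <- g$step
  g$comp_dirty <- TRUE
  slot
}

.gng_fresh_label <- function(g) {
  g$label_counter <- g$label_counter + 1L
  g$label_counter
}

.gng_kill_node <- function(g, slot) {
  g$alive[slot] <- FALSE
  g$pos[slot, ] <- NA_real_
  g$err[slot] <- 0
  g$age[slot, ] <- -1L
  g$age[, slot] <- -1L
  g$comp_dirty <- TRUE
}

#' Two nearest nodes to a query point
#'
#' Euclidean nearest and second-nearest live nodes; ties are broken by the
#' lower node id (insertion order).
#'
#' @param graph a `gng` graph with at least two live nodes.
#' @param x query feature vector.
#' @return list with `w1`, `w2` (slot indices), `d1`, `d2` (distances,
#'   `d1 <= d2`).
#' @export
gng_nearest_two <- function(graph, x) {
  live <- which(graph$alive)
  if (length(live) < 2) stop("need at least two live nodes")
  dif <- graph$pos[live, , drop = FALSE] -
    matrix(x, nrow = length(live), ncol = graph$dim, byrow = TRUE)
  d2 <- rowSums(dif * dif)
  o <- order(d2, graph$birth[live])
  list(w1 = live[o[1]], w2 = live[o[2]],
       d1 = sqrt(d2[o[1]]), d2 = sqrt(d2[o[2]]))
}

#' Connected components of the graph, with persistent cluster identities
#'
#' Computes the connected components of the node/edge graph over live nodes
#' and reconciles them with the persistent cluster identities carried by
#' the nodes: each component inherits the identity held by the plurality of
#' its members (ties broken toward the oldest member's identity). When a
#' component splits, the fragment with more nodes (ties: the one containing
#' the older node) keeps the identity and the separated fragment receives a
#' fresh one; when components merge, the plurality identity absorbs the
#' others. Cluster labels are therefore stable under node insertion,
#' deletion and transient edge turnover.
#'
#' @param graph a `gng` graph.
#' @return named integer vector: for each live node slot (names), the
#'   cluster identity of its component.
#' @export
gng_components <- function(graph) {
  live <- which(graph$alive)
  if (!graph$comp_dirty) {
    out <- graph$comp[live]
    names(out) <- live
    return(out)
  }
  # enumerate components (BFS over the age matrix)
  comp_idx <- rep(NA_integer_, length(graph$alive))
  members <- list()
  for (s in live[order(graph$birth[live])]) {
    if (!is.na(comp_idx[s])) next
    k <- length(members) + 1L
    queue <- s
    comp_idx[s] <- k
    got <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(graph$age[v, ] >= 0L)
      nb <- nb[is.na(comp_idx[nb])]
      if (length(nb)) {
        comp_idx[nb] <- k
        got <- c(got, nb)
        queue <- c(queue, nb)
      }
    }
    members[[k]] <- got
  }
  # reconcile persistent identities: a label goes to the strongest claimant
  n_comp <- length(members)
  assigned <- rep(NA_integer_, n_comp)
  claims <- lapply(members, function(m) graph$node_label[m])
  all_labels <- unique(unlist(claims))
  for (lab in all_labels) {
    votes <- vapply(claims, function(cl) sum(cl == lab), integer(1))
    cand <- which(votes > 0 & is.na(assigned))
    if (!length(cand)) next
    # strongest claim: among claimants with substantial support (at least
    # a quarter of the largest claimant's votes, so a tiny splinter cannot
    # walk away with a cluster's identity), the component holding the
    # label's oldest carrier node wins -- a long-lived anchor keeps its
    # cluster's identity through splits
    oldest <- vapply(cand, function(k)
      min(graph$birth[members[[k]][claims[[k]] == lab]]), integer(1))
    best <- cand[order(oldest, -votes[cand])][1]
    assigned[best] <- lab
  }
  for (k in seq_len(n_comp)) {
    fresh <- is.na(assigned[k])
    if (fresh) assigned[k] <- .gng_fresh_label(graph)
    graph$comp[members[[k]]] <- assigned[k]
    # A freshly separated fragment takes on its new identity. In a merged
    # component the members keep their own identities at first, so that
    # when a transient bridge between two clusters is pruned again both
    # sides recover their previous identity; but members that stay under
    # another component's label for many reconciliations assimilate it
    # (two co-resident node groups in one cluster must eventually share
    # one identity).
    if (fresh) {
      graph$node_label[members[[k]]] <- assigned[k]
      graph$label_mismatch[members[[k]]] <- 0L
    } else {
      mm <- members[[k]]
      nas <- mm[is.na(graph$node_label[mm])]
      if (length(nas)) graph$node_label[nas] <- assigned[k]
      mis <- mm[graph$node_label[mm] != assigned[k]]
      hit <- mm[graph$node_label[mm] == assigned[k]]
      graph$label_mismatch[hit] <- 0L
      if (length(mis)) {
        graph$label_mismatch[mis] <- graph$label_mismatch[mis] + 1L
        flip <- mis[graph$label_mismatch[mis] > 100L]
        if (length(flip)) {
          graph$node_label[flip] <- assigned[k]
          graph$label_mismatch[flip] <- 0L
        }
      }
    }
  }
  graph$comp[!graph$alive] <- NA_integer_
  graph$comp_dirty <- FALSE
  out <- graph$comp[live]
  names(out) <- live
  out
}

#' One streaming adaptation step
#'
#' Processes a single feature vector: finds the two nearest nodes, adds the
#' squared distance to the winner's error, moves the winner by `e_s1` and
#' its neighbours by `e_nbr` toward the spike, refreshes the winner-runner
#' edge to age 0, ages the winner's other edges, prunes edges older than
#' `edge_prune_age` (removing nodes left edgeless), inserts a new node in
#' the highest-error region every `lambda`-th step while below the node
#' budget, and returns the component label of the winner. Until `n_init`
#' distinct vectors have been seen, incoming vectors initialise the graph.
#'
#' @param graph a `gng` graph.
#' @param x feature vector.
#' @return the cluster (component) label assigned to `x`.
#' @export
gng_adapt <- function(graph, x) {
  p <- graph$params
  live_n <- sum(graph$alive)
  if (live_n < p$n_init) {
    if (live_n == 0) {
      s <- .gng_add_node(graph, x)
      return(graph$node_label[s])
    }
    dup <- vapply(which(graph$alive), function(s)
      isTRUE(all.equal(graph$pos[s, ], as.numeric(x))), logical(1))
    if (!any(dup)) {
      s <- .gng_add_node(graph, x)
      return(graph$node_label[s])
    }
    comp <- gng_components(graph)
    return(unname(comp[as.character(which(graph$alive)[dup][1])]))
  }

  graph$step <- graph$step + 1L
  nn <- gng_nearest_two(graph, x)
  w1 <- nn$w1; w2 <- nn$w2

  # running winner-distance scale: tracks the lower envelope of d1 (fast
  # down, slow up), i.e. the typical within-cluster spike-to-node distance
  if (is.na(graph$scale)) graph$scale <- nn$d1
  else if (nn$d1 < graph$scale) graph$scale <- graph$scale + 0.25 * (nn$d1 - graph$scale)
  else graph$scale <- graph$scale + 0.02 * (nn$d1 - graph$scale)

  # novelty: a spike far from every node marks an uncovered region (a new
  # cluster, or an outlier). A node is only spawned there once a second far
  # spike confirms the region within a recent window; isolated outliers
  # expire from the pending buffer. The existing nodes are never dragged
  # across the gap either way.
  if (nn$d1 > p$novelty_theta * graph$scale && graph$scale > 0) {
    window <- 20L * p$lambda
    fresh_pend <- !is.na(graph$pend_step) &
      graph$step - graph$pend_step <= window
    s <- NA_integer_
    if (any(fresh_pend)) {
      pd <- graph$pend_pos[fresh_pend, , drop = FALSE]
      dp <- sqrt(rowSums((pd - matrix(x, nrow(pd), graph$dim, byrow = TRUE))^2))
      hit <- which(dp <= p$novelty_theta * graph$scale)
      if (length(hit)) {
        at <- (pd[hit[1], ] + x) / 2
        s <- tryCatch(.gng_add_node(graph, at), error = function(e) NA_integer_)
        if (is.na(s) && is.finite(p$utility_max_idle)) {
          # budget full: reclaim long-idle nodes (e.g. after the data
          # distribution moved away from them), then retry once
          idle <- which(graph$alive &
                          graph$step - graph$last_win > p$utility_max_idle)
          for (v in idle) {
            if (sum(graph$alive) > p$n_init) .gng_kill_node(graph, v)
          }
          if (length(idle))
            s <- tryCatch(.gng_add_node(graph, at), error = function(e) NA_integer_)
        }
        slot <- which(fresh_pend)[hit[1]]
        graph$pend_step[slot] <- NA_integer_
      }
    }
    if (is.na(s)) {
      free <- which(is.na(graph$pend_step) |
                      graph$step - graph$pend_step > window)[1]
      if (!is.na(free)) {
        graph$pend_pos[free, ] <- x
        graph$pend_step[free] <- graph$step
      }
    }
    comp <- gng_components(graph)
    if (!is.na(s)) return(unname(comp[as.character(s)]))
    return(unname(comp[as.character(w1)]))
  }

  graph$err[w1] <- graph$err[w1] + nn$d1^2
  graph$last_win[w1] <- graph$step

  nb <- which(graph$age[w1, ] >= 0L)
  graph$pos[w1, ] <- graph$pos[w1, ] + p$e_s1 * (x - graph$pos[w1, ])
  for (v in nb) {
    graph$pos[v, ] <- graph$pos[v, ] + p$e_nbr * (x - graph$pos[v, ])
  }

  # age the winner's other edges, then create/refresh the winner-runner
  # edge -- but only when the runner-up is local too, so that two distant
  # clusters are never linked through a spike at one of them
  others <- setdiff(nb, w2)
  if (length(others)) {
    graph$age[w1, others] <- graph$age[w1, others] + 1L
    graph$age[others, w1] <- graph$age[w1, others]
  }
  # the runner-up must be local too: never link two distant clusters
  # through a spike at one of them
  if (nn$d2 <= p$edge_gate_kappa * graph$scale) {
    if (graph$age[w1, w2] < 0L) graph$comp_dirty <- TRUE
    graph$age[w1, w2] <- 0L
    graph$age[w2, w1] <- 0L
  }

  stale <- others[graph$age[w1, others] > p$edge_prune_age]
  if (length(stale)) {
    graph$age[w1, stale] <- -1L
    graph$age[stale, w1] <- -1L
    graph$comp_dirty <- TRUE
    for (v in stale) {
      if (all(graph$age[v, ] < 0L)) .gng_kill_node(graph, v)
    }
  }

  if (graph$step %% p$lambda == 0L) {
    if (is.finite(p$utility_max_idle)) {
      idle <- which(graph$alive & graph$step - graph$last_win > p$utility_max_idle)
      for (v in idle) {
        if (sum(graph$alive) > p$n_init) .gng_kill_node(graph, v)
      }
    }
    if (sum(graph$alive) < p$max_nodes) .gng_insert(graph)
    live <- which(graph$alive)
    graph$err[live] <- graph$err[live] * (1 - p$beta)
  }

  comp <- gng_components(graph)
  unname(comp[as.character(w1)])
}

# Canonical growing-neural-gas insertion: split between the highest-error
# node q and its highest-error neighbour f.
.gng_insert <- function(graph) {
  p <- graph$params
  live <- which(graph$alive)
  q <- live[order(-graph$err[live], graph$birth[live])[1]]
  nbq <- which(graph$age[q, ] >= 0L)
  if (length(nbq) == 0) return(invisible(NULL))
  f <- nbq[order(-graph$err[nbq], graph$birth[nbq])[1]]
  mid <- (graph$pos[q, ] + graph$pos[f, ]) / 2
  graph$err[q] <- graph$err[q] * p$alpha
  graph$err[f] <- graph$err[f] * p$alpha
  s <- .gng_add_node(graph, mid, error = graph$err[q],
                     label = graph$node_label[q])
  graph$age[q, f] <- -1L; graph$age[f, q] <- -1L
  graph$age[q, s] <- 0L; graph$age[s, q] <- 0L
  graph$age[f, s] <- 0L; graph$age[s, f] <- 0L
  graph$comp_dirty <- TRUE
  invisible(s)
}

#' Sort a feature stream with the growing-neural-gas graph
#'
#' Single pass over the time-ordered stream: every spike is classified by
#' [gng_adapt()] as it arrives and is not retained afterwards. Cluster
#' labels are re-mapped to dense integers (1, 2, ...) in order of first
#' appearance at the end of the pass.
#'
#' @param stream a [build_features()] result (`feature_stream`), or a plain
#'   feature matrix (then `times` and `channels` should be given).
#' @param params a [gng_params()]. A `NULL` `max_nodes` is resolved to
#'   `nodes_per_channel * number of distinct channels` in the stream.
#' @param times,channels per-spike peak samples and channels when `stream`
#'   is a bare matrix.
#' @return An object of class `sort_result`: `records` (data frame
#'   `peak_sample`, `cluster_id`, `channel`), `graph` (final `gng` state),
#'   `params`.
#' @export
sort_stream <- function(stream, params = gng_params(), times = NULL,
                        channels = NULL) {
  if (inherits(stream, "feature_stream")) {
    feats <- stream$features
    times <- stream$events$peak_sample
    channels <- stream$events$channel
  } else {
    feats <- as.matrix(stream)
    if (is.null(times)) times <- seq_len(nrow(feats))
    if (is.null(channels)) channels <- rep(NA_integer_, nrow(feats))
  }
  n <- nrow(feats)
  if (is.null(params$max_nodes)) {
    n_active <- max(1L, length(unique(channels[!is.na(channels)])))
    params$max_nodes <- as.integer(round(params$nodes_per_channel * n_active))
  }
  if (n == 0) {
    return(structure(list(records = data.frame(peak_sample = integer(0),
                                               cluster_id = integer(0),
                                               channel = integer(0)),
                          graph = NULL, params = params),
                     class = "sort_result"))
  }
  g <- gng_new(params, ncol(feats))
  raw <- integer(n)
  for (i in seq_len(n)) {
    raw[i] <- gng_adapt(g, feats[i, ])
  }
  dense <- match(raw, unique(raw))
  structure(list(records = data.frame(peak_sample = times,
                                      cluster_id = dense,
                                      channel = channels),
                 graph = g, params = params, raw_labels = raw),
            class = "sort_result")
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf("sort_result: %d spikes in %d clusters\n",
              nrow(x$records), length(unique(x$records$cluster_id))))
  invisible(x)
}
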