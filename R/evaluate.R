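# Evaluation: ground-truth accuracy scoring, two-sorter agreement, and
# spike-train autocorrelograms.

# Greedy in-time pairing: walk the (time-sorted) stream `ta` and pair each
# event with the nearest unconsumed event of `tb` within +/- tol samples.
# Returns for each element of ta the index into tb (NA if unmatched).
.pair_times <- function(ta, tb, tol) {
  na <- length(ta); nb <- length(tb)
  out <- rep(NA_integer_, na)
  if (na == 0 || nb == 0) return(out)
  consumed <- rep(FALSE, nb)
  lo <- 1L
  for (i in seq_len(na)) {
    t <- ta[i]
    while (lo <= nb && (tb[lo] < t - tol || consumed[lo])) lo <- lo + 1L
    j <- lo
    best <- NA_integer_; bestd <- tol + 1
    while (j <= nb && tb[j] <= t + tol) {
      if (!consumed[j]) {
        d <- abs(tb[j] - t)
        if (d < bestd) { bestd <- d; best <- j }
      }
      j <- j + 1L
    }
    if (!is.na(best)) {
      out[i] <- best
      consumed[best] <- TRUE
    }
  }
  out
}

#' Score a sorting result against ground truth
#'
#' Pairs each sorted spike with the nearest unconsumed ground-truth event
#' within `time_tol_samples` (greedy in time order), maps clusters to
#' neurons by the optimal one-to-one assignment maximising matched spikes
#' ([solve_assignment()]), and scores accuracy. The headline accuracy uses
#' the ground-truth spike count as denominator, so missed detections count
#' as errors; `accuracy_detected` conditions on matched spikes only.
#'
#' @param result a `sort_result`.
#' @param truth a `ground_truth` object (or its `$events` data frame).
#' @param time_tol_samples pairing tolerance (default 15 = 0.5 ms at 30 kHz).
#' @return list: `accuracy`, `accuracy_detected`, `per_neuron` (named
#'   vector, ground-truth denominator), `confusion` (cluster x neuron
#'   matched-spike counts), `assignment` (neuron assigned to each cluster,
#'   0 = unassigned), `n_truth`, `n_sorted`, `n_matched`.
#' @export
match_to_ground_truth <- function(result, truth, time_tol_samples = 15) {
  ev <- if (inherits(truth, "ground_truth")) truth$events else truth
  if (is.null(ev) || nrow(ev) == 0) stop("empty ground truth")
  rec <- result$records
  n_truth <- nrow(ev)
  neurons <- sort(unique(ev$neuron_id))
  if (nrow(rec) == 0) {
    per <- stats::setNames(numeric(length(neurons)), neurons)
    return(list(accuracy = 0, accuracy_detected = NA_real_, per_neuron = per,
                confusion = matrix(0, 0, length(neurons)),
                assignment = integer(0),
                n_truth = n_truth, n_sorted = 0L, n_matched = 0L))
  }
  o <- order(rec$peak_sample)
  rec <- rec[o, , drop = FALSE]
  pair <- .pair_times(rec$peak_sample, ev$spike_sample, time_tol_samples)
  matched <- !is.na(pair)
  clusters <- sort(unique(rec$cluster_id))
  conf <- matrix(0L, nrow = length(clusters), ncol = length(neurons),
                 dimnames = list(clusters, neurons))
  if (any(matched)) {
    tab <- table(factor(rec$cluster_id[matched], levels = clusters),
                 factor(ev$neuron_id[pair[matched]], levels = neurons))
    conf[] <- as.integer(tab)
  }
  assign <- solve_assignment(conf)
  correct_by_neuron <- stats::setNames(numeric(length(neurons)),
                                       as.character(neurons))
  for (k in seq_along(clusters)) {
    if (assign[k] > 0) {
      nm <- as.character(neurons[assign[k]])
      correct_by_neuron[nm] <- correct_by_neuron[nm] + conf[k, assign[k]]
    }
  }
  truth_counts <- table(factor(ev$neuron_id, levels = neurons))
  per_neuron <- as.numeric(correct_by_neuron) / as.numeric(truth_counts)
  names(per_neuron) <- names(correct_by_neuron)
  correct <- sum(correct_by_neuron)
  list(accuracy = correct / n_truth,
       accuracy_detected = if (sum(matched)) correct / sum(matched) else NA_real_,
       per_neuron = per_neuron,
       confusion = conf,
       assignment = assign,
       n_truth = n_truth,
       n_sorted = nrow(rec),
       n_matched = sum(matched))
}

#' Spike-level agreement between two sorting results
#'
#' Pairs spikes of sorter A with spikes of sorter B by time coincidence
#' (greedy, `time_tol_samples`), builds the clustersA x clustersB
#' common-spike count matrix, and computes the agreement percentage as the
#' best one-to-one matched diagonal over the total spike count of the
#' reference sorter A. Optionally restricted to A clusters with at least
#' `min_spikes` spikes.
#'
#' @param result_a,result_b `sort_result` objects from the same recording.
#' @param time_tol_samples coincidence tolerance (default 15 samples).
#' @param min_spikes minimum A-cluster size entering the agreement score.
#' @return list of class `agreement_matrix`: `matrix` (common-spike
#'   counts), `unmatched_a`, `unmatched_b` (per-cluster counts of spikes
#'   with no time-coincident partner), `agreement` (percent), `assignment`.
#' @export
agreement_matrix <- function(result_a, result_b, time_tol_samples = 15,
                             min_spikes = 0) {
  ra <- result_a$records[order(result_a$records$peak_sample), , drop = FALSE]
  rb <- result_b$records[order(result_b$records$peak_sample), , drop = FALSE]
  ca <- sort(unique(ra$cluster_id)); cb <- sort(unique(rb$cluster_id))
  pair <- .pair_times(ra$peak_sample, rb$peak_sample, time_tol_samples)
  matched <- !is.na(pair)
  m <- matrix(0L, nrow = length(ca), ncol = length(cb),
              dimnames = list(ca, cb))
  if (any(matched)) {
    tab <- table(factor(ra$cluster_id[matched], levels = ca),
                 factor(rb$cluster_id[pair[matched]], levels = cb))
    m[] <- as.integer(tab)
  }
  unmatched_a <- table(factor(ra$cluster_id[!matched], levels = ca))
  bmatched <- rep(FALSE, nrow(rb))
  bmatched[pair[matched]] <- TRUE
  unmatched_b <- table(factor(rb$cluster_id[!bmatched], levels = cb))

  keep <- which(as.integer(table(factor(ra$cluster_id, levels = ca))) >= min_spikes)
  total_ref <- sum(ra$cluster_id %in% ca[keep])
  agree <- 0
  assign <- integer(length(ca))
  if (length(keep) && length(cb)) {
    sub <- m[keep, , drop = FALSE]
    a_sub <- solve_assignment(sub)
    assign[keep] <- a_sub
    agree <- sum(vapply(seq_along(keep), function(i)
      if (a_sub[i] > 0) sub[i, a_sub[i]] else 0L, numeric(1)))
  }
  structure(list(matrix = m,
                 unmatched_a = unmatched_a,
                 unmatched_b = unmatched_b,
                 agreement = if (total_ref > 0) 100 * agree / total_ref else NA_real_,
                 assignment = assign),
            class = "agreement_matrix")
}

#' @export
print.agreement_matrix <- function(x, ...) {
  cat(sprintf("agreement_matrix: %d x %d clusters, agreement %.1f%%\n",
              nrow(x$matrix), ncol(x$matrix), x$agreement))
  invisible(x)
}

#' Autocorrelogram of a spike train
#'
#' Histogram of pairwise spike-time differences within `+/- window_ms`,
#' excluding zero-lag self pairs; symmetric by construction. An empty
#' centre (dip within the refractory period) indicates a cleanly sorted
#' single unit.
#'
#' @param spike_times_s spike times in seconds (sorted or not).
#' @param bin_ms histogram bin width in milliseconds.
#' @param window_ms half-width of the lag window in milliseconds.
#' @return list: `lag_ms` (bin centres), `count`, `breaks_ms`.
#' @export
autocorrelogram <- function(spike_times_s, bin_ms = 1, window_ms = 50) {
  t <- sort(spike_times_s) * 1000  # ms
  nbin <- ceiling(window_ms / bin_ms)
  breaks <- seq(-nbin * bin_ms, nbin * bin_ms, by = bin_ms)
  counts <- integer(length(breaks) - 1)
  n <- length(t)
  if (n >= 2) {
    lags <- numeric(0)
    j0 <- 1L
    for (i in seq_len(n)) {
      j <- i + 1L
      while (j <= n && t[j] - t[i] <= window_ms) {
        lags <- c(lags, t[j] - t[i])
        j <- j + 1L
      }
    }
    # bin the positive (i < j) lags and mirror, so the histogram is
    # symmetric by construction
    idx <- pmin(floor(lags / bin_ms + 1e-9) + 1L, nbin)
    pos <- tabulate(idx, nbins = nbin)
    counts <- c(rev(pos), pos)
  }
  list(lag_ms = (breaks[-1] + breaks[-length(breaks)]) / 2,
       count = counts, breaks_ms = breaks)
}
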