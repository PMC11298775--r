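# Duplicate-spike elimination: the same action potential is picked up by
# several adjacent channels at (physically) zero delay; only the
# highest-amplitude copy is kept as the representative spike.

#' Duplicate-elimination configuration
#'
#' Two detected events are duplicates of one another if (1) their peak times
#' coincide within `coincidence_tol_samples` (the zero-delay criterion,
#' loosened by a few samples because filtering and noise jitter discrete
#' peak positions), (2) their channels are within `adjacency_radius`
#' (physically remote channels imply different neurons even for similar
#' waveforms), and (3) their peak-aligned waveforms correlate at
#' `r > r_th`.
#'
#' @param r_th Pearson correlation threshold (default 0.6).
#' @param coincidence_tol_samples peak-time tolerance (default 6 = 0.2 ms at
#'   30 kHz).
#' @param adjacency_radius channel distance limit (default 5 channels).
#' @return An object of class `dedup_config`.
#' @export
dedup_config <- function(r_th = 0.6, coincidence_tol_samples = 6,
                         adjacency_radius = 5) {
  if (r_th <= 0 || r_th >= 1) stop("r_th must be in (0, 1)")
  if (coincidence_tol_samples < 0 || adjacency_radius < 0)
    stop("tolerances must be >= 0")
  structure(list(r_th = r_th,
                 coincidence_tol_samples = as.integer(coincidence_tol_samples),
                 adjacency_radius = as.integer(adjacency_radius)),
            class = "dedup_config")
}

#' Pearson correlation between two waveforms
#'
#' Sample Pearson correlation `cov(a, b) / (sd(a) sd(b))`. If either
#' waveform is constant the correlation is undefined; 0 is returned with a
#' warning.
#'
#' @param waveform_a,waveform_b equal-length numeric vectors.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(waveform_a, waveform_b) {
  if (length(waveform_a) != length(waveform_b))
    stop("waveforms must have equal length")
  if (stats::sd(waveform_a) == 0 || stats::sd(waveform_b) == 0) {
    warning("constant waveform: correlation undefined, returning 0")
    return(0)
  }
  stats::cor(waveform_a, waveform_b)
}

#' Group coincident adjacent-channel events into duplicate sets
#'
#' Greedy single-pass grouping over the time-sorted event stream: the first
#' ungrouped event seeds a group and absorbs every later ungrouped event
#' whose peak time is within the coincidence tolerance of the seed, whose
#' channel is within the adjacency radius of the seed's channel, and whose
#' waveform correlates with the seed's at `r > r_th`. Every event belongs to
#' exactly one group.
#'
#' @param spikes a [detect_spikes()] result (`spike_events`).
#' @param cfg a [dedup_config()].
#' @return integer vector of group ids (one per event, dense from 1).
#' @export
group_duplicates <- function(spikes, cfg = dedup_config()) {
  stopifnot(inherits(spikes, "spike_events"), inherits(cfg, "dedup_config"))
  ev <- spikes$events
  n <- nrow(ev)
  group <- integer(n)
  if (n == 0) return(group)
  if (is.unsorted(ev$peak_sample)) stop("events must be time-sorted")
  sig <- spikes$sigma
  sd_of <- function(i) {
    if (is.null(sig)) return(0)
    s <- sig[match(as.character(ev$channel[i]), names(sig))]
    if (is.na(s)) 0 else s
  }
  g <- 0L
  for (i in seq_len(n)) {
    if (group[i] != 0L) next
    g <- g + 1L
    group[i] <- g
    j <- i + 1L
    while (j <= n && ev$peak_sample[j] - ev$peak_sample[i] <= cfg$coincidence_tol_samples) {
      if (group[j] == 0L &&
          abs(ev$channel[j] - ev$channel[i]) <= cfg$adjacency_radius) {
        r <- .aligned_r(spikes$waveforms[i, ], spikes$waveforms[j, ],
                        sd_of(i), sd_of(j))
        if (!is.na(r) && r > cfg$r_th) group[j] <- g
      }
      j <- j + 1L
    }
  }
  group
}

# Pearson r after aligning both waveforms on their absolute peaks (windows
# are extremum-centred by detection, so this is usually the identity; it
# guards against residual one-sample jitter within a window). When the
# per-channel noise SDs are supplied, the correlation is disattenuated for
# additive noise: a weak duplicate copy of a spike has true waveform
# correlation near 1 with the strong copy, but the observed r is shrunk by
# the noise variance share; dividing by sqrt((1 - s_a^2/var(a)) (1 -
# s_b^2/var(b))) recovers an estimate of the underlying correlation.
.aligned_r <- function(a, b, sd_a = 0, sd_b = 0) {
  pa <- which.max(abs(a)); pb <- which.max(abs(b))
  d <- pb - pa
  n <- length(a)
  if (d > 0) { b <- b[(1 + d):n]; a <- a[1:(n - d)] }
  else if (d < 0) { b <- b[1:(n + d)]; a <- a[(1 - d):n] }
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  r <- stats::cor(a, b)
  fa <- 1 - sd_a^2 / stats::var(a)
  fb <- 1 - sd_b^2 / stats::var(b)
  # only disattenuate when the signal clearly dominates the noise
  if (fa > 0.2 && fb > 0.2) r <- r / sqrt(fa * fb)
  max(min(r, 1), -1)
}

#' Select the representative spike of a duplicate group
#'
#' The member with the highest peak amplitude represents the group (highest
#' amplitude implies best signal-to-noise ratio); ties are broken by the
#' lowest channel index.
#'
#' @param group_events data frame of events of one group (rows of
#'   `spikes$events`).
#' @return the row index (within `group_events`) of the representative.
#' @export
select_representative <- function(group_events) {
  if (nrow(group_events) == 0) stop("empty group")
  o <- order(-group_events$peak_amplitude, group_events$channel)
  o[1]
}

#' Collapse duplicate groups to the representative spike stream
#'
#' Applies [group_duplicates()] and [select_representative()] and returns
#' the representative events as a new `spike_events` object, plus an audit
#' of the grouping.
#'
#' @param spikes a `spike_events` object (time-sorted).
#' @param cfg a [dedup_config()].
#' @return A `spike_events` object containing only the representatives, with
#'   extra fields `group_sizes` (members per group) and `group_id` (group of
#'   each original event).
#' @export
dedup <- function(spikes, cfg = dedup_config()) {
  group <- group_duplicates(spikes, cfg)
  ev <- spikes$events
  if (nrow(ev) == 0) {
    out <- spikes
    out$group_sizes <- integer(0)
    out$group_id <- group
    return(out)
  }
  reps <- vapply(split(seq_len(nrow(ev)), group), function(idx) {
    idx[select_representative(ev[idx, , drop = FALSE])]
  }, integer(1))
  reps <- reps[order(ev$peak_sample[reps], ev$channel[reps])]
  out <- spikes
  out$events <- ev[reps, , drop = FALSE]
  rownames(out$events) <- NULL
  out$waveforms <- spikes$waveforms[reps, , drop = FALSE]
  out$group_sizes <- as.integer(table(group))
  out$group_id <- group
  out
}
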