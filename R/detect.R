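# Per-channel threshold detection of spikes on the filtered voltages.

#' Detection threshold configuration
#'
#' The threshold on each channel is `k_sigma * sigma_c`, where `sigma_c` is
#' the robust noise estimate of [estimate_sigma()]. Each detection yields a
#' window of `window_samples` samples centred on the local extremum, and
#' further crossings within `dead_time_samples` on the same channel are
#' suppressed.
#'
#' @param k_sigma threshold multiplier (default 5).
#' @param window_samples waveform window length W (even, default 60 = 2 ms
#'   at 30 kHz).
#' @param dead_time_samples per-channel suppression after a detection
#'   (default 30 = 1 ms at 30 kHz).
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(k_sigma = 5, window_samples = 60,
                             dead_time_samples = 30) {
  if (k_sigma <= 0) stop("k_sigma must be > 0")
  if (window_samples %% 2 != 0) stop("window_samples must be even")
  structure(list(k_sigma = k_sigma,
                 window_samples = as.integer(window_samples),
                 dead_time_samples = as.integer(dead_time_samples)),
            class = "threshold_config")
}

#' Robust per-channel noise estimate
#'
#' `sigma_c = median(|v|) / 0.6745`, the classic median-based noise standard
#' deviation estimator for spike detection: for Gaussian noise the median of
#' `|v|` is 0.6745 sigma, and unlike a mean-based estimate the median is not
#' inflated by the spikes themselves.
#'
#' @param channel_trace numeric vector (one filtered channel).
#' @return The noise standard deviation estimate (0 for an all-zero trace).
#' @export
estimate_sigma <- function(channel_trace) {
  if (length(channel_trace) == 0) stop("empty trace")
  stats::median(abs(channel_trace)) / 0.6745
}

#' Threshold-based spike detection
#'
#' Finds crossings of `|v| > k_sigma * sigma_c` per channel, centres a
#' W-sample window on the local extremum of each crossing, suppresses
#' further crossings within the dead time on the same channel, and returns
#' all events time-sorted across channels. Detection uses the absolute
#' voltage so spikes of either polarity are found. Channels whose noise
#' estimate is zero are skipped with a warning. Events whose window would
#' extend past the recording edges are dropped.
#'
#' @param block a filtered [recording_block()].
#' @param cfg a [threshold_config()].
#' @return An object of class `spike_events`: list with `events` (data frame
#'   `channel` (0-based id), `peak_sample`, `peak_amplitude` = `max(abs(w))`),
#'   `waveforms` (matrix, one row per event), `window_samples`,
#'   `sample_rate_hz`, and `sigma` (per-channel noise estimates).
#' @export
detect_spikes <- function(block, cfg = threshold_config()) {
  stopifnot(inherits(block, "recording_block"), inherits(cfg, "threshold_config"))
  W <- cfg$window_samples
  half <- W %/% 2
  n_t <- n_samples(block)
  if (W > n_t) stop("window_samples exceeds the trace length")
  ev_ch <- list(); ev_peak <- list(); ev_amp <- list(); ev_wave <- list()
  sigma <- numeric(n_channels(block))
  for (c in seq_len(n_channels(block))) {
    v <- block$samples[, c]
    s <- estimate_sigma(v)
    sigma[c] <- s
    if (s == 0) {
      warning("channel ", block$channel_ids[c],
              " has zero noise estimate; detection disabled")
      next
    }
    th <- cfg$k_sigma * s
    av <- abs(v)
    above <- which(av > th)
    if (length(above) == 0) next
    # run starts: first crossing of each contiguous run above threshold
    starts <- above[c(TRUE, diff(above) > 1)]
    peaks <- integer(0)
    last_peak <- -Inf
    for (st in starts) {
      if (st - last_peak <= cfg$dead_time_samples) next
      seg <- st:min(st + half, n_t)
      pk <- seg[which.max(av[seg])]
      if (pk - last_peak <= cfg$dead_time_samples) next
      if (pk - half + 1L < 1L || pk + half > n_t) next
      peaks <- c(peaks, pk)
      last_peak <- pk
    }
    if (length(peaks) == 0) next
    idx <- outer(peaks, (-half + 1L):half, `+`)
    wf <- matrix(v[idx], nrow = length(peaks))
    ev_ch[[length(ev_ch) + 1L]] <- rep(block$channel_ids[c], length(peaks))
    ev_peak[[length(ev_peak) + 1L]] <- peaks
    ev_amp[[length(ev_amp) + 1L]] <- apply(abs(wf), 1, max)
    ev_wave[[length(ev_wave) + 1L]] <- wf
  }
  if (length(ev_peak) == 0) {
    events <- data.frame(channel = integer(0), peak_sample = integer(0),
                         peak_amplitude = numeric(0))
    waves <- matrix(numeric(0), ncol = W)
  } else {
    events <- data.frame(channel = unlist(ev_ch),
                         peak_sample = unlist(ev_peak),
                         peak_amplitude = unlist(ev_amp))
    waves <- do.call(rbind, ev_wave)
    o <- order(events$peak_sample, events$channel)
    events <- events[o, , drop = FALSE]
    rownames(events) <- NULL
    waves <- waves[o, , drop = FALSE]
  }
  names(sigma) <- as.character(block$channel_ids)
  structure(list(events = events, waveforms = waves,
                 window_samples = W, sample_rate_hz = block$sample_rate_hz,
                 sigma = sigma),
            class = "spike_events")
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("spike_events: %d events on %d channels (W = %d samples)\n",
              nrow(x$events), length(unique(x$events$channel)),
              x$window_samples))
  invisible(x)
}
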