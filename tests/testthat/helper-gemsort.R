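# Shared helpers for the test suite. All fixtures are generated in code.

# Accuracy of arbitrary integer labels against true labels, via the same
# optimal one-to-one assignment used by the package scorer.
label_accuracy <- function(cluster, truth) {
  conf <- table(cluster, truth)
  a <- solve_assignment(conf)
  correct <- sum(vapply(seq_len(nrow(conf)), function(k)
    if (a[k] > 0) conf[k, a[k]] else 0L, numeric(1)))
  correct / length(truth)
}

# Small recording with a single template inserted at known times on one
# channel, plus optional white noise.
toy_recording <- function(times, channel = 3, n_channels = 6,
                          n_samples = 30000, amplitude = 1,
                          family = "gaussian", noise_sd = 0,
                          sample_rate_hz = 30000, seed = 7) {
  set.seed(seed)
  m <- matrix(if (noise_sd > 0) rnorm(n_samples * n_channels, sd = noise_sd)
              else 0, nrow = n_samples, ncol = n_channels)
  tem <- make_template(family, 60, amplitude)
  p <- ceiling((length(tem) + 1) / 2)
  for (t in times) {
    idx <- (t - p + 1):(t - p + length(tem))
    ok <- idx >= 1 & idx <= n_samples
    m[idx[ok], channel + 1] <- m[idx[ok], channel + 1] + tem[ok]
  }
  recording_block(m, sample_rate_hz)
}

# Deterministic stream of labelled Gaussian blobs in feature space.
blob_stream <- function(n, centers, sd = 0.25, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  id <- sample(rep(seq_len(k), length.out = n))
  X <- centers[id, , drop = FALSE] +
    matrix(rnorm(n * ncol(centers), sd = sd), n)
  list(X = X, id = id)
}

# Build a spike_events object directly (for dedup unit tests).
manual_events <- function(channel, peak_sample, waveforms,
                          sample_rate_hz = 30000, sigma = NULL) {
  waveforms <- as.matrix(waveforms)
  amp <- apply(abs(waveforms), 1, max)
  o <- order(peak_sample, channel)
  structure(list(
    events = data.frame(channel = channel[o], peak_sample = peak_sample[o],
                        peak_amplitude = amp[o]),
    waveforms = waveforms[o, , drop = FALSE],
    window_samples = ncol(waveforms),
    sample_rate_hz = sample_rate_hz,
    sigma = sigma),
    class = "spike_events")
}
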