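# Noise elimination: per-channel high-pass filtering to remove LFP and
# drift, then local common average referencing (L-CAR) to cancel noise that
# is spatially correlated across the probe.

#' Zero-phase Butterworth high-pass filter
#'
#' Applies a second-order high-pass Butterworth filter (3 dB cut-off
#' `cutoff_hz`, default 300 Hz) to every channel. Filtering is zero-phase
#' (forward-backward), which preserves spike peak times — a property the
#' downstream zero-delay duplicate criterion relies on.
#'
#' @param block a [recording_block()].
#' @param cutoff_hz 3 dB cut-off frequency (must be below Nyquist).
#' @param order filter order of the underlying one-pass design.
#' @return A filtered `recording_block`.
#' @export
highpass <- function(block, cutoff_hz = 300, order = 2) {
  stopifnot(inherits(block, "recording_block"))
  nyq <- block$sample_rate_hz / 2
  if (cutoff_hz >= nyq) stop("cutoff_hz must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "high")
  out <- block$samples
  for (c in seq_len(ncol(out))) {
    out[, c] <- .filtfilt(bf$b, bf$a, out[, c])
  }
  recording_block(out, block$sample_rate_hz, block$channel_ids)
}

# Zero-phase IIR filtering (forward-backward), with short reflection
# padding to suppress edge transients. The MA part runs through
# stats::filter(sides = 1) and the AR part through its recursive mode,
# both C implementations.
.filtfilt <- function(b, a, x) {
  one_pass <- function(x) {
    y <- as.numeric(stats::filter(x, b, method = "convolution", sides = 1))
    for (i in seq_len(length(b) - 1)) {
      y[i] <- sum(b[seq_len(i)] * x[i:1])
    }
    if (length(a) > 1) y <- as.numeric(stats::filter(y, -a[-1], method = "recursive"))
    y
  }
  np <- min(3 * (max(length(a), length(b)) - 1) * 10, length(x) - 1)
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - np)]
  xx <- c(pre, x, post)
  y <- one_pass(xx)
  y <- rev(one_pass(rev(y)))
  y[(np + 1):(np + length(x))]
}

#' L-CAR configuration
#'
#' `n_near` and `n_far` (`n_far > n_near`, both even) bound the symmetric
#' band of channels averaged as the noise reference for each channel: on each
#' side of channel `c`, channels at offsets `n_near/2` to `n_far/2`
#' (inclusive) are included. The inner exclusion zone keeps channels that see
#' the spike itself (the duplication radius) out of the reference.
#'
#' @param n_near nearest included channel distance x2 (even, >= 2).
#' @param n_far farthest included channel distance x2 (even, > n_near).
#' @return An object of class `lcar_config`.
#' @export
lcar_config <- function(n_near = 12, n_far = 20) {
  if (n_far <= n_near || n_near < 2) stop("need n_far > n_near >= 2")
  if (n_near %% 2 != 0 || n_far %% 2 != 0)
    stop("n_near and n_far must be even (bands are symmetric about c)")
  structure(list(n_near = as.integer(n_near), n_far = as.integer(n_far)),
            class = "lcar_config")
}

#' Local common average referencing
#'
#' For each channel `c`, subtracts the mean voltage of the two symmetric
#' channel bands at offsets `n_near/2` to `n_far/2` on each side. The sum
#' is always divided by the full nominal band size `n`, so for edge
#' channels (where part of the band falls off the probe) only a partial
#' common-mode correction is applied. Renormalising by the truncated band
#' size instead would amplify the spike bleed of any strong unit inside
#' the one-sided reference to detectable amplitude on edge channels, which
#' is worse than an incomplete common-mode subtraction.
#'
#' @param block a [recording_block()].
#' @param cfg an [lcar_config()].
#' @return A referenced `recording_block`.
#' @export
lcar <- function(block, cfg = lcar_config()) {
  stopifnot(inherits(block, "recording_block"), inherits(cfg, "lcar_config"))
  nch <- n_channels(block)
  if (cfg$n_far >= 2 * nch) stop("n_far too large for the channel count")
  lo <- cfg$n_near / 2
  hi <- cfg$n_far / 2
  m <- block$samples
  out <- m
  offs <- c(-(hi:lo), lo:hi)
  n_nominal <- length(offs)
  # cumulative channel sums: band sums become two column differences
  cs <- matrix(0, nrow = nrow(m), ncol = nch + 1)
  for (c in seq_len(nch)) cs[, c + 1] <- cs[, c] + m[, c]
  band_sum <- function(from, to) {  # inclusive channel-index range, clipped
    from <- max(from, 1); to <- min(to, nch)
    if (from > to) return(0)
    cs[, to + 1] - cs[, from]
  }
  for (c in seq_len(nch)) {
    ref <- (band_sum(c - hi, c - lo) + band_sum(c + lo, c + hi)) / n_nominal
    out[, c] <- m[, c] - ref
  }
  recording_block(out, block$sample_rate_hz, block$channel_ids)
}
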