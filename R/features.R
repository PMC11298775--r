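# Feature extraction: principal components learned from an initial batch of
# representative spikes, plus the recording-channel position as an extra
# feature separating similar waveforms recorded at different probe sites.

#' Fit a PCA basis on a training batch of spike waveforms
#'
#' Mean-centred PCA over the first training spikes of a run (waveform shapes
#' drift only slowly, so a basis learned during a short initial period stays
#' valid and no re-fitting is done while streaming). Components are
#' orthonormal and ordered by descending explained variance.
#'
#' Detection centres windows on the sample-level extremum, which jitters by
#' a few samples under noise (especially for flat-peaked waveforms); that
#' jitter would otherwise leak into the principal components as spurious
#' shape variance. Both training and projection therefore re-align each
#' waveform to the running mean waveform at the lag (within
#' `align_max_shift`) maximising their cross-correlation.
#'
#' @param training_waveforms matrix with one waveform per row (all length W).
#' @param n_components number of components to keep (default 2).
#' @param align_max_shift maximum alignment lag in samples (0 disables).
#' @return An object of class `pca_basis`: `components` (n_components x W),
#'   `mean_waveform`, `coeff_sd` (per-component training projection SD, used
#'   to standardise coefficients), `n_components`, `training_count`,
#'   `align_max_shift`.
#' @export
fit_pca <- function(training_waveforms, n_components = 2, align_max_shift = 6) {
  training_waveforms <- as.matrix(training_waveforms)
  m <- nrow(training_waveforms)
  if (m < n_components + 1)
    stop("need at least ", n_components + 1, " training spikes, got ", m)
  if (align_max_shift > 0 && m > 2) {
    ref <- colMeans(training_waveforms)
    training_waveforms <- t(apply(training_waveforms, 1, .align_to,
                                  ref = ref, max_shift = align_max_shift))
  }
  pc <- stats::prcomp(training_waveforms, center = TRUE, scale. = FALSE)
  if (pc$sdev[n_components] < 1e-12)
    stop("degenerate training set: fewer than ", n_components,
         " directions of variance")
  comps <- t(pc$rotation[, seq_len(n_components), drop = FALSE])
  coeff_sd <- pc$sdev[seq_len(n_components)]
  structure(list(components = comps,
                 mean_waveform = pc$center,
                 coeff_sd = coeff_sd,
                 n_components = as.integer(n_components),
                 training_count = m,
                 align_max_shift = as.integer(align_max_shift)),
            class = "pca_basis")
}

# Shift `w` by the integer lag in [-max_shift, max_shift] maximising the
# inner product with `ref` (zero-padded at the edges).
.align_to <- function(w, ref, max_shift) {
  n <- length(w)
  best <- 0L; best_ip <- -Inf
  for (sh in -max_shift:max_shift) {
    if (sh >= 0) ip <- sum(w[1:(n - sh)] * ref[(1 + sh):n])
    else ip <- sum(w[(1 - sh):n] * ref[1:(n + sh)])
    if (ip > best_ip) { best_ip <- ip; best <- sh }
  }
  if (best == 0L) return(w)
  out <- numeric(n)
  if (best > 0) out[(1 + best):n] <- w[1:(n - best)]
  else out[1:(n + best)] <- w[(1 - best):n]
  out
}

#' Project a spike waveform onto a PCA basis
#'
#' The n-th coefficient is the inner product of the mean-centred waveform
#' with the n-th component, the discrete realisation of integrating the
#' spike against the component over the waveform epoch. Coefficients are
#' raw (not standardised); see [build_features()].
#'
#' @param waveform numeric vector of length W (or a matrix of row waveforms).
#' @param basis a [fit_pca()] result.
#' @return numeric vector of `n_components` coefficients (or a matrix with
#'   one row per waveform).
#' @export
project_spike <- function(waveform, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  W <- length(basis$mean_waveform)
  shift <- basis$align_max_shift
  if (is.null(shift)) shift <- 0L
  if (is.matrix(waveform)) {
    if (ncol(waveform) != W) stop("waveform length must be ", W)
    if (shift > 0)
      waveform <- t(apply(waveform, 1, .align_to, ref = basis$mean_waveform,
                          max_shift = shift))
    return(sweep(waveform, 2, basis$mean_waveform) %*% t(basis$components))
  }
  if (length(waveform) != W) stop("waveform length must be ", W)
  if (shift > 0)
    waveform <- .align_to(waveform, basis$mean_waveform, shift)
  drop((waveform - basis$mean_waveform) %*% t(basis$components))
}

#' Build feature vectors for a representative spike stream
#'
#' Feature vector of a spike: `{channel * channel_weight, a_0, a_1, ...}`.
#' PCA coefficients are standardised by the per-component training SD so the
#' channel weight has a single interpretable scale: with `channel_weight =
#' 1` one channel of probe distance equals one training SD of waveform
#' shape variation. `channel_weight = 0` is the shape-only ablation
#' (requires `allow_zero_weight = TRUE` since it discards the positional
#' information the multichannel sort relies on).
#'
#' @param spikes a `spike_events` object (the representative stream).
#' @param basis a [fit_pca()] result.
#' @param channel_weight scale applied to the channel index (default 1).
#' @param allow_zero_weight set `TRUE` to permit the shape-only ablation.
#' @return An object of class `feature_stream`: `features` (matrix, one row
#'   per spike: channel feature then standardised coefficients), `events`
#'   (the spike table), `basis`, `channel_weight`.
#' @export
build_features <- function(spikes, basis, channel_weight = 1,
                           allow_zero_weight = FALSE) {
  stopifnot(inherits(spikes, "spike_events"), inherits(basis, "pca_basis"))
  if (channel_weight < 0) stop("channel_weight must be >= 0")
  if (channel_weight == 0 && !allow_zero_weight)
    stop("channel_weight = 0 drops the positional feature; ",
         "set allow_zero_weight = TRUE for the shape-only ablation")
  coeffs <- project_spike(spikes$waveforms, basis)
  coeffs <- sweep(coeffs, 2, basis$coeff_sd, `/`)
  feats <- cbind(spikes$events$channel * channel_weight, coeffs)
  colnames(feats) <- c("channel_feature",
                       paste0("a", seq_len(basis$n_components) - 1L))
  structure(list(features = feats, events = spikes$events, basis = basis,
                 channel_weight = channel_weight,
                 sample_rate_hz = spikes$sample_rate_hz),
            class = "feature_stream")
}
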