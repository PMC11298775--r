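# End-to-end pipeline: high-pass -> L-CAR -> detect -> dedup -> PCA +
# channel feature -> growing-neural-gas stream clustering.

#' Full pipeline configuration
#'
#' Collects the per-stage configurations and the feature/training settings.
#' The PCA basis is trained on the first `training_spikes` representative
#' spikes or on those within the first `training_max_s` seconds, whichever
#' gives fewer.
#'
#' @param highpass_cutoff_hz high-pass 3 dB cut-off (default 300).
#' @param filter_order Butterworth order (default 2).
#' @param lcar an [lcar_config()].
#' @param threshold a [threshold_config()].
#' @param dedup a [dedup_config()].
#' @param n_components PCA components kept (default 2).
#' @param channel_weight channel-feature scale; 0 (shape-only ablation)
#'   is permitted here and forwarded with `allow_zero_weight`.
#' @param training_spikes PCA training batch size (default 200).
#' @param training_max_s PCA training time horizon in seconds (default 10).
#' @param gng a [gng_params()].
#' @param seed integer recorded in the provenance (the pipeline itself is
#'   deterministic; the seed matters when the input is generated).
#' @return An object of class `gemsort_config`.
#' @export
gemsort_config <- function(highpass_cutoff_hz = 300, filter_order = 2,
                           lcar = lcar_config(), threshold = threshold_config(),
                           dedup = dedup_config(), n_components = 2,
                           channel_weight = 3, training_spikes = 200,
                           training_max_s = 10, gng = gng_params(),
                           seed = 1L) {
  structure(list(highpass_cutoff_hz = highpass_cutoff_hz,
                 filter_order = filter_order, lcar = lcar,
                 threshold = threshold, dedup = dedup,
                 n_components = as.integer(n_components),
                 channel_weight = channel_weight,
                 training_spikes = as.integer(training_spikes),
                 training_max_s = training_max_s,
                 gng = gng, seed = as.integer(seed)),
            class = "gemsort_config")
}

#' Run the full GEMsort pipeline on a recording
#'
#' Applies, in order: zero-phase Butterworth high-pass, local common
#' average referencing, per-channel 5-sigma detection, duplicate-spike
#' elimination, PCA feature extraction (basis trained on the initial
#' representative batch) with the channel positional feature, and streaming
#' growing-neural-gas clustering. Per-stage counts are logged with
#' `message()` when `verbose = TRUE`. The run is fully deterministic for a
#' given input.
#'
#' @param input a [recording_block()] or a path readable by
#'   [read_recording()].
#' @param config a [gemsort_config()].
#' @param verbose log per-stage counts to stderr.
#' @return A `sort_result` whose `records` hold `(peak_sample, cluster_id,
#'   channel)` per representative spike, with extra fields: `stages`
#'   (per-stage event counts), `representatives` (the deduplicated
#'   `spike_events`), `basis`, `provenance`.
#' @export
run_gemsort <- function(input, config = gemsort_config(), verbose = FALSE) {
  block <- if (inherits(input, "recording_block")) input else read_recording(input)
  stopifnot(inherits(config, "gemsort_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  empty <- function() {
    structure(list(records = data.frame(peak_sample = integer(0),
                                        cluster_id = integer(0),
                                        channel = integer(0)),
                   graph = NULL, params = config$gng,
                   stages = list(detected = 0L, representatives = 0L),
                   representatives = NULL, basis = NULL,
                   provenance = list(seed = config$seed)),
              class = "sort_result")
  }
  if (n_samples(block) == 0) return(empty())

  filt <- tryCatch(
    lcar(highpass(block, config$highpass_cutoff_hz, config$filter_order),
         config$lcar),
    error = function(e) stop("preprocess stage: ", conditionMessage(e)))
  spikes <- tryCatch(detect_spikes(filt, config$threshold),
                     error = function(e) stop("detect stage: ", conditionMessage(e)))
  say("detect: %d events above %.3g-sigma threshold",
      nrow(spikes$events), config$threshold$k_sigma)
  if (nrow(spikes$events) == 0) return(empty())

  reps <- tryCatch(dedup(spikes, config$dedup),
                   error = function(e) stop("dedup stage: ", conditionMessage(e)))
  say("dedup: %d events collapsed to %d representatives",
      nrow(spikes$events), nrow(reps$events))

  n_rep <- nrow(reps$events)
  horizon <- config$training_max_s * block$sample_rate_hz
  n_train <- min(config$training_spikes, sum(reps$events$peak_sample <= horizon))
  n_train <- max(n_train, min(n_rep, config$n_components + 1L))
  if (n_train < config$n_components + 1L)
    stop("features stage: only ", n_rep, " representative spikes; need ",
         config$n_components + 1L, " for PCA training")
  basis <- tryCatch(
    fit_pca(reps$waveforms[seq_len(n_train), , drop = FALSE],
            config$n_components),
    error = function(e) stop("features stage: ", conditionMessage(e)))
  feats <- build_features(reps, basis, config$channel_weight,
                          allow_zero_weight = TRUE)
  say("features: PCA basis from %d training spikes, channel weight %g",
      n_train, config$channel_weight)

  result <- tryCatch(sort_stream(feats, config$gng),
                     error = function(e) stop("cluster stage: ", conditionMessage(e)))
  say("cluster: %d spikes in %d clusters (%d nodes)",
      nrow(result$records), length(unique(result$records$cluster_id)),
      if (!is.null(result$graph)) sum(result$graph$alive) else 0L)

  result$stages <- list(detected = nrow(spikes$events),
                        representatives = n_rep,
                        training_spikes = n_train)
  result$representatives <- reps
  result$basis <- basis
  result$provenance <- list(seed = config$seed,
                            channel_weight = config$channel_weight,
                            config = config)
  result
}
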