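#' Multichannel recording block
#'
#' Container for a rectangular multichannel extracellular voltage matrix.
#' Channels are ordered along the probe shank, so index adjacency equals
#' physical adjacency. Channel ids follow the probe convention and are
#' 0-based; column `j` of `samples` holds channel `channel_ids[j]`.
#'
#' @param samples numeric matrix, time x channel (signal units).
#' @param sample_rate_hz sampling rate in Hz (default 30000).
#' @param channel_ids integer channel ids in physical order; defaults to
#'   `0:(ncol(samples) - 1)`.
#' @return An object of class `recording_block`.
#' @export
recording_block <- function(samples, sample_rate_hz = 30000, channel_ids = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be a numeric matrix")
  if (is.null(channel_ids)) channel_ids <- seq_len(ncol(samples)) - 1L
  channel_ids <- as.integer(channel_ids)
  if (length(channel_ids) != ncol(samples))
    stop("channel_ids length must equal the number of channels")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive")
  structure(
    list(samples = samples,
         sample_rate_hz = sample_rate_hz,
         channel_ids = channel_ids),
    class = "recording_block")
}

#' @export
print.recording_block <- function(x, ...) {
  cat(sprintf("recording_block: %d channels x %d samples @ %g Hz (%.2f s)\n",
              ncol(x$samples), nrow(x$samples), x$sample_rate_hz,
              nrow(x$samples) / x$sample_rate_hz))
  invisible(x)
}

#' Number of channels / samples of a recording block
#' @param block a `recording_block`.
#' @return integer count.
#' @export
n_channels <- function(block) ncol(block$samples)

#' @rdname n_channels
#' @export
n_samples <- function(block) nrow(block$samples)

#' Write a recording as flat interleaved int16 binary plus sidecar config
#'
#' The voltage matrix is scaled to int16 full range and written
#' channel-interleaved (sample-major), the layout used by common acquisition
#' systems. The scale factor, channel count and sampling rate go to a
#' plain-text sidecar so the file is self-describing.
#'
#' @param block a `recording_block`.
#' @param path output path for the binary data; the sidecar is written to
#'   `paste0(path, ".cfg")`.
#' @param scale volts-per-count scale; if `NULL`, chosen so the absolute
#'   maximum maps to 30000 counts.
#' @return `path`, invisibly.
#' @export
write_recording <- function(block, path, scale = NULL) {
  stopifnot(inherits(block, "recording_block"))
  m <- block$samples
  if (is.null(scale)) {
    mx <- max(abs(m), 1e-12)
    scale <- mx / 30000
  }
  counts <- as.integer(round(t(m) / scale))  # interleaved: all channels of sample 1, ...
  counts <- pmax(pmin(counts, 32767L), -32768L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(counts, con, size = 2L, endian = "little")
  cfg <- c(
    sprintf("n_channels=%d", n_channels(block)),
    sprintf("sample_rate_hz=%.10g", block$sample_rate_hz),
    sprintf("scale=%.17g", scale),
    sprintf("channel_ids=%s", paste(block$channel_ids, collapse = ",")))
  writeLines(cfg, paste0(path, ".cfg"))
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path path to the flat binary file; the sidecar
#'   `paste0(path, ".cfg")` must exist.
#' @return A `recording_block`.
#' @export
read_recording <- function(path) {
  cfg_path <- paste0(path, ".cfg")
  if (!file.exists(cfg_path)) stop("sidecar config not found: ", cfg_path)
  kv <- strsplit(readLines(cfg_path), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  get <- function(k) vals[match(k, keys)]
  nch <- as.integer(get("n_channels"))
  rate <- as.numeric(get("sample_rate_hz"))
  scale <- as.numeric(get("scale"))
  ch_ids <- as.integer(strsplit(get("channel_ids"), ",")[[1]])
  n_bytes <- file.info(path)$size
  counts <- readBin(path, "integer", n = n_bytes / 2, size = 2L,
                    signed = TRUE, endian = "little")
  m <- matrix(counts * scale, ncol = nch, byrow = TRUE)
  recording_block(m, rate, ch_ids)
}

#' Write / read ground-truth spike events as CSV
#'
#' Columns: `neuron_id` (1-based), `spike_sample` (1-based sample index of the
#' template peak), `home_channel` (0-based probe channel id).
#'
#' @param truth a `ground_truth` object (see [render_recording()]).
#' @param path CSV path.
#' @return `path` (write) or a data frame (read), invisibly for write.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth$events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  ev <- utils::read.csv(path)
  structure(list(events = ev, templates = NULL), class = "ground_truth")
}

#' Write a sorting result as CSV
#'
#' Columns: `peak_sample`, `cluster_id`, `channel`.
#'
#' @param result a `sort_result`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_sort_result <- function(result, path) {
  utils::write.csv(result$records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sort_result
#' @export
read_sort_result <- function(path) {
  rec <- utils::read.csv(path)
  structure(list(records = rec, params = NULL, provenance = NULL),
            class = "sort_result")
}
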