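#' Continuous EEG recordings
#'
#' An `eeg_recording` holds a channels-by-samples matrix in microvolts, the
#' sampling rate, ordered channel labels, embedded stimulus markers
#' (0-based sample indices plus small integer codes), and the reference
#' label.
#'
#' @param data Numeric matrix, channels x samples, in uV.
#' @param rate_hz Sampling rate (samples/s).
#' @param channel_names Character vector, one label per row of `data`.
#' @param markers Data frame with columns `sample` (0-based index) and
#'   `code` (integer).
#' @param reference Reference label, e.g. `"FCz"` or `"common_average"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate_hz, channel_names,
                          markers = data.frame(sample = integer(0),
                                               code = integer(0)),
                          reference = "unknown") {
  data <- as.matrix(data)
  if (length(channel_names) != nrow(data)) {
    stop_invalid("channel_names length (%d) != number of rows (%d)",
                 length(channel_names), nrow(data))
  }
  if (rate_hz <= 0) stop_invalid("rate_hz must be positive")
  if (nrow(markers) > 0 &&
      (any(markers$sample < 0) || any(markers$sample >= ncol(data)))) {
    stop_invalid("marker sample indices must lie in [0, n_samples)")
  }
  rownames(data) <- channel_names
  structure(list(data = data, rate_hz = rate_hz,
                 channel_names = as.character(channel_names),
                 markers = markers, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), %d markers, ref=%s\n",
              nrow(x$data), ncol(x$data), x$rate_hz,
              ncol(x$data) / x$rate_hz, nrow(x$markers), x$reference))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An `eeg_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Extract one channel by label
#' @param rec An `eeg_recording`.
#' @param channel Channel label.
#' @return Numeric vector of samples.
#' @export
get_channel <- function(rec, channel) {
  i <- match(channel, rec$channel_names)
  if (is.na(i)) stop_invalid("channel '%s' not present", channel)
  rec$data[i, ]
}
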