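# --- filtering, referencing, artifact handling, epoching, pack reduction ----
#
# Fixed per-task order of operations:
#   filter -> (resample for the equalized pack) -> re-reference ->
#   muscular-artifact marking -> faulty-channel removal -> epoch ->
#   baseline -> threshold rejection
# Task filter bands: resting/active/passive 0.016-30 Hz, SSVEP 0.01-55 Hz,
# face 0.1-40 Hz; all with a 50 Hz notch.

#' Task filter settings
#' @param task Task name.
#' @return List with `low_hz`, `high_hz`, `notch_hz`.
#' @export
task_filter_settings <- function(task) {
  switch(task,
    resting = ,
    active_oddball = ,
    passive_oddball = list(low_hz = 0.016, high_hz = 30, notch_hz = 50),
    ssvep = list(low_hz = 0.01, high_hz = 55, notch_hz = 50),
    face = list(low_hz = 0.1, high_hz = 40, notch_hz = 50),
    stop_invalid("unknown task '%s'", task)
  )
}

filtfilt_mat <- function(data, flt) {
  t(apply(data, 1, function(x) signal::filtfilt(flt, x)))
}

#' Zero-phase band-pass plus notch filter
#'
#' Band-pass as a cascade of a 2nd-order Butterworth high-pass and a
#' 4th-order Butterworth low-pass, each applied forward-backward
#' (zero phase), followed by a 2-Hz-wide zero-phase Butterworth band-stop
#' at the notch frequency. When the high-pass cutoff is below one cycle
#' per record length the high-pass reduces to mean/linear detrending,
#' which is numerically equivalent at such cutoffs and avoids an
#' ill-conditioned recursion.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz High-pass cutoff (Hz).
#' @param high_hz Low-pass cutoff (Hz).
#' @param notch_hz Notch center (Hz), or `NULL` to skip.
#' @return The filtered recording.
#' @export
bandpass_notch <- function(rec, low_hz, high_hz, notch_hz = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate_hz / 2
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq)) {
    stop_invalid("need 0 < low (%g) < high (%g) < Nyquist (%g)",
                 low_hz, high_hz, nyq)
  }
  data <- rec$data
  n <- ncol(data)
  # DC removal always
  data <- data - rowMeans(data)
  if (low_hz >= rec$rate_hz / n) {
    hp <- signal::butter(2, low_hz / nyq, type = "high")
    data <- filtfilt_mat(data, hp)
  } else {
    # cutoff below the record's fundamental: linear detrend
    tt <- seq_len(n)
    data <- t(apply(data, 1, function(x) stats::lm.fit(cbind(1, tt), x)$residuals))
  }
  lp <- signal::butter(4, high_hz / nyq, type = "low")
  data <- filtfilt_mat(data, lp)
  if (!is.null(notch_hz) && notch_hz < nyq) {
    bs <- signal::butter(2, c(notch_hz - 1, notch_hz + 1) / nyq, type = "stop")
    data <- filtfilt_mat(data, bs)
  }
  rec$data <- data
  rec
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean across the retained channels.
#'
#' @param rec An [eeg_recording()].
#' @param exclude Channel labels excluded from the average (e.g. faulty
#'   electrodes); they are re-referenced but do not contribute to it.
#' @return The re-referenced recording with `reference = "common_average"`.
#' @export
rereference_common_average <- function(rec, exclude = character(0)) {
  stopifnot(inherits(rec, "eeg_recording"))
  keep <- !(rec$channel_names %in% exclude)
  if (sum(keep) < 2) stop_invalid("common average needs >= 2 retained channels")
  avg <- colMeans(rec$data[keep, , drop = FALSE])
  rec$data <- sweep(rec$data, 2, avg)
  rec$reference <- "common_average"
  rec
}

#' Downsample a recording
#'
#' Fourier-domain resampling: the spectrum of each channel is truncated at
#' the new Nyquist frequency and inverse-transformed on the target grid,
#' which acts as an ideal anti-alias low-pass. Markers are remapped to the
#' nearest target sample. Only downsampling is supported (rate
#' equalization across systems); duration is preserved within one sample.
#'
#' @param rec An [eeg_recording()].
#' @param target_hz Target rate (Hz), at most the current rate.
#' @return The resampled recording.
#' @export
resample_recording <- function(rec, target_hz) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_hz > rec$rate_hz) {
    stop_invalid("upsampling (%g -> %g Hz) is not supported",
                 rec$rate_hz, target_hz)
  }
  if (target_hz == rec$rate_hz) return(rec)
  n <- ncol(rec$data)
  m <- as.integer(round(n * target_hz / rec$rate_hz))
  new_data <- t(apply(rec$data, 1, resample_fft, m = m))
  markers <- rec$markers
  markers$sample <- pmin(m - 1L,
                         as.integer(round(markers$sample * target_hz / rec$rate_hz)))
  eeg_recording(new_data, target_hz, rec$channel_names, markers, rec$reference)
}

# spectrum-truncation resampling of one channel from n to m < n samples
resample_fft <- function(x, m) {
  n <- length(x)
  X <- stats::fft(x)
  half <- m %/% 2
  Y <- complex(m)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half >= 1) Y[(m - half + 1):m] <- X[(n - half + 1):n]
  if (m %% 2 == 0) Y[half + 1] <- Re(Y[half + 1])  # shared Nyquist bin
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Mark large muscular artifacts
#'
#' A span is marked on a channel wherever the peak-to-peak deflection
#' (max minus min) within a sliding window of `win_ms` exceeds
#' `amp_threshold_uv`; overlapping spans are merged.
#'
#' @param rec An [eeg_recording()].
#' @param amp_threshold_uv Peak-to-peak threshold (uV).
#' @param win_ms Sliding-window length (ms); the window slides per sample.
#' @return Named list (per channel) of data frames with 0-based
#'   `start_sample`, `end_sample` (half-open) spans.
#' @export
mark_muscular_artifacts <- function(rec, amp_threshold_uv = 500,
                                    win_ms = 800) {
  stopifnot(inherits(rec, "eeg_recording"),
            amp_threshold_uv > 0, win_ms > 0)
  w <- max(2L, ms_to_samples(win_ms, rec$rate_hz))
  n <- ncol(rec$data)
  out <- stats::setNames(vector("list", nrow(rec$data)), rec$channel_names)
  for (ch in seq_len(nrow(rec$data))) {
    x <- rec$data[ch, ]
    if (n < w) {
      ptp <- max(x) - min(x)
      spans <- if (ptp > amp_threshold_uv) {
        data.frame(start_sample = 0L, end_sample = n)
      } else {
        data.frame(start_sample = integer(0), end_sample = integer(0))
      }
      out[[ch]] <- spans
      next
    }
    hi <- sliding_max(x, w)
    lo <- -sliding_max(-x, w)
    bad <- which(hi - lo > amp_threshold_uv)  # window start indices (1-based)
    out[[ch]] <- merge_spans(bad - 1L, w, n)
  }
  out
}

# O(n) sliding maximum of window w (left-aligned), via per-block prefix
# and suffix cumulative maxima
sliding_max <- function(x, w) {
  n <- length(x)
  n_out <- n - w + 1
  m <- ceiling(n / w)
  pad <- m * w - n
  xp <- c(x, rep(-Inf, pad))
  mat <- matrix(xp, nrow = w)
  pre <- apply(mat, 2, cummax)                       # prefix max per block
  suf <- apply(mat[w:1, , drop = FALSE], 2, cummax)[w:1, , drop = FALSE]
  i <- seq_len(n_out)
  pmax(as.vector(suf)[i], as.vector(pre)[i + w - 1])
}

# merge overlapping [start, start + w) windows into disjoint spans
merge_spans <- function(starts0, w, n) {
  if (length(starts0) == 0) {
    return(data.frame(start_sample = integer(0), end_sample = integer(0)))
  }
  s <- starts0
  e <- pmin(s + w, n)
  breaks <- which(s[-1] > e[-length(e)])
  grp_start <- c(1, breaks + 1)
  grp_end <- c(breaks, length(s))
  data.frame(start_sample = s[grp_start], end_sample = e[grp_end])
}

#' Flag faulty electrodes from artifact coverage
#'
#' A channel is removed when its total artifact time exceeds
#' `max_fraction` of the recording. Removed channels are excluded from
#' referencing and averaging; they are never interpolated.
#'
#' @param rec An [eeg_recording()].
#' @param artifact_spans Output of [mark_muscular_artifacts()].
#' @param max_fraction Maximal tolerated artifact fraction.
#' @return List with `retained` and `removed` channel-label vectors and
#'   `fraction` (named numeric, artifact time fraction per channel).
#' @export
flag_faulty_electrodes <- function(rec, artifact_spans, max_fraction = 0.05) {
  n <- ncol(rec$data)
  if (n == 0) stop_invalid("zero-length recording")
  frac <- vapply(rec$channel_names, function(ch) {
    sp <- artifact_spans[[ch]]
    if (is.null(sp) || nrow(sp) == 0) return(0)
    sum(sp$end_sample - sp$start_sample) / n
  }, 0)
  removed <- rec$channel_names[frac > max_fraction]
  list(retained = setdiff(rec$channel_names, removed),
       removed = removed, fraction = frac)
}

#' Epoch sets
#'
#' An `epoch_set` holds trials x channels x samples windows cut around
#' event onsets, with per-trial labels, original trial indices, and
#' rejection flags. Time windows are half-open: `[tmin_ms, tmax_ms)`.
#'
#' @param rec An [eeg_recording()].
#' @param events An [event_sequence] (onsets in seconds); events whose
#'   window extends beyond the recording are dropped (count reported via
#'   the `n_dropped` attribute).
#' @param tmin_ms,tmax_ms Window relative to event onset (ms).
#' @return An `epoch_set`.
#' @export
epoch_recording <- function(rec, events, tmin_ms = -200, tmax_ms = 800) {
  stopifnot(inherits(rec, "eeg_recording"), tmax_ms > tmin_ms)
  rate <- rec$rate_hz
  n_samp <- as.integer(round((tmax_ms - tmin_ms) / 1000 * rate))
  onset_samp <- as.integer(round(events$events$onset_s * rate))
  offs <- ms_to_samples(tmin_ms, rate)
  # snap the window to the sample grid so reported epoch times are exact
  tmin_ms <- offs / rate * 1000
  tmax_ms <- (offs + n_samp) / rate * 1000
  start <- onset_samp + offs
  ok <- start >= 0 & (start + n_samp) <= ncol(rec$data)
  idx <- which(ok)
  arr <- array(0, dim = c(length(idx), nrow(rec$data), n_samp))
  for (k in seq_along(idx)) {
    s0 <- start[idx[k]]
    arr[k, , ] <- rec$data[, (s0 + 1):(s0 + n_samp), drop = FALSE]
  }
  structure(
    list(data = arr, tmin_ms = tmin_ms, tmax_ms = tmax_ms,
         labels = events$events$label[idx], trial_index = idx,
         rejected = rep(FALSE, length(idx)),
         reason = rep(NA_character_, length(idx)),
         n_trials_total = n_events(events),
         rate_hz = rate, channel_names = rec$channel_names),
    class = "epoch_set", n_dropped = sum(!ok)
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d ch x %d samples [%g, %g) ms @ %g Hz; %d rejected\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$tmin_ms, x$tmax_ms, x$rate_hz, sum(x$rejected)))
  invisible(x)
}

#' Time axis of an epoch set or waveform (ms)
#' @param x An `epoch_set` or `erp_waveform`.
#' @return Numeric vector of sample times (ms, half-open grid).
#' @export
epoch_times_ms <- function(x) {
  n <- if (inherits(x, "epoch_set")) dim(x$data)[3] else ncol(x$values)
  x$tmin_ms + (seq_len(n) - 1) * 1000 / x$rate_hz
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over
#' `[base_start_ms, base_end_ms)`.
#'
#' @param ep An `epoch_set`.
#' @param base_start_ms,base_end_ms Baseline window (ms relative to onset).
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(ep, base_start_ms = ep$tmin_ms,
                             base_end_ms = 0) {
  stopifnot(inherits(ep, "epoch_set"))
  tms <- epoch_times_ms(ep)
  sel <- tms >= base_start_ms & tms < base_end_ms
  if (!any(sel)) stop_invalid("empty baseline window [%g, %g)",
                              base_start_ms, base_end_ms)
  base <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - array(rep(base, dim(ep$data)[3]), dim = dim(ep$data))
  ep
}

#' Reject epochs with large deflections
#'
#' An epoch is rejected when any retained channel's peak-to-peak
#' deflection within the epoch strictly exceeds `threshold_uv`.
#'
#' @param ep An `epoch_set`.
#' @param threshold_uv Peak-to-peak threshold (uV).
#' @param channels Channels considered (default all); pass the retained
#'   list from [flag_faulty_electrodes()] to ignore removed electrodes.
#' @return The `epoch_set` with updated `rejected`/`reason`; the rejection
#'   fraction is available via `attr(, "rejection_fraction")`.
#' @export
reject_epochs <- function(ep, threshold_uv = 200,
                          channels = ep$channel_names) {
  stopifnot(inherits(ep, "epoch_set"), threshold_uv > 0)
  chi <- match(channels, ep$channel_names)
  chi <- chi[!is.na(chi)]
  n_tr <- dim(ep$data)[1]
  if (n_tr > 0 && length(chi) > 0) {
    sub <- ep$data[, chi, , drop = FALSE]
    ptp <- apply(sub, c(1, 2), function(x) max(x) - min(x))
    bad <- apply(ptp > threshold_uv, 1, any)
    newly <- bad & !ep$rejected
    ep$rejected <- ep$rejected | bad
    ep$reason[newly] <- "ptp_threshold"
  }
  attr(ep, "rejection_fraction") <- if (n_tr > 0) mean(ep$rejected) else 0
  ep
}

#' Dataset-reduction pack specifications
#'
#' `100a` is the full dataset equalized to 128 Hz; `100b` the full dataset
#' at native rates; `75`/`50` the first 75%/50% of trials at native rates.
#'
#' @param name One of `"100a"`, `"100b"`, `"75"`, `"50"`.
#' @return List with `name`, `fraction`, `rate_policy`.
#' @export
pack_spec <- function(name = c("100a", "100b", "75", "50")) {
  name <- match.arg(name)
  list(name = name,
       fraction = switch(name, `100a` = 1, `100b` = 1, `75` = 0.75, `50` = 0.5),
       rate_policy = if (name == "100a") "equalized_128" else "native")
}

#' Reduce a sequence or epoch set to a leading fraction of trials
#'
#' Retains the first `floor(fraction * n_trials)` trials in original order.
#'
#' @param x An [event_sequence] or `epoch_set`.
#' @param pack A [pack_spec()] (or one of its names).
#' @return Object of the same type, reduced.
#' @export
subset_pack <- function(x, pack) {
  if (is.character(pack)) pack <- pack_spec(pack)
  frac <- pack$fraction
  if (inherits(x, "event_sequence")) {
    keep <- floor(frac * n_events(x))
    x$events <- x$events[seq_len(keep), , drop = FALSE]
    if (keep > 0) {
      x$total_duration_s <- min(x$total_duration_s,
                                x$events$onset_s[keep] + x$events$duration_s[keep])
    } else {
      x$total_duration_s <- 0
    }
    return(x)
  }
  if (inherits(x, "epoch_set")) {
    # "first fraction of trials" counts original trials, not surviving epochs
    n_orig <- x$n_trials_total %||% max(x$trial_index, 0)
    keep_trials <- floor(frac * n_orig)
    sel <- x$trial_index <= keep_trials
    x$data <- x$data[sel, , , drop = FALSE]
    x$labels <- x$labels[sel]
    x$trial_index <- x$trial_index[sel]
    x$rejected <- x$rejected[sel]
    x$reason <- x$reason[sel]
    x$n_trials_total <- keep_trials
    return(x)
  }
  stop_invalid("subset_pack: unsupported type '%s'", class(x)[1])
}

#' Run the fixed preprocessing chain for one task
#'
#' filter -> (resample to 128 Hz if `pack` is `100a`) -> common-average
#' re-reference -> muscular-artifact marking -> faulty-electrode removal ->
#' epoch -> baseline -> rejection. Epoch windows: -200..800 ms with a
#' 200-ms baseline for the visual/active tasks; -50..560 ms with a 50-ms
#' baseline for the passive oddball.
#'
#' @param rec An [eeg_recording()].
#' @param events An [event_sequence].
#' @param pack A [pack_spec()] name.
#' @param amp_threshold_uv,artifact_win_ms,max_faulty_fraction,reject_uv
#'   Artifact-rule thresholds.
#' @return List with `epochs` (for ERP tasks) or `recording` (continuous
#'   tasks), `retained`/`removed` channels, `rejection_fraction`,
#'   `n_dropped_events`.
#' @export
preprocess_task <- function(rec, events, pack = "100a",
                            amp_threshold_uv = 500, artifact_win_ms = 800,
                            max_faulty_fraction = 0.05, reject_uv = 200) {
  pk <- pack_spec(pack)
  fs <- task_filter_settings(events$task)
  rec <- bandpass_notch(rec, fs$low_hz, fs$high_hz, fs$notch_hz)
  if (pk$rate_policy == "equalized_128" && rec$rate_hz > 128) {
    rec <- resample_recording(rec, 128)
    events <- events  # onsets are in seconds; unchanged
  }
  spans <- mark_muscular_artifacts(rec, amp_threshold_uv, artifact_win_ms)
  flags <- flag_faulty_electrodes(rec, spans, max_faulty_fraction)
  rec <- rereference_common_average(rec, exclude = flags$removed)

  if (events$task %in% c("resting", "ssvep")) {
    return(list(recording = rec, retained = flags$retained,
                removed = flags$removed, rejection_fraction = 0,
                n_dropped_events = 0))
  }
  win <- if (events$task == "passive_oddball") c(-50, 560) else c(-200, 800)
  base <- if (events$task == "passive_oddball") c(-50, 0) else c(-200, 0)
  events <- subset_pack(events, pk)
  ep <- epoch_recording(rec, events, win[1], win[2])
  ep <- baseline_correct(ep, base[1], base[2])
  ep <- reject_epochs(ep, reject_uv, channels = flags$retained)
  list(epochs = ep, retained = flags$retained, removed = flags$removed,
       rejection_fraction = attr(ep, "rejection_fraction"),
       n_dropped_events = attr(ep, "n_dropped"))
}
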