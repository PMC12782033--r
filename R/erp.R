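# --- ERP waveforms and component measures -----------------------------------

#' ERP waveform
#'
#' Channels-by-samples average of epochs, with its time axis and the
#' number of epochs averaged.
#'
#' @param values Matrix channels x samples (uV).
#' @param tmin_ms,tmax_ms Window (ms), half-open.
#' @param rate_hz Sampling rate.
#' @param channel_names Channel labels.
#' @param condition Condition label.
#' @param n_epochs_averaged Number of epochs behind the average.
#' @return An `erp_waveform` object.
#' @export
erp_waveform <- function(values, tmin_ms, tmax_ms, rate_hz, channel_names,
                         condition = NA_character_, n_epochs_averaged = 1L) {
  values <- as.matrix(values)
  if (n_epochs_averaged < 1) stop_invalid("n_epochs_averaged must be >= 1")
  rownames(values) <- channel_names
  structure(list(values = values, tmin_ms = tmin_ms, tmax_ms = tmax_ms,
                 rate_hz = rate_hz, channel_names = channel_names,
                 condition = condition,
                 n_epochs_averaged = as.integer(n_epochs_averaged)),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform> %s: %d ch x %d samples [%g, %g) ms, n=%d\n",
              x$condition, nrow(x$values), ncol(x$values),
              x$tmin_ms, x$tmax_ms, x$n_epochs_averaged))
  invisible(x)
}

# epochs entering a condition average, honoring the oddball exclusion rules
selected_epochs <- function(ep, label, exclude_post_deviant_standards = FALSE,
                            standards_pre_deviant_only = FALSE) {
  keep <- ep$labels == label & !ep$rejected
  if (label == "standard" &&
      (exclude_post_deviant_standards || standards_pre_deviant_only)) {
    is_dev <- ep$labels == "deviant"
    if (exclude_post_deviant_standards) {
      post_dev <- c(FALSE, is_dev[-length(is_dev)])
      keep <- keep & !post_dev
    }
    if (standards_pre_deviant_only) {
      pre_dev <- c(is_dev[-1], FALSE)
      keep <- keep & pre_dev
    }
  }
  which(keep)
}

#' Average epochs of one condition
#'
#' For oddball tasks the standard average can exclude standards
#' immediately following a deviant (active oddball) or keep only standards
#' immediately preceding a deviant (passive oddball / MMN convention).
#'
#' @param ep An `epoch_set`.
#' @param label Condition label to average.
#' @param exclude_post_deviant_standards Drop standards that directly
#'   follow a deviant.
#' @param standards_pre_deviant_only Keep only standards that directly
#'   precede a deviant.
#' @return An [erp_waveform()].
#' @export
average_condition <- function(ep, label,
                              exclude_post_deviant_standards = FALSE,
                              standards_pre_deviant_only = FALSE) {
  stopifnot(inherits(ep, "epoch_set"))
  idx <- selected_epochs(ep, label, exclude_post_deviant_standards,
                         standards_pre_deviant_only)
  if (length(idx) == 0) {
    stop_invalid("no retained '%s' epochs after exclusions", label)
  }
  vals <- apply(ep$data[idx, , , drop = FALSE], c(2, 3), mean)
  erp_waveform(vals, ep$tmin_ms, ep$tmax_ms, ep$rate_hz, ep$channel_names,
               condition = label, n_epochs_averaged = length(idx))
}

#' Deviant-minus-standard difference wave
#'
#' @param dev,std `erp_waveform`s on matching time axes and channels.
#' @return An `erp_waveform` of the pointwise difference.
#' @export
difference_wave <- function(dev, std) {
  stopifnot(inherits(dev, "erp_waveform"), inherits(std, "erp_waveform"))
  if (!isTRUE(all.equal(c(dev$tmin_ms, dev$tmax_ms, dev$rate_hz),
                        c(std$tmin_ms, std$tmax_ms, std$rate_hz))) ||
      !identical(dev$channel_names, std$channel_names)) {
    stop_invalid("difference_wave: waveforms must share time axis and channels")
  }
  erp_waveform(dev$values - std$values, dev$tmin_ms, dev$tmax_ms,
               dev$rate_hz, dev$channel_names,
               condition = paste0(dev$condition, "-", std$condition),
               n_epochs_averaged = min(dev$n_epochs_averaged,
                                       std$n_epochs_averaged))
}

#' Unweighted grand average across participants
#'
#' @param waves List of `erp_waveform`s on a common grid.
#' @return An `erp_waveform`.
#' @export
grand_average <- function(waves) {
  stopifnot(length(waves) >= 1)
  w1 <- waves[[1]]
  vals <- Reduce(`+`, lapply(waves, `[[`, "values")) / length(waves)
  erp_waveform(vals, w1$tmin_ms, w1$tmax_ms, w1$rate_hz, w1$channel_names,
               condition = w1$condition, n_epochs_averaged = length(waves))
}

#' Locate a peak in a search window
#'
#' Single-sample extremum: the most negative (`polarity = "negative"`) or
#' most positive (`"positive"`) voltage within the half-open window
#' `[window_ms[1], window_ms[2])`; ties go to the earlier sample.
#'
#' @param w An `erp_waveform`.
#' @param electrode Channel label.
#' @param window_ms Length-2 search window (ms).
#' @param polarity `"negative"` or `"positive"`.
#' @return List (class `peak_measure`) with `component`-free fields
#'   `electrode`, `latency_ms`, `amplitude_uv`, `search_window_ms`,
#'   `polarity`.
#' @export
find_peak <- function(w, electrode, window_ms,
                      polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(w, "erp_waveform"))
  row <- match(electrode, w$channel_names)
  if (is.na(row)) stop_invalid("electrode '%s' not in waveform", electrode)
  tms <- epoch_times_ms(w)
  sel <- which(tms >= window_ms[1] & tms < window_ms[2])
  if (length(sel) == 0) stop_invalid("empty search window [%g, %g) ms",
                                     window_ms[1], window_ms[2])
  x <- w$values[row, sel]
  i <- if (polarity == "negative") which.min(x) else which.max(x)
  structure(list(electrode = electrode, latency_ms = tms[sel[i]],
                 amplitude_uv = x[i], search_window_ms = window_ms,
                 polarity = polarity),
            class = "peak_measure")
}

#' P100-N170 peak-to-peak amplitude
#'
#' @param p100 A positive-polarity `peak_measure`.
#' @param n170 A negative-polarity `peak_measure` at the same electrode.
#' @return Scalar peak-to-peak amplitude (uV), P100 minus N170.
#' @export
p2p_amplitude <- function(p100, n170) {
  stopifnot(inherits(p100, "peak_measure"), inherits(n170, "peak_measure"))
  if (!identical(p100$electrode, n170$electrode)) {
    stop_invalid("P2P requires both peaks at the same electrode")
  }
  if (p100$polarity != "positive" || n170$polarity != "negative") {
    stop_invalid("P2P expects a positive and a negative peak")
  }
  p100$amplitude_uv - n170$amplitude_uv
}

#' Integration window centered on the MMN peak
#'
#' The window center is the mean of the Fz and Cz grand-average peak
#' latencies; the window extends `half_width_ms` on each side (50 ms
#' total by default). With a single usable electrode its latency is the
#' center.
#'
#' @param lat_fz_ms,lat_cz_ms Grand-average MMN peak latencies (ms); one
#'   may be `NA`.
#' @param half_width_ms Half width (ms).
#' @return Named numeric vector `c(center, start, end)` in ms.
#' @export
mmn_window <- function(lat_fz_ms, lat_cz_ms, half_width_ms = 25) {
  lats <- c(lat_fz_ms, lat_cz_ms)
  if (all(is.na(lats))) stop_invalid("at least one latency is required")
  center <- mean(lats, na.rm = TRUE)
  c(center = center, start = center - half_width_ms,
    end = center + half_width_ms)
}

#' Signed area under the curve
#'
#' Trapezoidal integral of the voltage over a time window, reported in
#' nV.s (1 uV.ms = 1 nV.s). The sign carries the component polarity
#' (negative for a fronto-central MMN).
#'
#' @param w An `erp_waveform`.
#' @param electrode Channel label.
#' @param window_ms Length-2 integration window (ms), inclusive of both
#'   endpoints on the sample grid.
#' @return Scalar signed area (nV.s).
#' @export
erp_auc <- function(w, electrode, window_ms) {
  stopifnot(inherits(w, "erp_waveform"))
  row <- match(electrode, w$channel_names)
  if (is.na(row)) stop_invalid("electrode '%s' not in waveform", electrode)
  tms <- epoch_times_ms(w)
  if (window_ms[1] < w$tmin_ms - 1e-9 || window_ms[2] > max(tms) + 1e-9) {
    stop_invalid("window [%g, %g] outside waveform span", window_ms[1],
                 window_ms[2])
  }
  sel <- which(tms >= window_ms[1] - 1e-9 & tms <= window_ms[2] + 1e-9)
  if (length(sel) < 2) stop_invalid("window too narrow for integration")
  x <- w$values[row, sel]
  t <- tms[sel]
  # fractional edge segments: evaluate the linear interpolant exactly at
  # the window endpoints so the integral covers the full window length
  if (t[1] > window_ms[1] + 1e-9 && sel[1] > 1) {
    x0 <- stats::approx(tms, w$values[row, ], xout = window_ms[1])$y
    t <- c(window_ms[1], t); x <- c(x0, x)
  }
  nlast <- sel[length(sel)]
  if (t[length(t)] < window_ms[2] - 1e-9 && nlast < length(tms)) {
    x1 <- stats::approx(tms, w$values[row, ], xout = window_ms[2])$y
    t <- c(t, window_ms[2]); x <- c(x, x1)
  }
  sum(diff(t) * (utils::head(x, -1) + utils::tail(x, -1)) / 2)  # uV.ms = nV.s
}

#' Per-system component search windows
#'
#' Benchmark presets: N170 120-160 ms (LA/BA) or 100-140 ms (EM); P100
#' 80-120 / 60-100 ms; N200 200-280 ms and P300 280-420 ms for all
#' systems; MMN searched in 100-250 ms.
#'
#' @param component One of `"P100"`, `"N170"`, `"N200"`, `"P300"`,
#'   `"MMN"`.
#' @param system System name (`"EM"`, `"LA"`, `"BA"`); only P100/N170
#'   windows depend on it.
#' @return Length-2 numeric window (ms).
#' @export
component_window <- function(component, system = "BA") {
  em <- identical(system, "EM")
  switch(component,
    P100 = if (em) c(60, 100) else c(80, 120),
    N170 = if (em) c(100, 140) else c(120, 160),
    N200 = c(200, 280),
    P300 = c(280, 420),
    MMN = c(100, 250),
    stop_invalid("unknown component '%s'", component)
  )
}
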