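# --- synthetic continuous EEG -----------------------------------------------
#
# Signal model per channel, sampled at the system rate:
#   x = attenuation * (alpha + ssvep + sum of evoked templates) + noise
# where noise is 1/f (power exponent 1) spectrally-shaped Gaussian noise
# scaled to noise_sd_uv * noise_scale, alpha is a 10 Hz oscillation on the
# occipital channels whose amplitude is multiplied by alpha_ec_gain during
# eyes-closed blocks, ssvep adds the block fundamental plus two harmonics on
# the occipital channels, and templates are Gaussian-windowed half-sinusoids
# added at each eliciting event (shifted by the system latency).

# 1/f amplitude-shaped Gaussian noise, one channel per row, rescaled so each
# row has standard deviation sd_uv
one_over_f_noise <- function(n_ch, n, rate_hz, sd_uv, exponent = 1) {
  if (sd_uv <= 0 || n == 0) return(matrix(0, n_ch, n))
  if (n < 4) return(matrix(stats::rnorm(n_ch * n, 0, sd_uv), n_ch, n))
  out <- matrix(0, n_ch, n)
  freqs <- seq(0, rate_hz / 2, length.out = floor(n / 2) + 1)
  shape <- c(0, 1 / freqs[-1]^(exponent / 2))  # amplitude ~ f^(-1/2) for power 1/f
  for (ch in seq_len(n_ch)) {
    white <- stats::rnorm(n)
    spec <- stats::fft(white)
    half <- shape
    full <- c(half, rev(half[2:(n - length(half) + 1)]))
    x <- Re(stats::fft(spec * full, inverse = TRUE)) / n
    out[ch, ] <- x / stats::sd(x) * sd_uv
  }
  out
}

# template waveform sampled on the recording grid: half-sinusoid lobe of
# given width, tapered by a Gaussian window (sigma = width/4), peak = 1 at
# the center sample
template_kernel <- function(width_ms, rate_hz) {
  w <- width_ms / 1000
  t <- seq(-w / 2, w / 2, by = 1 / rate_hz)
  lobe <- cos(pi * t / w)          # 1 at center, 0 at +/- w/2
  taper <- exp(-0.5 * (t / (w / 4))^2)
  lobe * taper / max(lobe * taper)
}

#' Synthesize a continuous recording for one task and one system
#'
#' Builds a multichannel recording at the system's sampling rate embedding
#' the ground-truth effects appropriate for the task, then applies the
#' system's imperfections: overall attenuation, latency shift of evoked
#' responses, noise scaling, Bernoulli trigger dropout, and faulty
#' channels (signal zeroed, high-variance noise added).
#'
#' @param events An [event_sequence] (defines the task and markers).
#' @param profile A [system_profile()].
#' @param truth A [ground_truth()].
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   recordings.
#' @param pad_s Seconds of signal appended after the last event (room for
#'   the last epoch window).
#' @return An [eeg_recording()] with attributes `lost_triggers` (markers
#'   dropped), `faulty_channels` (labels) recording the simulated defects.
#' @export
synthesize_recording <- function(events, profile, truth, seed = 1,
                                 pad_s = 1) {
  stopifnot(inherits(events, "event_sequence"),
            inherits(profile, "system_profile"),
            inherits(truth, "ground_truth"))
  rate <- profile$rate_hz
  if (events$task == "ssvep") {
    fmax <- 3 * max(vapply(names(truth$ssvep_amps), as.numeric, 0))
    if (any(unlist(truth$ssvep_amps) > 0) && fmax >= rate / 2) {
      stop_invalid("rate %g Hz too low for requested harmonic %g Hz", rate, fmax)
    }
  }
  n <- max(1L, as.integer(ceiling((events$total_duration_s + pad_s) * rate)))
  chans <- default_montage(profile$n_channels)
  n_ch <- profile$n_channels
  tt <- (seq_len(n) - 1) / rate

  with_seed(seed, {
    sig <- matrix(0, n_ch, n)
    occ <- which(chans %in% c("O1", "Oz", "O2"))

    # occipital alpha with EO/EC amplitude modulation
    if (truth$alpha_base_uv > 0 && length(occ) > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      alpha <- truth$alpha_base_uv * sin(2 * pi * truth$alpha_freq_hz * tt + phase)
      gain <- rep(1, n)
      if (events$task == "resting" && !is.null(events$blocks)) {
        for (b in seq_len(nrow(events$blocks))) {
          if (events$blocks$label[b] == "EC") {
            i0 <- floor(events$blocks$start_s[b] * rate) + 1
            i1 <- min(n, ceiling(events$blocks$end_s[b] * rate))
            gain[i0:i1] <- truth$alpha_ec_gain
          }
        }
      }
      for (ch in occ) sig[ch, ] <- sig[ch, ] + alpha * gain
    }

    # flicker response: fundamental + two harmonics during each block
    if (events$task == "ssvep" && !is.null(events$blocks) && length(occ) > 0) {
      for (b in seq_len(nrow(events$blocks))) {
        f0 <- events$blocks$freq_hz[b]
        amps <- truth$ssvep_amps[[as.character(f0)]]
        if (is.null(amps)) amps <- c(0, 0, 0)
        i0 <- floor(events$blocks$start_s[b] * rate) + 1
        i1 <- min(n, ceiling(events$blocks$end_s[b] * rate))
        idx <- i0:i1
        resp <- rep(0, length(idx))
        for (h in seq_along(amps)) {
          if (h * f0 < rate / 2 && amps[h] > 0) {
            resp <- resp + amps[h] * sin(2 * pi * h * f0 * (tt[idx] - tt[idx[1]]))
          }
        }
        for (ch in occ) sig[ch, idx] <- sig[ch, idx] + resp
      }
    }

    # evoked templates at event onsets, shifted by the system latency
    templ <- Filter(function(tp) is.null(tp$task) || tp$task == events$task,
                    truth$erp_templates)
    for (tp in templ) {
      kern <- template_kernel(tp$width_ms, rate)
      half <- (length(kern) - 1) %/% 2
      rows <- match(names(tp$electrodes), chans)
      keep <- !is.na(rows)
      rows <- rows[keep]; wts <- unname(tp$electrodes)[keep]
      if (length(rows) == 0) next
      lat_s <- (tp$latency_ms + profile$latency_shift_ms) / 1000
      for (k in seq_len(n_events(events))) {
        g <- tp$label_gain[events$events$label[k]]
        if (is.na(g) || g == 0) next
        center <- as.integer(round((events$events$onset_s[k] + lat_s) * rate)) + 1L
        i0 <- center - half; i1 <- center + half
        k0 <- max(1L, i0); k1 <- min(n, i1)
        if (k0 > k1) next
        seg <- kern[(k0 - i0 + 1):(k1 - i0 + 1)] * tp$amplitude_uv * g
        for (j in seq_along(rows)) {
          sig[rows[j], k0:k1] <- sig[rows[j], k0:k1] + seg * wts[j]
        }
      }
    }

    sig <- sig * profile$attenuation
    noise_sd <- truth$noise_sd_uv * profile$noise_scale
    if (noise_sd > 0) sig <- sig + one_over_f_noise(n_ch, n, rate, noise_sd)

    # blink-like frontal transients (off by default)
    if (truth$blink_rate_hz > 0) {
      frontal <- which(chans %in% c("Fp1", "Fp2", "Fz", "F3", "F4"))
      n_blink <- stats::rpois(1, truth$blink_rate_hz * n / rate)
      if (n_blink > 0 && length(frontal) > 0) {
        kern <- 150 * template_kernel(300, rate)
        half <- (length(kern) - 1) %/% 2
        centers <- sort(sample.int(n, n_blink))
        for (c0 in centers) {
          k0 <- max(1L, c0 - half); k1 <- min(n, c0 + half)
          seg <- kern[(k0 - (c0 - half) + 1):(k1 - (c0 - half) + 1)]
          for (ch in frontal) sig[ch, k0:k1] <- sig[ch, k0:k1] + seg
        }
      }
    }

    # faulty channels: signal replaced by broadband high-amplitude noise,
    # large enough to stay above the muscular-artifact threshold even
    # after band-pass filtering
    faulty <- which(stats::runif(n_ch) < profile$faulty_channel_prob)
    for (ch in faulty) sig[ch, ] <- stats::rnorm(n, 0, 500)

    # markers with Bernoulli dropout
    samp <- as.integer(round(events$events$onset_s * rate))
    keep <- samp < n
    samp <- samp[keep]
    codes <- events$events$code[keep]
    dropped <- stats::runif(length(samp)) < profile$trigger_loss_prob
    markers <- data.frame(sample = samp[!dropped], code = codes[!dropped])

    rec <- eeg_recording(sig, rate, chans, markers, reference = "FCz")
    attr(rec, "lost_triggers") <- sum(dropped)
    attr(rec, "faulty_channels") <- chans[faulty]
    rec
  })
}
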