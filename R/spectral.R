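# --- resting-state alpha power and SSVEP SNR spectra ------------------------

#' Morlet wavelet time-frequency power
#'
#' Convolves each channel with L2-normalized complex Morlet wavelets
#' (default 7 cycles at every frequency) and returns squared magnitude.
#' Samples closer to an edge than half the wavelet length are flagged and
#' excluded from [alpha_band_power()] averages.
#'
#' @param segment Numeric matrix (channels x samples) or vector, in uV.
#' @param rate_hz Sampling rate.
#' @param freqs_hz Analysis frequencies (Hz), default 1-40.
#' @param n_cycles Wavelet width in cycles.
#' @return Array `freq x channel x time` of power, with attributes `freqs_hz`
#'   and `valid` (logical matrix freq x time, FALSE inside edge zones).
#' @export
morlet_power <- function(segment, rate_hz, freqs_hz = 1:40, n_cycles = 7) {
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1)
  n <- ncol(segment); n_ch <- nrow(segment)
  if (any(freqs_hz <= 0)) stop_invalid("frequencies must be positive")
  longest <- ceiling(n_cycles / min(freqs_hz) * rate_hz)
  if (n < longest) {
    stop_invalid("segment (%d samples) shorter than the longest wavelet (%d)",
                 n, longest)
  }
  nf <- length(freqs_hz)
  pow <- array(0, dim = c(nf, n_ch, n))
  valid <- matrix(TRUE, nf, n)
  nfft <- stats::nextn(2 * n, 2)
  seg_fft <- apply(segment, 1, function(x) stats::fft(c(x, rep(0, nfft - n))))
  for (fi in seq_len(nf)) {
    f <- freqs_hz[fi]
    sigma_t <- n_cycles / (2 * pi * f)
    half <- ceiling(3.5 * sigma_t * rate_hz)
    t <- (-half:half) / rate_hz
    w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
    w <- w / sqrt(sum(Mod(w)^2))            # L2 normalization
    wf <- stats::fft(c(w, rep(0, nfft - length(w))))
    for (ch in seq_len(n_ch)) {
      conv <- stats::fft(seg_fft[, ch] * wf, inverse = TRUE) / nfft
      # 'same' alignment: wavelet center at each sample
      pow[fi, ch, ] <- Mod(conv[(half + 1):(half + n)])^2
    }
    edge <- min(n, half)
    if (edge > 0) {
      valid[fi, seq_len(edge)] <- FALSE
      valid[fi, (n - edge + 1):n] <- FALSE
    }
  }
  attr(pow, "freqs_hz") <- freqs_hz
  attr(pow, "valid") <- valid
  pow
}

#' Band power from a Morlet decomposition
#'
#' Mean power over a frequency band and the valid (non-edge) time samples,
#' computed per channel first and then averaged across channels.
#'
#' @param pow Output of [morlet_power()].
#' @param band_hz Length-2 band (Hz), default the alpha band 8.5-12.7 Hz.
#' @return Scalar mean power (uV^2).
#' @export
alpha_band_power <- function(pow, band_hz = c(8.5, 12.7)) {
  freqs <- attr(pow, "freqs_hz")
  valid <- attr(pow, "valid")
  sel <- which(freqs >= band_hz[1] & freqs <= band_hz[2])
  if (length(sel) == 0) stop_invalid("no analysis frequencies inside band")
  vals <- vapply(seq_len(dim(pow)[2]), function(ch) {
    mean(vapply(sel, function(fi) mean(pow[fi, ch, valid[fi, ]]), 0))
  }, 0)
  mean(vals)
}

#' Alpha power for one resting-state condition
#'
#' Computes Morlet power per segment at the occipital electrodes, extracts
#' the alpha band, and averages over electrodes then over segments
#' (power -> electrode mean -> segment mean).
#'
#' @param rec A preprocessed [eeg_recording()].
#' @param blocks Data frame of block spans (`label`, `start_s`, `end_s`)
#'   as produced by [gen_resting_events()].
#' @param condition `"EO"` or `"EC"`.
#' @param electrodes Channels to average over.
#' @param band_hz Alpha band (Hz).
#' @param freqs_hz Morlet analysis grid.
#' @param fraction Leading fraction of each segment to use (dataset
#'   reduction for the continuous tasks).
#' @return Scalar mean alpha power (uV^2).
#' @export
condition_alpha_power <- function(rec, blocks, condition,
                                  electrodes = c("O1", "Oz", "O2"),
                                  band_hz = c(8.5, 12.7),
                                  freqs_hz = seq(4, 30, by = 0.5),
                                  fraction = 1) {
  rows <- match(electrodes, rec$channel_names)
  rows <- rows[!is.na(rows)]
  if (length(rows) == 0) stop_invalid("no occipital electrodes present")
  bl <- blocks[blocks$label == condition, , drop = FALSE]
  if (nrow(bl) == 0) stop_invalid("no %s blocks", condition)
  seg_powers <- vapply(seq_len(nrow(bl)), function(b) {
    len <- (bl$end_s[b] - bl$start_s[b]) * fraction
    i0 <- floor(bl$start_s[b] * rec$rate_hz) + 1
    i1 <- min(ncol(rec$data), floor((bl$start_s[b] + len) * rec$rate_hz))
    seg <- rec$data[rows, i0:i1, drop = FALSE]
    alpha_band_power(morlet_power(seg, rec$rate_hz, freqs_hz), band_hz)
  }, 0)
  mean(seg_powers)
}

#' Berger effect: eyes-closed minus eyes-open alpha power
#'
#' Positive when occipital alpha power increases with closed eyes.
#'
#' @param ec_power,eo_power Mean alpha band power (uV^2) for the EC and EO
#'   conditions.
#' @return Scalar difference EC - EO (uV^2).
#' @export
berger_effect <- function(ec_power, eo_power) {
  as.numeric(ec_power) - as.numeric(eo_power)
}

#' Hanning-windowed amplitude spectrum
#'
#' Applies a Hann window per channel, zero-pads to reach the requested
#' frequency resolution when the natural resolution is coarser, and
#' corrects amplitudes for the window's coherent gain so a sinusoid of
#' amplitude A yields a peak of about A. Channel spectra are averaged.
#'
#' @param segment Matrix (channels x samples) or vector, in uV.
#' @param rate_hz Sampling rate.
#' @param resolution_hz Target bin spacing (Hz).
#' @return A `spectrum_amp` object: list with `freqs_hz`, `amplitude`,
#'   `resolution_hz`, `electrodes`.
#' @export
fft_amplitude_spectrum <- function(segment, rate_hz, resolution_hz = 0.05) {
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1)
  n <- ncol(segment)
  if (n == 0) stop_invalid("empty segment")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))  # Hann
  target_nfft <- as.integer(round(rate_hz / resolution_hz))
  nfft <- max(n, target_nfft)
  amp <- 0
  for (ch in seq_len(nrow(segment))) {
    xw <- segment[ch, ] * w
    spec <- stats::fft(c(xw, rep(0, nfft - n)))
    amp <- amp + 2 * Mod(spec[seq_len(floor(nfft / 2) + 1)]) / sum(w)
  }
  amp <- amp / nrow(segment)
  freqs <- (seq_along(amp) - 1) * rate_hz / nfft
  if (nfft > target_nfft) {
    # natural grid finer than requested: regrid onto the target spacing
    grid <- seq(0, rate_hz / 2, by = resolution_hz)
    amp <- stats::approx(freqs, amp, xout = grid, rule = 2)$y
    freqs <- grid
  }
  structure(list(freqs_hz = freqs, amplitude = amp,
                 resolution_hz = freqs[2] - freqs[1],
                 electrodes = rownames(segment)),
            class = "spectrum_amp")
}

#' Neighbor-bin SNR spectrum
#'
#' The SNR at bin k is its amplitude divided by the mean amplitude of the
#' `n_side` bins on each side after excluding the `n_exclude/2` immediate
#' neighbors on each side (defaults: 20 surrounding bins, 10 per side,
#' excluding the two immediate neighbors). Bins whose neighborhood crosses
#' the spectrum edge use the available one-sided bins; zero-amplitude
#' neighborhoods give `NA`.
#'
#' @param spec A `spectrum_amp` from [fft_amplitude_spectrum()].
#' @param n_side Neighbor bins per side.
#' @param n_exclude Total immediate neighbors excluded (split across
#'   sides).
#' @return Numeric vector of per-bin SNR values (same length as the
#'   spectrum) with attribute `freqs_hz`.
#' @export
snr_spectrum <- function(spec, n_side = 10, n_exclude = 2) {
  amp <- spec$amplitude
  n <- length(amp)
  excl <- n_exclude %/% 2
  offs <- (excl + 1):(excl + n_side)
  if (n < max(offs) + 1) {
    stop_invalid("spectrum too short (%d bins) for the neighborhood", n)
  }
  # sliding-sum formulation: neighborhood sum = (window of radius
  # excl + n_side) minus (window of radius excl), each clipped to the
  # spectrum, which reproduces the one-sided edge handling exactly
  cs <- cumsum(c(0, amp))
  k <- seq_len(n)
  winsum <- function(r) cs[pmin(n, k + r) + 1] - cs[pmax(0, k - r - 1) + 1]
  wincount <- function(r) pmin(n, k + r) - pmax(1, k - r) + 1
  r_out <- excl + n_side
  denom_sum <- winsum(r_out) - winsum(excl)
  denom_n <- wincount(r_out) - wincount(excl)
  denom <- denom_sum / denom_n
  snr <- ifelse(denom > 0, amp / denom, NA_real_)
  attr(snr, "freqs_hz") <- spec$freqs_hz
  snr
}

#' Pooled SNR at a fundamental and its first two harmonics
#'
#' Mean of the SNR at `f0`, `2*f0`, ..., `n_harmonics*f0` (nearest bins):
#' 6, 12, 18 Hz for the 6 Hz condition; 10, 20, 30 Hz for 10 Hz; 15, 30,
#' 45 Hz for 15 Hz.
#'
#' @param snr SNR vector from [snr_spectrum()] (carries `freqs_hz`).
#' @param f0_hz Fundamental frequency (Hz).
#' @param n_harmonics Number of pooled components including the
#'   fundamental.
#' @return Scalar pooled SNR.
#' @export
pooled_harmonic_snr <- function(snr, f0_hz, n_harmonics = 3) {
  freqs <- attr(snr, "freqs_hz")
  targets <- f0_hz * seq_len(n_harmonics)
  if (max(targets) > max(freqs)) {
    stop_invalid("harmonic %g Hz outside the spectrum (max %g Hz)",
                 max(targets), max(freqs))
  }
  idx <- vapply(targets, function(f) which.min(abs(freqs - f)), 0L)
  mean(snr[idx])
}

#' SSVEP condition SNR from a preprocessed recording
#'
#' Averages the amplitude spectra of the condition's flicker segments
#' (Hann window, common frequency grid) over segments and occipital
#' electrodes, converts to an SNR spectrum, and pools the fundamental with
#' its first two harmonics.
#'
#' @param rec A preprocessed [eeg_recording()].
#' @param blocks SSVEP block table (`freq_hz`, `start_s`, `end_s`) from
#'   [gen_ssvep_events()].
#' @param f0_hz Condition fundamental (Hz).
#' @param electrodes Channels averaged over.
#' @param resolution_hz Spectrum bin spacing.
#' @param fraction Leading fraction of each segment used.
#' @return Scalar pooled harmonic SNR, with the full SNR vector as
#'   attribute `snr`.
#' @export
ssvep_condition_snr <- function(rec, blocks, f0_hz,
                                electrodes = c("O1", "Oz", "O2"),
                                resolution_hz = 0.05, fraction = 1) {
  rows <- match(electrodes, rec$channel_names)
  rows <- rows[!is.na(rows)]
  if (length(rows) == 0) stop_invalid("no occipital electrodes present")
  bl <- blocks[abs(blocks$freq_hz - f0_hz) < 1e-9, , drop = FALSE]
  if (nrow(bl) == 0) stop_invalid("no %g Hz blocks", f0_hz)
  # equal-length truncation so spectra share one frequency grid
  len_s <- min((bl$end_s - bl$start_s) * fraction)
  specs <- lapply(seq_len(nrow(bl)), function(b) {
    i0 <- floor(bl$start_s[b] * rec$rate_hz) + 1
    i1 <- min(ncol(rec$data), i0 + round(len_s * rec$rate_hz) - 1)
    fft_amplitude_spectrum(rec$data[rows, i0:i1, drop = FALSE],
                           rec$rate_hz, resolution_hz)
  })
  avg <- specs[[1]]
  if (length(specs) > 1) {
    avg$amplitude <- rowMeans(vapply(specs, `[[`, avg$amplitude, "amplitude"))
  }
  snr <- snr_spectrum(avg)
  out <- pooled_harmonic_snr(snr, f0_hz)
  attr(out, "snr") <- snr
  out
}
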