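#' Virtual acquisition-system profiles
#'
#' A `system_profile` parameterizes one virtual EEG system: its sampling
#' rate, overall signal gain (attenuation), trigger latency shift, noise
#' multiplier, trigger-loss probability and per-channel fault probability.
#'
#' @param name System label.
#' @param rate_hz Sampling rate in Hz.
#' @param attenuation Gain applied to all neural signal components, in
#'   (0, 1].
#' @param latency_shift_ms Signed shift (ms) applied to evoked-response
#'   latencies relative to the recorded markers; negative values make
#'   components appear earlier.
#' @param noise_scale Multiplier on the background-noise standard deviation.
#' @param trigger_loss_prob Per-event probability that a marker is dropped.
#' @param faulty_channel_prob Per-channel probability of a faulty (flat +
#'   high noise) electrode.
#' @param n_channels Number of channels.
#' @return A `system_profile` object.
#' @export
system_profile <- function(name, rate_hz, attenuation = 1,
                           latency_shift_ms = 0, noise_scale = 1,
                           trigger_loss_prob = 0, faulty_channel_prob = 0,
                           n_channels = 32) {
  if (rate_hz <= 0) stop_invalid("rate_hz must be positive")
  if (attenuation <= 0 || attenuation > 1) {
    stop_invalid("attenuation must be in (0, 1]")
  }
  for (p in c(trigger_loss_prob, faulty_channel_prob)) {
    if (p < 0 || p > 1) stop_invalid("probabilities must be in [0, 1]")
  }
  structure(list(name = name, rate_hz = rate_hz, attenuation = attenuation,
                 latency_shift_ms = latency_shift_ms,
                 noise_scale = noise_scale,
                 trigger_loss_prob = trigger_loss_prob,
                 faulty_channel_prob = faulty_channel_prob,
                 n_channels = as.integer(n_channels)),
            class = "system_profile")
}

#' The three benchmark system presets
#'
#' `EM`: 128 Hz consumer-grade wireless system with attenuated signal,
#' shortened latencies, higher noise, occasional trigger loss and faulty
#' channels. `LA`: 500 Hz portable research-grade system. `BA`: 250 Hz
#' wired research-grade system (reference quality).
#'
#' @param n_channels Channels per system (default 32; smaller montages keep
#'   the benchmark's measurement sites).
#' @return Named list of three `system_profile` objects.
#' @export
system_presets <- function(n_channels = 32) {
  list(
    EM = system_profile("EM", 128, attenuation = 0.6, latency_shift_ms = -20,
                        noise_scale = 1.5, trigger_loss_prob = 0.01,
                        faulty_channel_prob = 0.05, n_channels = n_channels),
    LA = system_profile("LA", 500, attenuation = 0.95, latency_shift_ms = 0,
                        noise_scale = 1.0, trigger_loss_prob = 0.0005,
                        faulty_channel_prob = 0.002, n_channels = n_channels),
    BA = system_profile("BA", 250, attenuation = 1.0, latency_shift_ms = 0,
                        noise_scale = 1.0, trigger_loss_prob = 0,
                        faulty_channel_prob = 0, n_channels = n_channels)
  )
}

#' Read / write system profiles as YAML
#'
#' @param profiles Named list of `system_profile` objects.
#' @param path YAML file path.
#' @return `read_system_profiles` returns a named list of profiles;
#'   `write_system_profiles` returns `path` invisibly.
#' @export
write_system_profiles <- function(profiles, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_invalid("the 'yaml' package is required for YAML profile I/O")
  }
  yaml::write_yaml(lapply(profiles, unclass), path)
  invisible(path)
}

#' @rdname write_system_profiles
#' @export
read_system_profiles <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_invalid("the 'yaml' package is required for YAML profile I/O")
  }
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p) do.call(system_profile, p))
}

#' Evoked-response template
#'
#' A Gaussian-windowed half-sinusoid whose extremum equals `amplitude_uv`
#' at `latency_ms` after stimulus onset. `electrodes` gives spatial
#' weights; `label_gain` gives a per-condition multiplier (labels absent
#' from it do not elicit the component).
#'
#' @param component Component name (e.g. `"N170"`).
#' @param latency_ms Peak latency (ms post-onset).
#' @param amplitude_uv Signed peak amplitude (uV); negative for N170, N200,
#'   MMN.
#' @param width_ms Full width of the half-sinusoid lobe (ms).
#' @param electrodes Named numeric vector of channel weights.
#' @param label_gain Named numeric vector of condition multipliers.
#' @param task Task the component belongs to (`NULL` = any task whose
#'   labels match `label_gain`).
#' @return An `erp_template` object.
#' @export
erp_template <- function(component, latency_ms, amplitude_uv, width_ms,
                         electrodes, label_gain, task = NULL) {
  stopifnot(width_ms > 0, length(electrodes) > 0, length(label_gain) > 0)
  structure(list(component = component, latency_ms = latency_ms,
                 amplitude_uv = amplitude_uv, width_ms = width_ms,
                 electrodes = electrodes, label_gain = label_gain,
                 task = task),
            class = "erp_template")
}

#' Simulator ground truth
#'
#' Container for the effects the simulator embeds: the eyes-closed/open
#' occipital alpha amplitude ratio, flicker-response amplitudes
#' (fundamental plus two harmonics), and the evoked-response templates.
#'
#' @param alpha_ec_gain Amplitude ratio of occipital alpha EC/EO.
#' @param alpha_base_uv Baseline (eyes-open) alpha amplitude (uV).
#' @param alpha_freq_hz Alpha oscillation frequency (Hz).
#' @param ssvep_amps Named list mapping fundamental frequency (as string,
#'   e.g. `"6"`) to a length-3 amplitude vector (uV) for the fundamental and
#'   its first two harmonics.
#' @param erp_templates List of [erp_template()] objects.
#' @param noise_sd_uv Standard deviation of the 1/f background noise (uV).
#' @param blink_rate_hz Rate of blink-like frontal transients (0 disables).
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(alpha_ec_gain = 2, alpha_base_uv = 5,
                         alpha_freq_hz = 10,
                         ssvep_amps = list(`6` = c(1, 0.5, 0.25),
                                           `10` = c(1, 0.5, 0.25),
                                           `15` = c(1, 0.5, 0.25)),
                         erp_templates = default_erp_templates(),
                         noise_sd_uv = 5, blink_rate_hz = 0) {
  if (alpha_ec_gain < 0 || alpha_base_uv < 0 || noise_sd_uv < 0) {
    stop_invalid("amplitudes must be non-negative")
  }
  if (any(unlist(ssvep_amps) < 0)) stop_invalid("SSVEP amplitudes must be >= 0")
  structure(list(alpha_ec_gain = alpha_ec_gain, alpha_base_uv = alpha_base_uv,
                 alpha_freq_hz = alpha_freq_hz, ssvep_amps = ssvep_amps,
                 erp_templates = erp_templates, noise_sd_uv = noise_sd_uv,
                 blink_rate_hz = blink_rate_hz),
            class = "ground_truth")
}

#' Null ground truth (no embedded effects)
#' @param noise_sd_uv Background-noise standard deviation (uV).
#' @return A `ground_truth` with no alpha modulation, no flicker response
#'   and no evoked components.
#' @export
null_ground_truth <- function(noise_sd_uv = 5) {
  ground_truth(alpha_ec_gain = 1, alpha_base_uv = 0,
               ssvep_amps = list(`6` = c(0, 0, 0), `10` = c(0, 0, 0),
                                 `15` = c(0, 0, 0)),
               erp_templates = list(), noise_sd_uv = noise_sd_uv)
}

#' Default evoked-response templates
#'
#' Canonical component set: P100 (+4 uV, 100 ms) and N170 (-5 uV, 150 ms)
#' at P7/P8, stronger for faces than textures; N200 (-3 uV, 260 ms) and
#' P300 (+5 uV, 380 ms) fronto-central for deviants in the active oddball;
#' MMN (-2 uV, 190 ms) fronto-central for deviants in the passive oddball.
#' Lobe widths: P100 60, N170 70, N200 80, P300 150, MMN 80 ms.
#'
#' @return List of `erp_template` objects.
#' @export
default_erp_templates <- function() {
  list(
    erp_template("P100", 100, 4, 60,
                 electrodes = c(P7 = 1, P8 = 1, O1 = 0.5, O2 = 0.5),
                 label_gain = c(face = 1, texture = 0.8), task = "face"),
    erp_template("N170", 150, -5, 70,
                 electrodes = c(P7 = 1, P8 = 1),
                 label_gain = c(face = 1, texture = 0.4), task = "face"),
    erp_template("N200", 260, -3, 80,
                 electrodes = c(Fz = 1, Cz = 0.8, Pz = 0.5),
                 label_gain = c(deviant = 1, standard = 0),
                 task = "active_oddball"),
    erp_template("P300", 380, 5, 150,
                 electrodes = c(Fz = 0.7, Cz = 1, Pz = 0.8),
                 label_gain = c(deviant = 1, standard = 0),
                 task = "active_oddball"),
    erp_template("MMN", 190, -2, 80,
                 electrodes = c(Fz = 1, Cz = 0.8, Pz = 0.2),
                 label_gain = c(deviant = 1, standard = 0),
                 task = "passive_oddball")
  )
}
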