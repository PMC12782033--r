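# shared builders for small synthetic fixtures

# ground truth with only background noise and an optional single template
noise_only_truth <- function(noise_sd_uv = 3) {
  ground_truth(alpha_ec_gain = 1, alpha_base_uv = 0,
               ssvep_amps = list(`6` = c(0, 0, 0), `10` = c(0, 0, 0),
                                 `15` = c(0, 0, 0)),
               erp_templates = list(), noise_sd_uv = noise_sd_uv)
}

single_template_truth <- function(template, noise_sd_uv = 0) {
  tr <- noise_only_truth(noise_sd_uv)
  tr$erp_templates <- list(template)
  tr
}

# clean profile: no attenuation, no dropout, no faults
clean_profile <- function(rate_hz = 128, n_channels = 8, ...) {
  system_profile("clean", rate_hz, n_channels = n_channels, ...)
}

# an erp_waveform from a plain channels x samples matrix
waveform_fixture <- function(values, rate_hz = 128, tmin_ms = -200,
                             channels = paste0("ch", seq_len(nrow(values)))) {
  erp_waveform(values, tmin_ms, tmin_ms + ncol(values) * 1000 / rate_hz,
               rate_hz, channels, condition = "fix")
}

# an epoch_set from a trials x channels x samples array
epochs_fixture <- function(arr, labels, rate_hz = 128, tmin_ms = -200) {
  structure(
    list(data = arr, tmin_ms = tmin_ms,
         tmax_ms = tmin_ms + dim(arr)[3] * 1000 / rate_hz,
         labels = labels, trial_index = seq_len(dim(arr)[1]),
         rejected = rep(FALSE, dim(arr)[1]),
         reason = rep(NA_character_, dim(arr)[1]),
         n_trials_total = dim(arr)[1],
         rate_hz = rate_hz,
         channel_names = paste0("ch", seq_len(dim(arr)[2]))),
    class = "epoch_set")
}

# minimal event sequence with given onsets/labels
new_event_seq_for_test <- function(onsets_s, task, labels,
                                   duration_s = 0.3) {
  ev <- data.frame(onset_s = onsets_s,
                   code = as.integer(factor(labels)),
                   label = labels, duration_s = duration_s,
                   stringsAsFactors = FALSE)
  eegbench:::new_event_sequence(ev, task,
                                max(onsets_s) + duration_s + 1)
}

expect_same_events <- function(a, b) {
  expect_equal(a$events, b$events)
  expect_identical(a$task, b$task)
  expect_equal(a$total_duration_s, b$total_duration_s)
}
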