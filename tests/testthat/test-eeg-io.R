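# BrainVision I/O and marker/log reconciliation

test_that("write -> read round-trip is float32-lossless with exact markers", {
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(6 * 400, 0, 20), 6, 400), 250,
                       c("Fz", "Cz", "Pz", "O1", "Oz", "O2"),
                       data.frame(sample = c(10L, 99L, 250L),
                                  code = c(1L, 2L, 1L)))
  path <- withr::local_tempfile(fileext = ".vhdr")
  write_brainvision(rec, path)
  back <- read_brainvision(path)
  expect_equal(back$rate_hz, 250)
  expect_equal(back$channel_names, rec$channel_names)
  expect_lt(max(abs(back$data - rec$data)), 1e-4)  # float32 rounding
  expect_equal(back$markers$sample, rec$markers$sample)
  expect_equal(back$markers$code, rec$markers$code)
})

test_that("a hand-written int16 fixture decodes with per-channel resolution", {
  dir <- withr::local_tempdir()
  hdr <- file.path(dir, "fix.vhdr")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "DataFile=fix.eeg", "MarkerFile=fix.vmrk",
    "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
    "NumberOfChannels=2", "SamplingInterval=7812.5",
    "[Binary Infos]", "BinaryFormat=INT_16",
    "[Channel Infos]",
    "Ch1=A,,0.1,µV", "Ch2=B,,0.5,µV"), hdr)
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000",
    "Mk2=Stimulus,S  7,3,1,0"), file.path(dir, "fix.vmrk"))
  con <- file(file.path(dir, "fix.eeg"), "wb")
  # multiplexed: (A1,B1,A2,B2,...); stored value 100 at 0.1 uV -> 10 uV
  writeBin(as.integer(c(100, 2, -50, 4, 0, -6, 30, 8)), con, size = 2,
           endian = "little")
  close(con)
  rec <- read_brainvision(hdr)
  expect_equal(rec$rate_hz, 128)  # SamplingInterval 7812.5 us
  expect_equal(rec$data["A", ], c(10, -5, 0, 3))
  expect_equal(rec$data["B", ], c(1, 2, -3, 4))
  expect_equal(rec$markers$sample, 2L)  # Mk position 3 is 1-based
  expect_equal(rec$markers$code, 7L)
})

test_that("the written header encodes the sampling interval in microseconds", {
  rec <- eeg_recording(matrix(0, 2, 8), 128, c("A", "B"))
  path <- withr::local_tempfile(fileext = ".vhdr")
  write_brainvision(rec, path)
  expect_true(any(grepl("SamplingInterval=7812.5",
                        readLines(path), fixed = TRUE)))
  # empty-marker recording still carries the New Segment marker
  vmrk <- readLines(sub("vhdr$", "vmrk", path))
  expect_true(any(grepl("^Mk1=New Segment", vmrk)))
  expect_false(any(grepl("^Mk2=", vmrk)))
})

test_that("unsupported dialects and missing companions are rejected", {
  dir <- withr::local_tempdir()
  hdr <- file.path(dir, "bad.vhdr")
  writeLines(c("[Common Infos]", "DataFile=absent.eeg",
               "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
               "NumberOfChannels=1", "SamplingInterval=4000"), hdr)
  expect_error(read_brainvision(hdr), "not found")
})

make_marker_rec <- function(onsets_s, rate = 128, codes = 1L) {
  n <- ceiling(max(onsets_s) * rate) + 10
  eeg_recording(matrix(0, 1, n), rate, "Cz",
                data.frame(sample = as.integer(round(onsets_s * rate)),
                           code = rep_len(codes, length(onsets_s))))
}

test_that("match_events is a bijection when no trigger is lost", {
  a <- gen_passive_oddball_events(40, 10, seed = 3)
  log <- data.frame(trial_index = seq_len(50), label = a$events$label,
                    onset_ms = a$events$onset_s * 1000,
                    code = a$events$code)
  rec <- make_marker_rec(a$events$onset_s)
  m <- match_events(rec, log)
  expect_equal(attr(m, "lost_triggers"), 0L)
  expect_equal(n_events(m), 50)
  expect_equal(m$events$label, a$events$label)
  # idempotent in the sense that rematching the matched onsets is stable
  m2 <- match_events(rec, log)
  expect_equal(m2$events, m$events)
})

test_that("a dropped marker is reported lost without disturbing other labels", {
  a <- gen_passive_oddball_events(40, 10, seed = 4)
  log <- data.frame(trial_index = seq_len(50), label = a$events$label,
                    onset_ms = a$events$onset_s * 1000, code = a$events$code)
  for (k in c(5L, 25L, 50L)) {
    rec <- make_marker_rec(a$events$onset_s[-k])
    m <- match_events(rec, log)
    expect_equal(attr(m, "lost_triggers"), 1L)
    expect_equal(attr(m, "lost_rows"), k)
    expect_equal(m$events$label, a$events$label[-k])
  }
})

test_that("lost-trigger counts match the simulator dropout over seeds", {
  truth <- noise_only_truth(1)
  prof <- system_profile("EMish", 128, trigger_loss_prob = 0.03,
                         n_channels = 2)
  ev <- gen_passive_oddball_events(80, 20, seed = 1)
  log <- data.frame(trial_index = seq_len(100), label = ev$events$label,
                    onset_ms = ev$events$onset_s * 1000,
                    code = ev$events$code)
  for (seed in 1:25) {
    rec <- synthesize_recording(ev, prof, truth, seed = seed)
    m <- match_events(rec, log)
    expect_equal(attr(m, "lost_triggers"), attr(rec, "lost_triggers"))
  }
})

test_that("alignment fails loudly when most rows are unmatched", {
  log <- data.frame(trial_index = 1:10, label = "standard",
                    onset_ms = seq(0, 9000, by = 1000), code = 1L)
  rec <- make_marker_rec(c(0, 1))  # 8 of 10 lost
  expect_error(match_events(rec, log), "alignment failure")
})

test_that("the dynamic-programming fallback agrees with greedy on clean trains", {
  a <- gen_passive_oddball_events(20, 5, seed = 9)
  log <- data.frame(trial_index = seq_len(25), label = a$events$label,
                    onset_ms = a$events$onset_s * 1000, code = a$events$code)
  rec <- make_marker_rec(a$events$onset_s[-10])
  g <- match_events(rec, log, dp = FALSE)
  d <- match_events(rec, log, dp = TRUE)
  expect_equal(g$events$label, d$events$label)
  expect_equal(attr(d, "lost_triggers"), 1L)
})
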