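# filtering, referencing, resampling, artifact rules, epoching, packs

test_that("the notch removes 50 Hz and the pass-band is preserved", {
  t <- seq(1 / 250, 20, by = 1 / 250)
  rec <- eeg_recording(rbind(sin(2 * pi * 50 * t), sin(2 * pi * 10 * t)),
                       250, c("A", "B"))
  out <- bandpass_notch(rec, 0.5, 55, 50)
  mid <- 1000:4000  # avoid filtfilt edge transients
  expect_lt(sd(out$data[1, mid]) / sd(rec$data[1, mid]), 0.01)
  expect_gt(sd(out$data[2, mid]) / sd(rec$data[2, mid]), 0.95)
  zero <- bandpass_notch(eeg_recording(matrix(0, 2, 1000), 250, c("A", "B")),
                         0.5, 55, 50)
  expect_equal(max(abs(zero$data)), 0)
  expect_error(bandpass_notch(rec, 10, 200, 50), "Nyquist")
})

test_that("common-average referencing zeroes the channel mean", {
  rec <- eeg_recording(matrix(5, 4, 50), 128, paste0("c", 1:4))
  out <- rereference_common_average(rec)
  expect_equal(max(abs(out$data)), 0)

  pm <- eeg_recording(rbind(rep(1, 10), rep(-1, 10)), 128, c("a", "b"))
  expect_equal(rereference_common_average(pm)$data, pm$data)

  set.seed(2)
  x <- matrix(rnorm(400), 4, 100)
  out <- rereference_common_average(eeg_recording(x, 128, paste0("c", 1:4)))
  expect_equal(out$data, sweep(x, 2, colMeans(x)), ignore_attr = TRUE)

  # excluded channels do not contribute to the average
  y <- rbind(x[1:3, ], 1e6)
  outx <- rereference_common_average(
    eeg_recording(y, 128, paste0("c", 1:4)), exclude = "c4")
  expect_equal(outx$data[1:3, ], sweep(x[1:3, ], 2, colMeans(x[1:3, ])),
               ignore_attr = TRUE)
})

test_that("downsampling preserves in-band amplitude and remaps markers", {
  t <- seq(0, 5, by = 1 / 500)
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * t)), 500, "A",
                       data.frame(sample = 500L, code = 1L))
  out <- resample_recording(rec, 128)
  expect_equal(out$rate_hz, 128)
  expect_equal(out$markers$sample, 128L)  # t = 1.000 s
  mid <- 100:540
  expect_lt(abs(diff(range(out$data[1, mid])) / 2 - 1), 0.02)
  # duration preserved within one sample
  expect_lte(abs(ncol(out$data) / 128 - ncol(rec$data) / 500), 1 / 128)

  expect_identical(resample_recording(rec, 500), rec)
  expect_error(resample_recording(rec, 1000), "upsampling")
})

test_that("muscular-artifact spans match a brute-force sliding window", {
  rate <- 100
  flat <- eeg_recording(matrix(0, 2, 500), rate, c("a", "b"))
  sp <- mark_muscular_artifacts(flat, 500, 800)
  expect_equal(nrow(sp$a), 0)

  # 600 uV step on one channel
  x <- rep(0, 500); x[250:500] <- 600
  rec <- eeg_recording(rbind(x, 0 * x), rate, c("a", "b"))
  sp <- mark_muscular_artifacts(rec, 500, 800)
  w <- 80  # 800 ms at 100 Hz
  expect_equal(nrow(sp$a), 1)
  # step is at 0-based sample 249; windows [s, s+w) containing both sides
  # start at 249 - w + 1 and end (merged, half-open) at 248 + w
  expect_equal(sp$a$start_sample, 249 - w + 1)
  expect_equal(sp$a$end_sample, 248 + w)
  expect_equal(nrow(sp$b), 0)

  # 499 uV never crosses the threshold
  x2 <- rep(0, 500); x2[250] <- 499
  sp2 <- mark_muscular_artifacts(eeg_recording(rbind(x2), rate, "a"), 500, 800)
  expect_equal(nrow(sp2$a), 0)

  # random fixture vs O(n^2) reference
  set.seed(4)
  y <- matrix(rnorm(8 * 300, 0, 180), 8, 300)
  rec <- eeg_recording(y, rate, paste0("c", 1:8))
  sp <- mark_muscular_artifacts(rec, 500, 200)
  wlen <- 20
  for (ch in 1:8) {
    marked <- rep(FALSE, 300)
    for (s in 1:(300 - wlen + 1)) {
      win <- y[ch, s:(s + wlen - 1)]
      if (max(win) - min(win) > 500) marked[s:(s + wlen - 1)] <- TRUE
    }
    got <- rep(FALSE, 300)
    spc <- sp[[paste0("c", ch)]]
    if (nrow(spc) > 0) {
      for (r in seq_len(nrow(spc))) {
        got[(spc$start_sample[r] + 1):spc$end_sample[r]] <- TRUE
      }
    }
    expect_equal(got, marked)
  }
})

test_that("faulty electrodes are flagged by the 5% artifact-time rule", {
  rec <- eeg_recording(matrix(0, 2, 1000), 100, c("a", "b"))
  spans <- list(a = data.frame(start_sample = 0L, end_sample = 40L),   # 4 %
                b = data.frame(start_sample = 0L, end_sample = 60L))   # 6 %
  fl <- flag_faulty_electrodes(rec, spans, 0.05)
  expect_equal(fl$retained, "a")
  expect_equal(fl$removed, "b")
  expect_equal(unname(fl$fraction), c(0.04, 0.06))
  empty <- eeg_recording(matrix(numeric(0), 1, 0), 100, "a")
  expect_error(flag_faulty_electrodes(empty, spans), "zero-length")
})

test_that("epoching slices half-open windows and drops boundary events", {
  rate <- 100
  ramp <- matrix(rep(seq_len(1000), each = 2), 2, byrow = FALSE)
  rec <- eeg_recording(ramp, rate, c("a", "b"))
  ev <- new_event_seq_for_test(c(0, 2, 9.9), "face",
                               c("face", "texture", "face"))
  ep <- epoch_recording(rec, ev, -200, 800)
  expect_equal(dim(ep$data)[1], 1)              # first and last out of bounds
  expect_equal(attr(ep, "n_dropped"), 2)
  expect_equal(ep$labels, "texture")
  # values equal direct slicing: event at 2 s -> samples 181..280 (1-based)
  expect_equal(ep$data[1, 1, ], ramp[1, 181:280])
  expect_equal(dim(ep$data)[3], 100)            # (800 - -200) ms at 100 Hz
})

test_that("baseline correction subtracts the prestimulus mean", {
  arr <- array(7, dim = c(2, 2, 100))
  ep <- epochs_fixture(arr, c("face", "face"), rate_hz = 100, tmin_ms = -200)
  out <- baseline_correct(ep, -200, 0)
  expect_equal(max(abs(out$data)), 0)

  ramp <- array(rep(1:100, each = 2), dim = c(1, 2, 100))
  epr <- epochs_fixture(ramp, "face", rate_hz = 100, tmin_ms = -200)
  outr <- baseline_correct(epr, -200, 0)
  base_mean <- mean(ramp[1, 1, 1:20])  # first 200 ms
  expect_equal(outr$data[1, 1, ], ramp[1, 1, ] - base_mean)
})

test_that("epoch rejection uses a strict peak-to-peak threshold", {
  arr <- array(0, dim = c(3, 2, 50))
  arr[2, 1, 25] <- 250                            # one spike epoch
  arr[3, 2, c(10, 30)] <- c(100, -100)            # exactly 200 p-t-p
  ep <- epochs_fixture(arr, rep("face", 3), rate_hz = 100, tmin_ms = 0)
  out <- reject_epochs(ep, 200)
  expect_equal(out$rejected, c(FALSE, TRUE, FALSE))
  expect_equal(attr(out, "rejection_fraction"), 1 / 3)
  zero <- reject_epochs(epochs_fixture(array(0, dim = c(4, 2, 10)),
                                       rep("x", 4), 100, 0), 200)
  expect_equal(sum(zero$rejected), 0)
})

test_that("pack reduction keeps the leading floor(fraction * n) trials", {
  p <- gen_passive_oddball_events(562, 112, seed = 2)
  expect_equal(n_events(subset_pack(p, "75")), 505)
  expect_equal(n_events(subset_pack(p, "50")), 337)
  expect_equal(sum(subset_pack(p, "75")$events$label == "deviant"), 84)
  expect_equal(sum(subset_pack(p, "50")$events$label == "deviant"), 56)

  one <- gen_face_events(2, seed = 1)
  half <- subset_pack(one, "50")
  expect_equal(n_events(half), 1)
  arr <- array(rnorm(5 * 2 * 10), dim = c(5, 2, 10))
  ep <- epochs_fixture(arr, rep(c("a", "b"), length.out = 5))
  ep50 <- subset_pack(ep, "50")
  expect_equal(dim(ep50$data)[1], 2)
  expect_equal(ep50$trial_index, 1:2)
})

test_that("filtering and common-average referencing commute (linearity)", {
  set.seed(12)
  rec <- eeg_recording(matrix(rnorm(6 * 2000, 0, 10), 6, 2000), 250,
                       paste0("c", 1:6))
  a <- rereference_common_average(bandpass_notch(rec, 0.5, 40, 50))
  b <- bandpass_notch(rereference_common_average(rec), 0.5, 40, 50)
  expect_lt(max(abs(a$data - b$data)), 1e-6)
})

test_that("the full chain is deterministic", {
  truth <- noise_only_truth(3)
  prof <- clean_profile(rate_hz = 250)
  ev <- gen_face_events(10, seed = 2)
  rec <- synthesize_recording(ev, prof, truth, seed = 5)
  p1 <- preprocess_task(rec, ev, pack = "100a")
  p2 <- preprocess_task(rec, ev, pack = "100a")
  expect_identical(p1$epochs$data, p2$epochs$data)
  expect_equal(p1$epochs$rate_hz, 128)  # equalized pack
})
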