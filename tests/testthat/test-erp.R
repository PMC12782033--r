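# condition averaging, difference waves, peak and area measures

test_that("oddball averaging honors the exclusion rules", {
  arr <- array(0, dim = c(5, 1, 10))
  for (i in 1:5) arr[i, 1, ] <- i
  ep <- epochs_fixture(arr, c("standard", "deviant", "standard", "standard",
                              "deviant"))
  std <- average_condition(ep, "standard",
                           exclude_post_deviant_standards = TRUE)
  expect_equal(std$n_epochs_averaged, 2)       # trials 1 and 4 (1-based)
  expect_equal(unique(as.numeric(std$values)), mean(c(1, 4)))

  arr6 <- array(0, dim = c(6, 1, 10))
  for (i in 1:6) arr6[i, 1, ] <- i
  ep6 <- epochs_fixture(arr6, c("standard", "standard", "deviant",
                                "standard", "standard", "deviant"))
  pre <- average_condition(ep6, "standard", standards_pre_deviant_only = TRUE)
  expect_equal(pre$n_epochs_averaged, 2)       # trials 2 and 5
  expect_equal(unique(as.numeric(pre$values)), mean(c(2, 5)))

  all_same <- average_condition(ep, "deviant")
  expect_equal(all_same$n_epochs_averaged, 2)
  # rejected epochs never enter an average
  ep$rejected[2] <- TRUE
  expect_equal(average_condition(ep, "deviant")$n_epochs_averaged, 1)
  ep$rejected[5] <- TRUE
  expect_error(average_condition(ep, "deviant"), "no retained")
})

test_that("difference waves subtract pointwise", {
  d <- waveform_fixture(rbind(c(1, 2, 3)))
  s <- waveform_fixture(rbind(c(3, 1, 5)))
  dw <- difference_wave(d, s)
  expect_equal(as.numeric(dw$values), c(-2, 1, -2))
  expect_equal(max(abs(difference_wave(d, d)$values)), 0)
  bad <- waveform_fixture(rbind(c(1, 2, 3)), rate_hz = 64)
  expect_error(difference_wave(d, bad), "share")
})

test_that("find_peak picks the single-sample extremum with early tie-break", {
  w <- waveform_fixture(rbind(seq(10, 1, length.out = 10)), rate_hz = 100,
                        tmin_ms = 0)
  pk <- find_peak(w, "ch1", c(20, 80), "negative")
  expect_equal(pk$latency_ms, 70)  # last in-window sample of a falling ramp

  ramp <- waveform_fixture(rbind(1:10), rate_hz = 100, tmin_ms = 0)
  expect_equal(find_peak(ramp, "ch1", c(20, 80), "negative")$latency_ms, 20)

  tie <- waveform_fixture(rbind(c(0, -3, 0, -3, 0)), rate_hz = 100,
                          tmin_ms = 0)
  expect_equal(find_peak(tie, "ch1", c(0, 50), "negative")$latency_ms, 10)

  set.seed(11)
  for (i in 1:25) {
    v <- rnorm(64)
    w <- waveform_fixture(rbind(v), rate_hz = 128, tmin_ms = -200)
    tms <- epoch_times_ms(w)
    sel <- which(tms >= 0 & tms < 300)
    pk <- find_peak(w, "ch1", c(0, 300), "positive")
    expect_equal(pk$amplitude_uv, max(v[sel]))
    expect_equal(pk$latency_ms, tms[sel[which.max(v[sel])]])
  }
  expect_error(find_peak(ramp, "ch1", c(200, 300), "negative"), "empty")
})

test_that("peak-to-peak amplitude is P100 minus N170", {
  w <- waveform_fixture(rbind(c(rep(0, 5), 3, rep(0, 5), -5, rep(0, 52))),
                        rate_hz = 128, tmin_ms = 0)
  p100 <- find_peak(w, "ch1", c(0, 80), "positive")
  n170 <- find_peak(w, "ch1", c(80, 150), "negative")
  expect_equal(p2p_amplitude(p100, n170), 8)
  expect_error(p2p_amplitude(n170, p100), "positive")
})

test_that("simulated N170 recovers template amplitude under attenuation", {
  templ <- erp_template("N170", 150, -4, 70, electrodes = c(P7 = 1),
                        label_gain = c(face = 1), task = "face")
  p100 <- erp_template("P100", 100, 4, 60, electrodes = c(P7 = 1),
                       label_gain = c(face = 1), task = "face")
  truth <- noise_only_truth(0)
  truth$erp_templates <- list(p100, templ)
  prof <- system_profile("half", 128, attenuation = 0.5, n_channels = 8)
  ev <- gen_face_events(8, seed = 1)
  rec <- synthesize_recording(ev, prof, truth, seed = 1)
  ep <- baseline_correct(epoch_recording(rec, ev, -200, 800), -200, 0)
  w <- average_condition(ep, "face")
  pk1 <- find_peak(w, "P7", c(60, 120), "positive")
  pk2 <- find_peak(w, "P7", c(120, 180), "negative")
  expect_lt(abs(p2p_amplitude(pk1, pk2) - 4), 0.4)  # (4 + 4) x 0.5
})

test_that("the MMN area window reproduces the latency-averaging arithmetic", {
  expect_equal(mmn_window(141, 188),
               c(center = 164.5, start = 139.5, end = 189.5))
  expect_equal(mmn_window(195, 188),
               c(center = 191.5, start = 166.5, end = 216.5))
  expect_equal(mmn_window(200, 200), c(center = 200, start = 175, end = 225))
  expect_equal(mmn_window(190, NA), c(center = 190, start = 165, end = 215))
})

test_that("the trapezoidal area matches closed forms and a fine grid", {
  z <- waveform_fixture(matrix(0, 1, 128), rate_hz = 128, tmin_ms = 0)
  expect_equal(erp_auc(z, "ch1", c(100, 150)), 0)

  const <- waveform_fixture(matrix(-1, 1, 1000), rate_hz = 1000, tmin_ms = 0)
  expect_equal(erp_auc(const, "ch1", c(100, 150)), -50)  # -1 uV x 50 ms

  # half-sine trough, amplitude -3, width 50 ms, at 128 Hz vs analytic
  f <- function(t_ms) ifelse(t_ms >= 100 & t_ms <= 150,
                             -3 * sin(pi * (t_ms - 100) / 50), 0)
  tms <- (0:63) * 1000 / 128
  w <- waveform_fixture(rbind(f(tms)), rate_hz = 128, tmin_ms = 0)
  analytic <- -(2 / pi) * 3 * 50
  expect_lt(abs(erp_auc(w, "ch1", c(100, 150)) - analytic) / abs(analytic),
            0.02)
  expect_error(erp_auc(w, "ch1", c(400, 600)), "outside")
})

test_that("grand averaging is the unweighted mean and is idempotent", {
  a <- waveform_fixture(rbind(c(1, 2, 3)))
  b <- waveform_fixture(rbind(c(3, 4, 5)))
  ga <- grand_average(list(a, b))
  expect_equal(as.numeric(ga$values), c(2, 3, 4))
  expect_equal(grand_average(list(a))$values, a$values)
  ga2 <- grand_average(list(a, b, ga))
  expect_equal(as.numeric(ga2$values), c(2, 3, 4))
})

test_that("component search windows follow the per-system presets", {
  expect_equal(component_window("N170", "EM"), c(100, 140))
  expect_equal(component_window("N170", "LA"), c(120, 160))
  expect_equal(component_window("P100", "EM"), c(60, 100))
  expect_equal(component_window("N200", "EM"), c(200, 280))
  expect_equal(component_window("P300", "BA"), c(280, 420))
  expect_equal(component_window("MMN", "BA"), c(100, 250))
})
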