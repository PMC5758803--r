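test_that("population sampling controls the echo-neuron count exactly", {
  cal <- calibration_preset()
  gt0 <- sample_population(50, echo_fraction = 0, calib = cal, seed = 1)
  expect_false(any(gt0$is_echo))
  gt <- sample_population(777, calib = cal, seed = 2)
  expect_equal(sum(gt$is_echo), round(cal$echo_fraction * 777))
  expect_true(all(gt$bf_hz >= 2000 & gt$bf_hz <= 40000))
  expect_true(all(gt$n_echo_events[gt$is_echo] %in% 1:5))
  expect_true(all(is.na(gt$echo_freq_hz[!gt$is_echo])))
  expect_error(sample_population(10, echo_fraction = 1.2), "echo_fraction")
})

test_that("sampled parameters match their configured means (law of large numbers)", {
  cal <- calibration_preset()
  gt <- sample_population(600, calib = cal, seed = 3)
  for (fld in list(c("evoked_amp", "evoked_amp_mean"),
                   c("spont_rate_hz", "spont_rate"),
                   c("noise_sd", "noise_sd"))) {
    v <- gt[[fld[1]]]
    expect_lt(abs(mean(v) - cal[[fld[2]]]),
              3 * stats::sd(v) / sqrt(length(v)))
  }
  ea <- gt$echo_amp[gt$is_echo]
  expect_lt(abs(mean(ea) - cal$echo_amp_mean), 3 * stats::sd(ea) / sqrt(length(ea)))
  el <- gt$echo_latency_s[gt$is_echo]
  expect_lt(abs(mean(el) - cal$echo_latency_mean),
            3 * stats::sd(el) / sqrt(length(el)))
})

test_that("echo frequencies sit on the grid point nearest BF (with step jitter)", {
  cal <- calibration_preset()
  cal$echo_step_jitter_prob <- 0
  freqs <- make_protocol()$frequencies_hz
  gt <- sample_population(300, echo_fraction = 1, calib = cal, seed = 4)
  near <- freqs[vapply(log2(gt$bf_hz),
                       function(x) which.min(abs(log2(freqs) - x)), 1L)]
  expect_equal(gt$echo_freq_hz, near)
})

test_that("a null neuron synthesizes to a constant baseline", {
  p <- small_protocol()
  gt <- make_gt(evoked_amp = 0, spont_rate_hz = 0, noise_sd = 0)
  tr <- synthesize_trace(gt, p, noise_sd = 0, baseline_f = 80, seed = 1)
  expect_equal(tr$f, rep(80, length(tr$f)))
  expect_equal(nrow(attr(tr, "events")[attr(tr, "events")$amplitude > 0, ]), 0)
})

test_that("the event log accounts for every kernel placed", {
  p <- small_protocol()
  cal <- jitterless_calib()
  gt <- make_gt(bf_hz = 8000, is_echo = TRUE, echo_freq_hz = 8000,
                n_echo_events = 4L, echo_amp = 0.3, echo_latency_s = 0.2,
                spont_rate_hz = 0, noise_sd = 0)
  tr <- synthesize_trace(gt, p, noise_sd = 0, seed = 1, calib = cal)
  ev <- attr(tr, "events")
  expect_equal(sum(ev$category == "evoked"), 3 * 5)  # n_freqs x n_reps
  expect_equal(sum(ev$category == "echo"), 4)
  expect_equal(sum(ev$category == "spontaneous"), 0)
  # echo kernels at t_end + k * isi + latency, exactly (no jitter)
  tr_idx <- which.min(abs(p$frequencies_hz - 8000))
  t_end <- echotune:::train_end_onsets(p)[tr_idx]
  expect_equal(ev$time_s[ev$category == "echo"],
               t_end + (1:4) * p$isi_s + 0.2)
  # evoked amplitudes follow the Gaussian tuning exactly
  amps <- ev$amplitude[ev$category == "evoked"]
  d_oct <- log2(rep(p$frequencies_hz, each = 5) / 8000)
  expect_equal(sort(unique(round(amps, 10))),
               sort(unique(round(0.12 * exp(-d_oct^2 / (2 * 0.8^2)), 10))))
})

test_that("tuning closure: evoked amplitude is exact at BF and BF + sigma", {
  # grid chosen so that one tone sits at BF and one exactly sigma away
  sig <- 0.8
  p <- make_protocol(n_freqs = 3, f_min_hz = 8000,
                     f_max_hz = 8000 * 2^(2 * sig), n_reps = 2,
                     gap_s = 20, first_onset_s = 30)
  gt <- make_gt(bf_hz = 8000, tuning_sigma_oct = sig, evoked_amp = 0.2,
                spont_rate_hz = 0)
  tr <- synthesize_trace(gt, p, noise_sd = 0, seed = 1,
                         calib = jitterless_calib())
  ev <- attr(tr, "events")
  a <- tapply(ev$amplitude, ev$freq_hz, unique)
  expect_equal(unname(a[as.character(8000)]), 0.2)
  expect_equal(unname(a[[2]]), 0.2 * exp(-1 / 2))
})

test_that("sessions are deterministic under a seed, including on disk", {
  p <- small_protocol()
  cal <- calibration_preset()
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- synthesize_session(n_neurons = 3, protocol = p, calib = cal,
                           seed = 9, out_dir = d1)
  s2 <- synthesize_session(n_neurons = 3, protocol = p, calib = cal,
                           seed = 9, out_dir = d2)
  expect_equal(s1$ground_truth, s2$ground_truth)
  expect_equal(s1$traces[[2]]$f, s2$traces[[2]]$f)
  for (f in c("traces.csv", "ground_truth.csv", "events.csv", "protocol.json"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  # traces round-trip through the reader
  back <- read_traces(file.path(d1, "traces.csv"))
  expect_equal(length(back), 3)
  expect_equal(back[[1]]$f, s1$traces[[1]]$f, tolerance = 1e-12)
  expect_equal(back[[1]]$frame_rate_hz, 40)
})

test_that("trace preconditions are enforced", {
  p <- small_protocol()
  gt <- make_gt()
  expect_error(synthesize_trace(gt, p, duration_s = 60), "too short")
  p2 <- make_protocol(n_freqs = 2, f_min_hz = 4000, f_max_hz = 8000,
                      n_reps = 3, first_onset_s = 5)
  expect_error(synthesize_trace(gt, p2, seed = 1), "pre-train")
})
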