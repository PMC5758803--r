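test_that("no transients means no echo classification", {
  p <- small_protocol()
  w <- build_windows(p)
  cls <- classify_echo(NULL, w, spont_rate_hz = 0.01, neuron_id = "a")
  expect_false(cls$is_echo)
  expect_equal(cls$p_spont, 1)
  expect_equal(nrow(cls$events), 0)
  expect_error(classify_echo(NULL, w, spont_rate_hz = -1), "spont_rate")
})

test_that("generator echo neurons classify correctly against ground truth", {
  p <- small_protocol()
  cal <- jitterless_calib()
  w <- build_windows(p)
  gt_echo <- make_gt(bf_hz = 8000, is_echo = TRUE, echo_freq_hz = 8000,
                     n_echo_events = 4L, echo_amp = 0.3,
                     echo_latency_s = 0.2, spont_rate_hz = 0)
  gt_null <- make_gt(bf_hz = 8000, spont_rate_hz = 0)
  for (case in list(list(gt = gt_echo, expect = TRUE),
                    list(gt = gt_null, expect = FALSE))) {
    tr <- synthesize_trace(case$gt, p, seed = 21, calib = cal)
    d <- compute_dff(tr)
    trans <- detect_transients(d)
    tt <- trace_times(d)
    rate <- estimate_spont_rate(trans, p, c(0, max(tt)), prior_count = 0.5)
    cls <- classify_echo(trans, w, rate, neuron_id = case$gt$neuron_id)
    expect_equal(cls$is_echo, case$expect)
    if (case$expect) {
      expect_equal(nrow(cls$events), 4)
      expect_equal(cls$echo_freqs_hz, 8000)
      expect_equal(cls$n_echo_events_max, 4)
      # every event lies inside exactly one echo window
      ew <- w[w$kind == "echo", ]
      n_win <- vapply(cls$events$onset_s, function(o)
        sum(o >= ew$start_s & o < ew$end_s), 1L)
      expect_true(all(n_win == 1))
    }
  }
})

test_that("false-positive rate on pure-spontaneous nulls stays at or below alpha", {
  p <- make_protocol()
  w <- build_windows(p)
  duration <- echotune:::protocol_min_duration(p) + 2
  rate_true <- 0.005
  set.seed(99)
  fp <- logical(1000)
  for (i in 1:1000) {
    n_ev <- stats::rpois(1, rate_true * duration)
    on <- sort(stats::runif(n_ev, 0, duration))
    trans <- data.frame(onset_s = on, peak_amp = rep(0.1, n_ev))
    rate <- estimate_spont_rate(trans, p, c(0, duration), prior_count = 0.5)
    fp[i] <- classify_echo(trans, w, rate, alpha = 0.05)$is_echo
  }
  # valid (possibly conservative) test: FP rate within binomial error of,
  # or below, the nominal level
  expect_lte(mean(fp), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("spontaneous rate estimation excludes trains and echo windows", {
  p <- small_protocol()
  extent <- c(0, 130)
  expect_equal(estimate_spont_rate(NULL, p, extent), 0)
  # transients only inside trains do not count
  trans_in <- data.frame(onset_s = p$train_onsets_s + 1)
  expect_equal(estimate_spont_rate(trans_in, p, extent), 0)
  # transients in silence count; rate = n / free time
  trans_free <- data.frame(onset_s = c(5, 10, 20))
  r <- estimate_spont_rate(trans_free, p, extent)
  ends <- echotune:::train_end_onsets(p)
  blocked <- sum(pmin(ends + 5 * 2 + 0.75, 130) - p$train_onsets_s)
  expect_equal(r, 3 / (130 - blocked))
  expect_error(estimate_spont_rate(NULL, p, c(20, 100), k_max = 20),
               "insufficient")
})

test_that("Poisson rate recovery from long stimulus-free recordings", {
  p <- small_protocol()
  duration <- 760
  rate_true <- 0.05
  set.seed(5)
  errs <- vapply(1:20, function(i) {
    n_ev <- stats::rpois(1, rate_true * duration)
    trans <- data.frame(onset_s = sort(stats::runif(n_ev, 0, duration)))
    estimate_spont_rate(trans, p, c(0, duration)) - rate_true
  }, 1)
  t_free <- duration - sum(echotune:::train_end_onsets(p) + 10.75 -
                             p$train_onsets_s)
  se <- sqrt(rate_true / t_free)
  expect_lt(abs(mean(errs)), 3 * se / sqrt(20))
})

test_that("neuron summaries degrade gracefully on silent traces", {
  p <- small_protocol()
  d <- as_dff(rep(0, 40 * 120))
  w <- build_windows(p)
  cls <- classify_echo(NULL, w, 0, neuron_id = "z")
  sm <- summarize_neuron(d, NULL, w, cls)
  expect_false(sm$is_echo)
  expect_equal(sm$baseline_amp, 0)
  expect_true(is.na(sm$sound_amp))
  expect_true(is.na(sm$echo_amp))
  expect_true(is.na(sm$sound_latency_s))
})

test_that("low-noise echo neuron summary matches configured parameters", {
  p <- small_protocol()
  cal <- jitterless_calib()
  gt <- make_gt(bf_hz = 8000, evoked_amp = 0.25, sound_latency_s = 0.08,
                is_echo = TRUE, echo_freq_hz = 8000, n_echo_events = 3L,
                echo_amp = 0.3, echo_latency_s = 0.25, spont_rate_hz = 0)
  tr <- synthesize_trace(gt, p, seed = 31, calib = cal)
  d <- compute_dff(tr)
  trans <- detect_transients(d)
  w <- build_windows(p)
  cls <- classify_echo(trans, w, 0.001, neuron_id = "n001")
  sm <- summarize_neuron(d, trans, w, cls)
  expect_true(sm$is_echo)
  expect_lt(abs(sm$echo_amp - 0.3), 0.03)
  expect_lt(abs(sm$echo_latency_s - 0.25), 0.05)
  expect_lt(abs(sm$sound_latency_s - 0.08), 0.03)
  expect_gt(sm$sound_amp, 0.1)
  expect_gt(sm$echo_latency_s, sm$sound_latency_s)
  expect_lt(sm$baseline_amp, 0.02)
})
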