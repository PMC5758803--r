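#' Estimate the spontaneous transient rate from stimulus-free time
#'
#' Stimulus-free time is the part of the recording outside every train
#' (train onset to last tone offset) and outside every anticipated-time
#' (echo) window. The rate is `(count + prior_count) / free_time`. The
#' default `prior_count = 0` is the plain event-count estimator; the
#' analysis pipeline uses `prior_count = 0.5` (a Jeffreys-style
#' regularization) when building the classification null, so that a neuron
#' with zero observed spontaneous events does not yield a degenerate
#' zero-rate null under which any single anticipated-time event would be
#' called significant.
#'
#' @param transients Transient table of one neuron.
#' @param protocol A `stim_protocol`.
#' @param trace_extent Numeric length-2, recording start and end time (s).
#' @param k_max,echo_halfwidth_s Echo-window layout, as in
#'   [build_windows()].
#' @param prior_count Pseudo-count added to the observed event count.
#' @return Spontaneous rate in events/s.
#' @export
estimate_spont_rate <- function(transients, protocol, trace_extent,
                                k_max = 5, echo_halfwidth_s = 0.75,
                                prior_count = 0) {
  if (prior_count < 0) stop("`prior_count` must be >= 0", call. = FALSE)
  ends <- train_end_onsets(protocol)
  # each train is blocked from its onset to the end of its last echo
  # window (or one ISI past the last tone when k_max = 0), so that
  # responses to the train's final tones cannot leak into "free" time
  post <- max(k_max * protocol$isi_s + echo_halfwidth_s, protocol$isi_s)
  blocked <- cbind(protocol$train_onsets_s, ends + post)
  blocked[, 1] <- pmax(blocked[, 1], trace_extent[1])
  blocked[, 2] <- pmin(blocked[, 2], trace_extent[2])
  blocked <- blocked[blocked[, 2] > blocked[, 1], , drop = FALSE]
  blocked <- blocked[order(blocked[, 1]), , drop = FALSE]

  free <- list(); cur <- trace_extent[1]
  for (i in seq_len(nrow(blocked))) {
    if (blocked[i, 1] > cur) free[[length(free) + 1]] <- c(cur, blocked[i, 1])
    cur <- max(cur, blocked[i, 2])
  }
  if (cur < trace_extent[2]) free[[length(free) + 1]] <- c(cur, trace_extent[2])
  t_free <- sum(vapply(free, function(iv) iv[2] - iv[1], 1))
  if (t_free < 30)
    stop("insufficient stimulus-free time (< 30 s) for rate estimation",
         call. = FALSE)
  n <- 0L
  if (!is.null(transients) && nrow(transients)) {
    on <- transients$onset_s
    n <- sum(vapply(free, function(iv) sum(on >= iv[1] & on < iv[2]), 1L))
  }
  (n + prior_count) / t_free
}

#' Classify a neuron as an echo neuron against a Poisson spontaneous null
#'
#' Counts detected transient onsets falling inside anticipated-time (echo)
#' windows across all trains, and computes the upper-tail Poisson
#' probability of at least that count under a homogeneous spontaneous
#' process: `p_spont = P(X >= count)` with
#' `E[X] = spont_rate_hz * total echo-window time`. The neuron is an echo
#' neuron when it has at least one anticipated-time event and
#' `p_spont < alpha`. Each matched transient is recorded with its train
#' frequency, echo index `k`, onset, peak amplitude and latency (onset
#' minus anticipated time).
#'
#' @param transients Transient table of one neuron.
#' @param windows Window table from [build_windows()].
#' @param spont_rate_hz Spontaneous rate for the null (events/s), from
#'   [estimate_spont_rate()] on the same neuron.
#' @param alpha Significance level.
#' @param neuron_id Identifier carried into the result.
#' @return An `echo_classification`: list with `neuron_id`, `is_echo`,
#'   `echo_freqs_hz`, `events` (one row per anticipated-time transient),
#'   `n_echo_events_max` (largest count after any single train), `p_spont`
#'   and `alpha`.
#' @export
classify_echo <- function(transients, windows, spont_rate_hz, alpha = 0.05,
                          neuron_id = NA_character_) {
  if (spont_rate_hz < 0) stop("`spont_rate_hz` must be >= 0", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]", call. = FALSE)
  ew <- windows[windows$kind == "echo", , drop = FALSE]
  events <- data.frame(freq_hz = numeric(), k = integer(), train = integer(),
                       onset_s = numeric(), peak_amp = numeric(),
                       latency_s = numeric())
  if (!is.null(transients) && nrow(transients) && nrow(ew)) {
    for (j in seq_len(nrow(ew))) {
      hit <- transients$onset_s >= ew$start_s[j] &
        transients$onset_s < ew$end_s[j]
      if (any(hit)) {
        tr <- transients[hit, , drop = FALSE]
        events <- rbind(events, data.frame(
          freq_hz = ew$freq_hz[j], k = ew$k[j], train = ew$train[j],
          onset_s = tr$onset_s, peak_amp = tr$peak_amp,
          latency_s = tr$onset_s - ew$ref_time_s[j]))
      }
    }
  }
  count <- nrow(events)
  lambda <- spont_rate_hz * sum(ew$end_s - ew$start_s)
  p <- if (count == 0) 1 else
    stats::ppois(count - 1, lambda, lower.tail = FALSE)
  structure(list(
    neuron_id = neuron_id, is_echo = count >= 1 && p < alpha,
    echo_freqs_hz = sort(unique(events$freq_hz)), events = events,
    n_echo_events_max = if (count) max(table(events$train)) else 0L,
    p_spont = p, alpha = alpha), class = "echo_classification")
}

#' Per-neuron response summary
#'
#' Measures sound, echo and baseline responses for one neuron.
#' `sound_amp` averages peak-mode amplitudes over sound windows that
#' contain a detected transient onset (responsive windows); `echo_amp`
#' averages the peak amplitudes of the classified anticipated-time events;
#' `baseline_amp` averages peak-mode amplitudes over all baseline windows
#' with no transient requirement. `sound_win_amp` and `echo_win_amp` are
#' the unconditional window averages (over all sound and echo windows),
#' used as the no-response activity level when pooling over all neurons.
#' Latencies average the defined per-window or per-event values. Absent
#' categories are `NA`, never 0.
#'
#' @param dff A `dff_trace`.
#' @param transients Transient table of the neuron.
#' @param windows Window table from [build_windows()].
#' @param cls An `echo_classification` for the neuron.
#' @return A one-row data.frame.
#' @export
summarize_neuron <- function(dff, transients, windows, cls) {
  sw <- measure_windows(dff, windows[windows$kind == "sound", , drop = FALSE],
                        transients, mode = "peak")
  bw <- measure_windows(dff, windows[windows$kind == "baseline", , drop = FALSE],
                        NULL, mode = "peak")
  # the k = 1 anticipated-time window overlaps the decay of the train's
  # last responses, which depresses its max-minus-start amplitude; the
  # no-response activity level therefore uses the k >= 2 windows
  ewin <- windows[windows$kind == "echo", , drop = FALSE]
  if (any(ewin$k >= 2)) ewin <- ewin[ewin$k >= 2, , drop = FALSE]
  ew <- measure_windows(dff, ewin, NULL, mode = "peak")
  resp <- !is.na(sw$latency_s)
  mean_or_na <- function(x) if (length(x) && any(!is.na(x)))
    mean(x, na.rm = TRUE) else NA_real_
  data.frame(
    neuron_id = cls$neuron_id,
    is_echo = cls$is_echo,
    p_spont = cls$p_spont,
    n_echo_events = nrow(cls$events),
    n_echo_events_max = cls$n_echo_events_max,
    echo_freq_hz = if (length(cls$echo_freqs_hz)) cls$echo_freqs_hz[1] else NA_real_,
    sound_amp = mean_or_na(sw$amplitude[resp]),
    sound_win_amp = mean_or_na(sw$amplitude),
    n_sound_resp = sum(resp),
    sound_latency_s = mean_or_na(sw$latency_s[resp]),
    echo_amp = mean_or_na(cls$events$peak_amp),
    echo_win_amp = mean_or_na(ew$amplitude),
    echo_latency_s = mean_or_na(cls$events$latency_s),
    baseline_amp = mean_or_na(bw$amplitude),
    stringsAsFactors = FALSE
  )
}
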