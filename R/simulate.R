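#' Draw ground-truth neuron parameters for a synthetic imaging field
#'
#' Samples one imaging plane's worth of neurons from a calibration preset:
#' best frequencies uniform on the log-frequency band spanned by
#' `freqs_hz`, Gaussian tuning widths, tone-evoked and echo amplitudes,
#' latency means, spontaneous rates, per-neuron imaging noise and ROI
#' centroids uniform on a square field. Exactly
#' `round(echo_fraction * n_neurons)` neurons are flagged as echo neurons;
#' each has an echo-evoking frequency equal to the stimulus frequency
#' nearest its best frequency, displaced by one stimulus step with
#' probability `calib$echo_step_jitter_prob`, and an echo event count drawn
#' uniformly from `calib$n_echo_min:calib$n_echo_max`.
#'
#' @param n_neurons Number of neurons (>= 1).
#' @param echo_fraction Proportion of echo neurons in `[0, 1]`; defaults to
#'   the preset's calibrated prevalence.
#' @param field_um Side of the square imaged field in micrometres.
#' @param calib A calibration preset, see [calibration_preset()].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param freqs_hz Stimulus frequency grid used to place echo frequencies
#'   and bound best frequencies.
#' @return A data.frame with one row per neuron (columns `neuron_id`,
#'   `bf_hz`, `tuning_sigma_oct`, `evoked_amp`, `spont_rate_hz`, `is_echo`,
#'   `echo_freq_hz`, `n_echo_events`, `echo_amp`, `echo_latency_s`,
#'   `sound_latency_s`, `noise_sd`, `x_um`, `y_um`).
#' @export
sample_population <- function(n_neurons, echo_fraction = calib$echo_fraction,
                              field_um = calib$field_um,
                              calib = calibration_preset(), seed = NULL,
                              freqs_hz = make_protocol()$frequencies_hz) {
  if (n_neurons < 1 || n_neurons != round(n_neurons))
    stop("`n_neurons` must be a positive integer", call. = FALSE)
  if (echo_fraction < 0 || echo_fraction > 1)
    stop("`echo_fraction` must lie in [0, 1]", call. = FALSE)
  if (field_um <= 0) stop("`field_um` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n <- as.integer(n_neurons)
  lf <- log2(freqs_hz)
  bf <- 2^stats::runif(n, min(lf), max(lf))
  sig <- pmax(calib$tuning_sigma_min,
              stats::rnorm(n, calib$tuning_sigma_mean, calib$tuning_sigma_sd))
  n_echo <- as.integer(round(echo_fraction * n))
  is_echo <- rep(FALSE, n)
  if (n_echo > 0) is_echo[sample.int(n, n_echo)] <- TRUE

  # echo frequency: grid point nearest BF, +/- one step with small prob.
  idx <- vapply(log2(bf), function(x) which.min(abs(lf - x)), integer(1))
  shift <- ifelse(stats::runif(n) < calib$echo_step_jitter_prob,
                  sample(c(-1L, 1L), n, replace = TRUE), 0L)
  idx <- pmin(pmax(idx + shift, 1L), length(freqs_hz))

  gt <- data.frame(
    neuron_id = sprintf("n%03d", seq_len(n)),
    bf_hz = bf,
    tuning_sigma_oct = sig,
    evoked_amp = rlnorm_mean_cv(n, calib$evoked_amp_mean, calib$evoked_amp_cv),
    spont_rate_hz = rlnorm_mean_cv(n, calib$spont_rate, calib$spont_rate_cv),
    is_echo = is_echo,
    echo_freq_hz = ifelse(is_echo, freqs_hz[idx], NA_real_),
    n_echo_events = ifelse(is_echo,
                           sample(seq(calib$n_echo_min, calib$n_echo_max),
                                  n, replace = TRUE), NA_integer_),
    echo_amp = ifelse(is_echo,
                      rlnorm_mean_cv(n, calib$echo_amp_mean, calib$echo_amp_cv),
                      NA_real_),
    echo_latency_s = ifelse(is_echo,
                            rlnorm_mean_cv(n, calib$echo_latency_mean,
                                           calib$echo_latency_cv), NA_real_),
    sound_latency_s = pmax(calib$sound_latency_min,
                           stats::rnorm(n, calib$sound_latency_mean,
                                        calib$sound_latency_between_sd)),
    noise_sd = rlnorm_mean_cv(n, calib$noise_sd, calib$noise_sd_cv),
    x_um = stats::runif(n, 0, field_um),
    y_um = stats::runif(n, 0, field_um),
    stringsAsFactors = FALSE
  )
  gt
}

# add one kernel to a delta-f/f vector in place (returns modified vector)
add_kernel <- function(dff, t, onset_s, amp, tau_rise, tau_decay) {
  i0 <- findInterval(onset_s, t) + 1L  # first frame at/after onset
  if (i0 > length(t)) return(dff)
  i1 <- min(length(t), i0 + ceiling(8 * tau_decay * 1 / (t[2] - t[1])))
  idx <- i0:i1
  dff[idx] <- dff[idx] + amp * calcium_kernel(t[idx] - onset_s, tau_rise, tau_decay)
  dff
}

#' Synthesize one ROI fluorescence trace
#'
#' Forward model for a single neuron: a baseline fluorescence modulated by
#' a delta-f/f signal that is the superposition of unit-peak
#' double-exponential transient kernels, plus white Gaussian noise:
#' `f(t) = baseline_f * (1 + signal(t) + noise(t))`. Kernels are placed at
#' (a) spontaneous Poisson event times, (b) every tone onset of every train
#' with amplitude scaled by Gaussian tuning in log2-frequency distance from
#' the neuron's best frequency and onset lag `sound_latency_s` plus jitter,
#' and (c) for echo neurons, `n_echo_events` anticipated-time events after
#' the train at the echo frequency, at `t_end + k * isi_s` plus
#' `echo_latency_s` and jitter (`t_end` = onset of the train's last tone).
#' Event-level latency jitter is Gaussian with preset SDs, truncated so
#' lags stay non-negative.
#'
#' Every kernel placed is recorded in the event log returned as
#' `attr(trace, "events")` (columns `category`, `time_s` = kernel onset,
#' `amplitude`, `freq_hz`, `k`), the ground-truth oracle for detector and
#' classifier tests.
#'
#' @param gt One neuron's ground-truth parameters: a single-row data.frame
#'   as returned by [sample_population()] (or a named list).
#' @param protocol A `stim_protocol`.
#' @param frame_rate_hz Sampling rate in Hz.
#' @param noise_sd Gaussian noise SD in delta-f/f units; defaults to the
#'   neuron's `noise_sd` field.
#' @param baseline_f Baseline fluorescence in arbitrary units.
#' @param duration_s Trace duration; must cover the protocol plus at least
#'   `6 * isi_s` of post-train and 30 s of pre-train silence.
#' @param seed Optional integer seed.
#' @param calib Calibration preset supplying kernel time constants, jitter
#'   SDs and spontaneous-amplitude statistics.
#' @return A `roi_trace`: list with `neuron_id`, `frame_rate_hz`, `f`,
#'   `t0_s` and the event-log attribute described above.
#' @export
synthesize_trace <- function(gt, protocol, frame_rate_hz = 40,
                             noise_sd = gt$noise_sd, baseline_f = 100,
                             duration_s = NULL, seed = NULL,
                             calib = calibration_preset()) {
  gt <- as.list(gt)
  if (is.null(duration_s))
    duration_s <- ceiling(protocol_min_duration(protocol) + protocol$isi_s)
  t_last <- max(train_end_onsets(protocol)) + protocol$tone_dur_s
  if (duration_s < t_last + 6 * protocol$isi_s)
    stop("`duration_s` too short: need >= 6 ISIs of post-train silence",
         call. = FALSE)
  if (min(protocol$train_onsets_s) < 30)
    stop("protocol must leave >= 30 s of pre-train silence", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n <- floor(duration_s * frame_rate_hz)
  t <- (seq_len(n) - 1) / frame_rate_hz
  dff <- numeric(n)
  ev <- list()

  # spontaneous Poisson events over the whole trace
  n_sp <- stats::rpois(1, gt$spont_rate_hz * duration_s)
  if (n_sp > 0) {
    ts <- sort(stats::runif(n_sp, 0, duration_s))
    amps <- rlnorm_mean_cv(n_sp, calib$spont_amp_mean, calib$spont_amp_cv)
    ev[[length(ev) + 1]] <- data.frame(category = "spontaneous", time_s = ts,
                                       amplitude = amps, freq_hz = NA_real_,
                                       k = NA_integer_)
  }

  # tone-evoked events: every tone of every train, Gaussian tuning
  for (tr in seq_along(protocol$frequencies_hz)) {
    f <- protocol$frequencies_hz[tr]
    d_oct <- log2(f / gt$bf_hz)
    amp <- gt$evoked_amp * exp(-d_oct^2 / (2 * gt$tuning_sigma_oct^2))
    onsets <- tone_onsets(protocol, tr)
    lags <- pmax(0, gt$sound_latency_s +
                   stats::rnorm(length(onsets), 0, calib$sound_jitter_sd))
    ev[[length(ev) + 1]] <- data.frame(category = "evoked",
                                       time_s = onsets + lags,
                                       amplitude = amp, freq_hz = f,
                                       k = NA_integer_)
  }

  # echo events after the train at the echo frequency
  if (isTRUE(gt$is_echo)) {
    tr <- which.min(abs(log2(protocol$frequencies_hz / gt$echo_freq_hz)))
    t_end <- train_end_onsets(protocol)[tr]
    k <- seq_len(gt$n_echo_events)
    lags <- pmax(0, gt$echo_latency_s +
                   stats::rnorm(length(k), 0, calib$echo_jitter_sd))
    ev[[length(ev) + 1]] <- data.frame(category = "echo",
                                       time_s = t_end + k * protocol$isi_s + lags,
                                       amplitude = gt$echo_amp,
                                       freq_hz = protocol$frequencies_hz[tr],
                                       k = k)
  }

  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(category = character(), time_s = numeric(),
               amplitude = numeric(), freq_hz = numeric(), k = integer())
  events <- events[events$time_s < duration_s, , drop = FALSE]
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL

  for (i in seq_len(nrow(events)))
    dff <- add_kernel(dff, t, events$time_s[i], events$amplitude[i],
                      calib$tau_rise, calib$tau_decay)
  if (noise_sd > 0) dff <- dff + stats::rnorm(n, 0, noise_sd)

  trace <- structure(list(neuron_id = gt$neuron_id, frame_rate_hz = frame_rate_hz,
                          f = baseline_f * (1 + dff), t0_s = 0),
                     class = "roi_trace")
  attr(trace, "events") <- events
  trace
}

#' Synthesize a complete imaging session
#'
#' Draws a population of neurons and synthesizes one fluorescence trace per
#' neuron under a shared stimulus protocol. Optionally writes the bundle to
#' disk as plain-text files (`traces.csv` with a `time_s` column and one
#' `neuron_<id>` column per ROI; `protocol.json`; `ground_truth.csv`;
#' `events.csv`).
#'
#' @param n_neurons Neurons per session.
#' @param protocol A `stim_protocol`; defaults to the standard 11-tone
#'   rhythmic protocol.
#' @param calib Calibration preset.
#' @param echo_fraction True echo-neuron prevalence.
#' @param frame_rate_hz Imaging frame rate in Hz.
#' @param seed Integer seed; the session is fully reproducible under it.
#' @param out_dir Optional output directory; created if missing.
#' @param duration_s Optional trace duration (s), default auto from protocol.
#' @return An `echo_session`: list with `protocol`, `traces` (list of
#'   `roi_trace`), `ground_truth`, `events` (pooled event log with a
#'   `neuron_id` column) and `seed`.
#' @export
synthesize_session <- function(n_neurons = 100, protocol = make_protocol(),
                               calib = calibration_preset(),
                               echo_fraction = calib$echo_fraction,
                               frame_rate_hz = 40, seed = 1,
                               out_dir = NULL, duration_s = NULL) {
  set.seed(seed)
  gt <- sample_population(n_neurons, echo_fraction = echo_fraction,
                          calib = calib, seed = NULL,
                          freqs_hz = protocol$frequencies_hz)
  traces <- vector("list", n_neurons)
  evs <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    tr <- synthesize_trace(gt[i, ], protocol, frame_rate_hz = frame_rate_hz,
                           duration_s = duration_s, calib = calib)
    traces[[i]] <- tr
    e <- attr(tr, "events")
    if (nrow(e)) e$neuron_id <- gt$neuron_id[i]
    evs[[i]] <- e
  }
  names(traces) <- gt$neuron_id
  events <- do.call(rbind, evs[vapply(evs, nrow, 1L) > 0])
  if (is.null(events)) events <- data.frame(category = character(),
                                            time_s = numeric(), amplitude = numeric(),
                                            freq_hz = numeric(), k = integer(),
                                            neuron_id = character())
  rownames(events) <- NULL
  bundle <- structure(list(protocol = protocol, traces = traces,
                           ground_truth = gt, events = events, seed = seed),
                      class = "echo_session")
  if (!is.null(out_dir)) write_session(bundle, out_dir)
  bundle
}

#' @export
print.echo_session <- function(x, ...) {
  cat(sprintf("<echo_session> %d neurons, %d trains, seed %s\n",
              length(x$traces), length(x$protocol$frequencies_hz),
              format(x$seed)))
  invisible(x)
}

#' Write / read session files
#'
#' @param bundle An `echo_session`.
#' @param dir Directory for `traces.csv`, `protocol.json`,
#'   `ground_truth.csv` and `events.csv`.
#' @return `write_session` returns `dir` invisibly.
#' @export
write_session <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_protocol(bundle$protocol, file.path(dir, "protocol.json"))
  tr <- bundle$traces
  tab <- data.frame(time_s = trace_times(tr[[1]]))
  for (nm in names(tr)) tab[[paste0("neuron_", nm)]] <- tr[[nm]]$f
  utils::write.csv(tab, file.path(dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(bundle$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$events, file.path(dir, "events.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_session
#' @param path Path of a `traces.csv`-style table (column `time_s` plus one
#'   column per neuron).
#' @return `read_traces` returns a named list of `roi_trace` objects.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(tab))
    stop("trace table must have a `time_s` column", call. = FALSE)
  dt <- diff(tab$time_s[1:2])
  cols <- setdiff(names(tab), "time_s")
  traces <- lapply(cols, function(cn) {
    structure(list(neuron_id = sub("^neuron_", "", cn),
                   frame_rate_hz = 1 / dt, f = tab[[cn]], t0_s = tab$time_s[1]),
              class = "roi_trace")
  })
  names(traces) <- sub("^neuron_", "", cols)
  traces
}

#' Frame times of a trace
#' @param trace A `roi_trace` or `dff_trace`.
#' @return Numeric vector of frame times in seconds.
#' @export
trace_times <- function(trace) {
  n <- length(if (!is.null(trace$f)) trace$f else trace$dff)
  trace$t0_s + (seq_len(n) - 1) / trace$frame_rate_hz
}
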