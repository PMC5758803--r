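#' Construct a rhythmic pure-tone stimulation protocol
#'
#' Builds the stimulus-protocol description used throughout the pipeline: a
#' set of log-spaced pure-tone frequencies, each presented as a rhythmic
#' train of `n_reps` tones at a fixed inter-stimulus interval (ISI), trains
#' separated by a silent gap. The defaults reproduce the standard tuning
#' protocol for mouse A1: 11 frequencies logarithmically spaced between 2
#' and 40 kHz, 20 repetitions per frequency, 2-s ISI, 100-ms tones with
#' 10-ms linear ramps.
#'
#' Trains are presented lowest-to-highest frequency. Train `k` starts
#' `gap_s` seconds after train `k-1` ends (a train spans
#' `(n_reps-1)*isi_s + tone_dur_s` seconds); the first train starts at
#' `first_onset_s`.
#'
#' @param n_freqs Number of tone frequencies (>= 1).
#' @param f_min_hz,f_max_hz Frequency band limits in Hz; frequencies are
#'   geometrically (log-)spaced from `f_min_hz` to `f_max_hz` inclusive.
#' @param n_reps Tones per train (>= 1).
#' @param isi_s Inter-stimulus interval in seconds (onset-to-onset within a
#'   train); must exceed `tone_dur_s`.
#' @param tone_dur_s Tone duration in seconds (> 0).
#' @param gap_s Silent gap between the end of one train and the onset of
#'   the next, in seconds.
#' @param first_onset_s Onset time of the first train's first tone, in
#'   seconds. The pre-train silence is used for baseline windows and
#'   spontaneous-rate estimation.
#' @param ramp_s On/off linear ramp duration in seconds (metadata only; the
#'   forward model does not synthesize acoustic waveforms).
#'
#' @return An object of class `stim_protocol`: a list with fields
#'   `frequencies_hz`, `isi_s`, `tone_dur_s`, `n_reps`, `train_onsets_s`
#'   (onset of each train's first tone, one per frequency) and `ramp_s`.
#' @examples
#' p <- make_protocol()
#' round(p$frequencies_hz[4]) # 4913 Hz
#' @export
make_protocol <- function(n_freqs = 11, f_min_hz = 2000, f_max_hz = 40000,
                          n_reps = 20, isi_s = 2, tone_dur_s = 0.1,
                          gap_s = 30, first_onset_s = 30, ramp_s = 0.01) {
  if (n_freqs < 1 || n_freqs != round(n_freqs))
    stop("`n_freqs` must be a positive integer", call. = FALSE)
  if (f_min_hz <= 0 || f_max_hz < f_min_hz)
    stop("need 0 < f_min_hz <= f_max_hz", call. = FALSE)
  if (n_reps < 1 || n_reps != round(n_reps))
    stop("`n_reps` must be a positive integer", call. = FALSE)
  if (tone_dur_s <= 0) stop("`tone_dur_s` must be > 0", call. = FALSE)
  if (isi_s <= tone_dur_s) stop("`isi_s` must exceed `tone_dur_s`", call. = FALSE)
  if (gap_s < 0 || first_onset_s < 0)
    stop("`gap_s` and `first_onset_s` must be >= 0", call. = FALSE)
  if (n_freqs > 1 && f_max_hz == f_min_hz)
    stop("distinct frequencies require f_max_hz > f_min_hz", call. = FALSE)

  freqs <- if (n_freqs == 1) f_min_hz else
    exp(seq(log(f_min_hz), log(f_max_hz), length.out = n_freqs))
  span <- (n_reps - 1) * isi_s + tone_dur_s
  onsets <- first_onset_s + (seq_len(n_freqs) - 1) * (span + gap_s)

  structure(list(frequencies_hz = freqs, isi_s = isi_s, tone_dur_s = tone_dur_s,
                 n_reps = n_reps, train_onsets_s = onsets, ramp_s = ramp_s),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  f <- x$frequencies_hz
  cat(sprintf("<stim_protocol> %d frequencies %.1f-%.1f kHz, %d reps, ISI %.3g s\n",
              length(f), min(f) / 1000, max(f) / 1000, x$n_reps, x$isi_s))
  invisible(x)
}

#' Tone onset times of one train
#'
#' @param protocol A `stim_protocol`.
#' @param train Train index (1-based, one train per frequency).
#' @return Numeric vector of `n_reps` tone onset times in seconds.
#' @keywords internal
tone_onsets <- function(protocol, train) {
  protocol$train_onsets_s[train] + (seq_len(protocol$n_reps) - 1) * protocol$isi_s
}

#' Onset time of the last tone of each train
#' @param protocol A `stim_protocol`.
#' @return Numeric vector, one value per train.
#' @keywords internal
train_end_onsets <- function(protocol) {
  protocol$train_onsets_s + (protocol$n_reps - 1) * protocol$isi_s
}

#' Minimal session duration covering a protocol
#'
#' Last tone onset plus the post-train observation period needed for echo
#' windows (`k_max` ISIs plus slack).
#' @keywords internal
protocol_min_duration <- function(protocol, k_max = 5, slack_s = 5) {
  max(train_end_onsets(protocol)) + protocol$tone_dur_s +
    k_max * protocol$isi_s + slack_s
}

#' Write / read a protocol as JSON
#'
#' The JSON object carries exactly the keys `frequencies_hz`, `isi_s`,
#' `tone_dur_s`, `n_reps`, `train_onsets_s`, `ramp_s`.
#'
#' @param protocol A `stim_protocol`.
#' @param path File path.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns a `stim_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  x <- unclass(protocol)[c("frequencies_hz", "isi_s", "tone_dur_s",
                           "n_reps", "train_onsets_s", "ramp_s")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("frequencies_hz", "isi_s", "tone_dur_s", "n_reps", "train_onsets_s", "ramp_s")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("protocol file missing fields: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  structure(x[need], class = "stim_protocol")
}
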