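# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so individual files run in seconds.

# compact 3-train protocol used by most unit tests
small_protocol <- function(n_reps = 5, gap_s = 20) {
  make_protocol(n_freqs = 3, f_min_hz = 4000, f_max_hz = 16000,
                n_reps = n_reps, isi_s = 2, tone_dur_s = 0.1,
                gap_s = gap_s, first_onset_s = 30)
}

# a single-neuron ground-truth row with controllable fields
make_gt <- function(neuron_id = "n001", bf_hz = 8000, tuning_sigma_oct = 0.8,
                    evoked_amp = 0.12, spont_rate_hz = 0, is_echo = FALSE,
                    echo_freq_hz = NA_real_, n_echo_events = NA_integer_,
                    echo_amp = NA_real_, echo_latency_s = NA_real_,
                    sound_latency_s = 0.083, noise_sd = 0.006,
                    x_um = 50, y_um = 50) {
  data.frame(neuron_id = neuron_id, bf_hz = bf_hz,
             tuning_sigma_oct = tuning_sigma_oct, evoked_amp = evoked_amp,
             spont_rate_hz = spont_rate_hz, is_echo = is_echo,
             echo_freq_hz = echo_freq_hz, n_echo_events = n_echo_events,
             echo_amp = echo_amp, echo_latency_s = echo_latency_s,
             sound_latency_s = sound_latency_s, noise_sd = noise_sd,
             x_um = x_um, y_um = y_um, stringsAsFactors = FALSE)
}

# calibration preset with all event-level jitter switched off, for exact
# noiseless oracle checks
jitterless_calib <- function() {
  cal <- calibration_preset()
  cal$sound_jitter_sd <- 0
  cal$echo_jitter_sd <- 0
  cal
}

# wrap a numeric vector as a dff_trace
as_dff <- function(x, frame_rate_hz = 40, id = "x") {
  structure(list(neuron_id = id, frame_rate_hz = frame_rate_hz, dff = x,
                 f0 = 1, t0_s = 0), class = "dff_trace")
}

# wrap a numeric vector as a roi_trace
as_roi <- function(f, frame_rate_hz = 40, id = "x") {
  structure(list(neuron_id = id, frame_rate_hz = frame_rate_hz, f = f,
                 t0_s = 0), class = "roi_trace")
}

# brute-force exact two-sided signed-rank p-value (enumerates all 2^n
# sign assignments); the independent oracle for wilcoxon_signed_rank
exact_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.vector(signs %*% r)
  ev <- n * (n + 1) / 4
  mean(abs(v_null - ev) >= abs(v_obs - ev) - 1e-12)
}

# brute-force exact two-sided rank-sum p-value (enumerates all C(m+n, m)
# assignments of ranks to the first group)
exact_rank_sum_p <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  combs <- utils::combn(length(r), m)
  w_null <- colSums(matrix(rank(c(x, y))[combs], nrow = m))
  ev <- m * (length(r) + 1) / 2
  mean(abs(w_null - ev) >= abs(w_obs - ev) - 1e-12)
}
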