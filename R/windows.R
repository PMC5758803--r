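#' Build sound, echo and baseline analysis windows for a protocol
#'
#' For every tone of every train, a sound window `[onset, onset +
#' sound_win_s]`. For every train, `k_max` echo windows centred at the
#' anticipated times `t_end + k * isi_s` (`t_end` = onset of the train's
#' last tone, `k = 1..k_max`) with half-width `echo_halfwidth_s`, and
#' `k_max` baseline windows of the same width tiling the silent period
#' immediately before the train onset.
#'
#' @param protocol A `stim_protocol`.
#' @param sound_win_s Sound-window length in seconds.
#' @param echo_halfwidth_s Echo-window half-width in seconds; must be
#'   smaller than `isi_s / 2` so echo windows stay disjoint.
#' @param k_max Number of anticipated-time windows per train.
#' @return A data.frame with columns `kind` (`"sound"`, `"echo"`,
#'   `"baseline"`), `train`, `freq_hz`, `k` (echo index, `NA` otherwise),
#'   `ref_time_s` (tone onset / anticipated time / window centre) and
#'   `start_s`, `end_s`.
#' @export
build_windows <- function(protocol, sound_win_s = 0.5,
                          echo_halfwidth_s = 0.75, k_max = 5) {
  if (k_max < 0) stop("`k_max` must be >= 0", call. = FALSE)
  if (echo_halfwidth_s >= protocol$isi_s / 2)
    stop("`echo_halfwidth_s` must be < isi_s / 2 (echo windows overlap)",
         call. = FALSE)
  freqs <- protocol$frequencies_hz
  ends <- train_end_onsets(protocol)
  w <- 2 * echo_halfwidth_s
  rows <- list()
  for (tr in seq_along(freqs)) {
    on <- tone_onsets(protocol, tr)
    rows[[length(rows) + 1]] <- data.frame(
      kind = "sound", train = tr, freq_hz = freqs[tr], k = NA_integer_,
      ref_time_s = on, start_s = on, end_s = on + sound_win_s)
    if (k_max >= 1) {
      ctr <- ends[tr] + seq_len(k_max) * protocol$isi_s
      rows[[length(rows) + 1]] <- data.frame(
        kind = "echo", train = tr, freq_hz = freqs[tr], k = seq_len(k_max),
        ref_time_s = ctr, start_s = ctr - echo_halfwidth_s,
        end_s = ctr + echo_halfwidth_s)
      st <- protocol$train_onsets_s[tr] - rev(seq_len(k_max)) * w
      if (any(st < 0))
        stop("pre-train period too short for baseline windows", call. = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        kind = "baseline", train = tr, freq_hz = freqs[tr], k = NA_integer_,
        ref_time_s = st + w / 2, start_s = st, end_s = st + w)
    }
  }
  out <- do.call(rbind, rows)
  # baseline windows must not reach into the previous train's echo span
  if (k_max >= 1 && length(freqs) > 1) {
    for (tr in 2:length(freqs)) {
      prev_end <- ends[tr - 1] + k_max * protocol$isi_s + echo_halfwidth_s
      bl <- out$kind == "baseline" & out$train == tr
      if (any(out$start_s[bl] < prev_end))
        stop("baseline windows overlap the previous train's echo windows;",
             " increase the inter-train gap", call. = FALSE)
    }
  }
  rownames(out) <- NULL
  out
}

# linear interpolation of a dff trace at arbitrary times
dff_at <- function(dff, times) {
  stats::approx(trace_times(dff), dff$dff, xout = times, rule = 2)$y
}

#' Measure the response in one analysis window
#'
#' Peak mode: amplitude is the maximum delta-f/f inside the window minus
#' the delta-f/f at the window start, floored at 0 (units delta-f/f).
#' Integral mode: trapezoidal integral of delta-f/f over
#' `[ref_time_s, ref_time_s + integral_win_s]` (units delta-f/f times s).
#' The latency is the first transient onset inside the window minus
#' `ref_time_s`, or `NA` when the window contains no transient onset.
#'
#' @param dff A `dff_trace`.
#' @param transients Transient table from [detect_transients()].
#' @param w One window: a single-row data.frame from [build_windows()].
#' @param mode `"peak"` or `"integral"`.
#' @param integral_win_s Integration length for integral mode, seconds.
#' @return A list with `amplitude` and `latency_s`.
#' @export
measure_window <- function(dff, transients, w, mode = c("peak", "integral"),
                           integral_win_s = 0.5) {
  mode <- match.arg(mode)
  res <- measure_windows(dff, w, transients, mode, integral_win_s)
  list(amplitude = res$amplitude[1], latency_s = res$latency_s[1])
}

# vectorized measurement over a window table; returns the table with
# `amplitude` and `latency_s` columns appended
measure_windows <- function(dff, windows, transients = NULL,
                            mode = "peak", integral_win_s = 0.5) {
  t <- trace_times(dff)
  x <- dff$dff
  if (any(windows$start_s < t[1] - 1e-9) ||
      any(pmax(windows$end_s,
               windows$ref_time_s + integral_win_s) > t[length(t)] + 1e-9))
    stop("window outside trace extent", call. = FALSE)
  n <- nrow(windows)
  amp <- numeric(n)
  if (mode == "peak") {
    i0 <- findInterval(windows$start_s, t) + 1L  # first frame > start
    i1 <- findInterval(windows$end_s + 1e-9, t)  # last frame <= end
    v0 <- dff_at(dff, windows$start_s)
    for (j in seq_len(n)) {
      m <- if (i1[j] >= i0[j]) max(x[i0[j]:i1[j]]) else -Inf
      amp[j] <- max(m, v0[j]) - v0[j]
    }
  } else {
    a <- windows$ref_time_s
    b <- a + integral_win_s
    i0 <- findInterval(a, t) + 1L
    i1 <- findInterval(b + 1e-9, t)
    va <- dff_at(dff, a)
    vb <- dff_at(dff, b)
    for (j in seq_len(n)) {
      idx <- if (i1[j] >= i0[j]) i0[j]:i1[j] else integer(0)
      tt <- c(a[j], t[idx], b[j])
      vv <- c(va[j], x[idx], vb[j])
      amp[j] <- sum(diff(tt) * (vv[-length(vv)] + vv[-1]) / 2)
    }
  }
  lat <- rep(NA_real_, n)
  if (!is.null(transients) && nrow(transients)) {
    on <- sort(transients$onset_s)
    pos <- findInterval(windows$start_s - 1e-9, on) + 1L
    hit <- pos <= length(on) & on[pmin(pos, length(on))] < windows$end_s
    lat[hit] <- on[pos[hit]] - windows$ref_time_s[hit]
  }
  windows$amplitude <- amp
  windows$latency_s <- lat
  windows
}
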