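#' Detect calcium transients by amplitude and rising-rate thresholds
#'
#' Finds contiguous excursions of the delta-f/f trace above
#' `amp_thresh_sd` times the robust noise SD that last at least
#' `min_dur_s`. Excursions separated by a sub-threshold dip shorter than
#' `min_separation_s` are merged, so a decay shoulder that briefly dips
#' below threshold cannot re-trigger as a separate event. Within an
#' excursion, events that ride on each other's decay (rhythmic responses
#' closer than the decay time) are resolved by peak splitting: a local
#' maximum counts as a distinct event only when the valley separating it
#' from its neighbours drops at least twice the amplitude threshold below
#' it (chained real transients fall nearly to baseline between peaks,
#' noise ripples on a decay tail do not).
#' The onset of an excursion's first event is the threshold crossing
#' immediately before it, linearly interpolated between the straddling
#' frames; the onset of a subsequent chained event is the valley preceding
#' its peak. The onset-to-peak rise rate must reach `rise_thresh`, and an
#' event whose onset follows the previous onset by less than
#' `min_separation_s` is discarded. Events are returned sorted by onset.
#'
#' @param dff A `dff_trace`.
#' @param amp_thresh_sd Amplitude threshold as a multiple of the noise SD.
#' @param rise_thresh Minimum onset-to-peak rise rate in delta-f/f per
#'   second.
#' @param min_dur_s Minimum supra-threshold duration in seconds.
#' @param min_separation_s Minimum onset-to-onset separation in seconds.
#' @param noise_sd Noise SD in delta-f/f units; estimated with
#'   [estimate_noise_sd()] when `NULL`.
#' @return A data.frame of transients (`neuron_id`, `onset_s`, `peak_s`,
#'   `peak_amp`, `rise_rate`, `offset_s`), possibly empty.
#' @export
detect_transients <- function(dff, amp_thresh_sd = 3, rise_thresh = 0.1,
                              min_dur_s = 0.1, min_separation_s = 0.2,
                              noise_sd = NULL) {
  if (amp_thresh_sd <= 0 || rise_thresh <= 0 || min_dur_s <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  x <- dff$dff
  fr <- dff$frame_rate_hz
  dt <- 1 / fr
  t <- trace_times(dff)
  if (is.null(noise_sd)) noise_sd <- suppressWarnings(estimate_noise_sd(dff))
  empty <- data.frame(neuron_id = character(), onset_s = numeric(),
                      peak_s = numeric(), peak_amp = numeric(),
                      rise_rate = numeric(), offset_s = numeric())
  if (noise_sd <= 0) return(empty)
  thr <- amp_thresh_sd * noise_sd

  above <- x > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  # merge excursions separated by a sub-threshold dip shorter than the
  # separation scale: a decay shoulder dipping below threshold must not
  # re-trigger as a second event
  nab <- ends - starts + 1L
  if (length(starts) > 1) {
    gap <- (starts[-1] - ends[-length(ends)]) * dt
    grp <- cumsum(c(1L, gap >= min_separation_s))
    nab <- as.integer(tapply(nab, grp, sum))  # supra-threshold frames only
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
  }
  keep <- nab * dt >= min_dur_s
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(empty)

  out <- lapply(seq_along(starts), function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    peaks <- i0 - 1L + split_peaks(x[i0:i1], prom = 2 * thr,
                                   min_sep = ceiling(min_separation_s / dt))
    exc_onset <- if (i0 == 1L) t[1] else
      t[i0 - 1L] + (thr - x[i0 - 1L]) / (x[i0] - x[i0 - 1L]) * dt
    exc_offset <- if (i1 == length(x)) t[length(x)] else
      t[i1] + (x[i1] - thr) / (x[i1] - x[i1 + 1L]) * dt
    np <- length(peaks)
    onset_s <- base <- numeric(np)
    offset_s <- numeric(np)
    for (q in seq_len(np)) {
      if (q == 1L) { onset_s[q] <- exc_onset; base[q] <- thr } else {
        iv <- peaks[q - 1L] + which.min(x[peaks[q - 1L]:peaks[q]]) - 1L
        lvl <- x[iv] + thr  # local-baseline crossing level
        below <- which(x[iv:peaks[q]] < lvl)
        if (length(below)) {
          jb <- iv + max(below) - 1L
          onset_s[q] <- t[jb] + (lvl - x[jb]) / (x[jb + 1L] - x[jb]) * dt
        } else onset_s[q] <- t[iv]
        base[q] <- lvl
      }
      offset_s[q] <- if (q == np) exc_offset else
        t[peaks[q] + which.min(x[peaks[q]:peaks[q + 1L]]) - 1L]
    }
    peak_amp <- x[peaks]
    rise_rate <- (peak_amp - base) / pmax(t[peaks] - onset_s, dt / 2)
    data.frame(neuron_id = rep(dff$neuron_id %||% NA_character_, np),
               onset_s = onset_s, peak_s = t[peaks], peak_amp = peak_amp,
               rise_rate = rise_rate, offset_s = offset_s)
  })
  out <- do.call(rbind, out)
  # local-baseline criterion: the peak must rise at least one threshold
  # above the median level of the 0.3 s preceding the onset, so that the
  # decay tail of a large transient hovering around the absolute threshold
  # cannot re-trigger ghost events
  pre_base <- vapply(out$onset_s, function(on) {
    idx <- which(t >= on - 0.3 & t < on)
    if (length(idx)) stats::median(x[idx]) else 0
  }, 1)
  out <- out[out$peak_amp - pre_base >= thr, , drop = FALSE]
  out <- out[out$rise_rate >= rise_thresh, , drop = FALSE]
  if (nrow(out) > 1) {
    keep <- c(TRUE, diff(out$onset_s) >= min_separation_s)
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# indices of distinct event peaks within one supra-threshold segment:
# greedy prominence splitting — a candidate local maximum survives only if
# the valley between it and every already-accepted (taller or earlier
# accepted) peak drops at least `prom` below the candidate, and it keeps
# `min_sep` frames from accepted peaks
split_peaks <- function(seg, prom, min_sep) {
  n <- length(seg)
  if (n == 1L) return(1L)
  is_max <- c(seg[1] >= seg[2],
              if (n > 2) seg[2:(n - 1)] >= seg[1:(n - 2)] &
                seg[2:(n - 1)] > seg[3:n] else NULL,
              seg[n] > seg[n - 1])
  cand <- which(is_max)
  cand <- cand[order(seg[cand], decreasing = TRUE)]
  acc <- integer(0)
  for (c in cand) {
    ok <- TRUE
    for (a in acc) {
      rng <- if (a < c) a:c else c:a
      if (abs(c - a) < min_sep || seg[c] - min(seg[rng]) < prom) {
        ok <- FALSE; break
      }
    }
    if (ok) acc <- c(acc, c)
  }
  sort(acc)
}

#' Extract ROI traces from an image stack
#'
#' Per frame, the trace value is the arithmetic mean of the pixel
#' intensities inside the ROI mask.
#'
#' @param image_stack A numeric array `[rows, cols, frames]`.
#' @param rois A list of logical masks (`rows x cols`) or two-column pixel
#'   index matrices (row, col).
#' @param frame_rate_hz Sampling rate of the stack.
#' @param t0_s Time of the first frame.
#' @param ids Optional character vector of ROI identifiers.
#' @return A named list of `roi_trace` objects.
#' @export
extract_roi_traces <- function(image_stack, rois, frame_rate_hz = 40,
                               t0_s = 0, ids = NULL) {
  if (length(dim(image_stack)) != 3)
    stop("`image_stack` must be a [rows, cols, frames] array", call. = FALSE)
  d <- dim(image_stack)
  npix <- d[1] * d[2]
  flat <- matrix(image_stack, nrow = npix, ncol = d[3])
  if (is.null(ids)) ids <- sprintf("roi%02d", seq_along(rois))
  traces <- lapply(seq_along(rois), function(i) {
    m <- rois[[i]]
    lin <- if (is.matrix(m) && !is.logical(m)) {
      if (any(m[, 1] < 1 | m[, 1] > d[1] | m[, 2] < 1 | m[, 2] > d[2]))
        stop("ROI pixels outside frame bounds", call. = FALSE)
      (m[, 2] - 1) * d[1] + m[, 1]
    } else {
      if (!identical(dim(m), d[1:2]))
        stop("mask dimensions must match the frame", call. = FALSE)
      which(m)
    }
    if (!length(lin)) stop("empty ROI mask", call. = FALSE)
    f <- if (length(lin) == 1) flat[lin, ] else colMeans(flat[lin, , drop = FALSE])
    structure(list(neuron_id = ids[i], frame_rate_hz = frame_rate_hz,
                   f = as.numeric(f), t0_s = t0_s), class = "roi_trace")
  })
  names(traces) <- ids
  traces
}

#' Render traces into a synthetic image stack
#'
#' Builds a small synthetic movie in which every pixel of an ROI carries
#' its neuron's fluorescence value over a uniform background, for testing
#' [extract_roi_traces()] end to end. Off the main simulation path.
#'
#' @param traces A list of `roi_trace` objects (equal lengths).
#' @param rois Logical masks, one per trace, all of the same dimension.
#' @param background Background intensity.
#' @return A numeric array `[rows, cols, frames]`.
#' @export
render_stack <- function(traces, rois, background = 0) {
  stopifnot(length(traces) == length(rois), length(traces) >= 1)
  d <- dim(rois[[1]])
  nf <- length(traces[[1]]$f)
  stack <- array(background, dim = c(d[1], d[2], nf))
  flat <- matrix(stack, nrow = d[1] * d[2])
  for (i in seq_along(traces)) flat[which(rois[[i]]), ] <-
    matrix(traces[[i]]$f, nrow = sum(rois[[i]]), ncol = nf, byrow = TRUE)
  array(flat, dim = c(d[1], d[2], nf))
}
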