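#' Compute relative fluorescence change (delta-f/f)
#'
#' Normalizes a raw ROI fluorescence trace by its percentile baseline:
#' `f0` is the 25th percentile of the whole single-trial trace (linear
#' interpolation convention, [stats::quantile()] type 7) and
#' `dff = (f - f0) / f0`.
#'
#' @param trace A `roi_trace` (or any list with `f`, `frame_rate_hz`,
#'   `neuron_id`, `t0_s`).
#' @param probs Baseline percentile, default 0.25.
#' @return A `dff_trace`: list with `neuron_id`, `frame_rate_hz`, `dff`,
#'   `f0` and `t0_s`.
#' @examples
#' tr <- structure(list(neuron_id = "a", frame_rate_hz = 1,
#'                      f = c(8, 10, 12, 10), t0_s = 0), class = "roi_trace")
#' compute_dff(tr)$f0 # 9.5
#' @export
compute_dff <- function(trace, probs = 0.25) {
  f <- trace$f
  if (length(f) < 2 || any(!is.finite(f)))
    stop("trace must be finite with length >= 2", call. = FALSE)
  f0 <- unname(stats::quantile(f, probs = probs, type = 7))
  if (f0 <= 0)
    stop("degenerate baseline: 25th percentile of fluorescence is <= 0",
         call. = FALSE)
  structure(list(neuron_id = trace$neuron_id,
                 frame_rate_hz = trace$frame_rate_hz,
                 dff = (f - f0) / f0, f0 = f0, t0_s = trace$t0_s),
            class = "dff_trace")
}

#' Robust noise SD of a delta-f/f trace
#'
#' Estimates the imaging-noise standard deviation as
#' `1.4826 * mad(diff(dff)) / sqrt(2)`: first differencing whitens slow
#' transients (their frame-to-frame increments are small relative to the
#' noise), and the median absolute deviation is insensitive to the sparse
#' large increments at event onsets. For white Gaussian noise the estimate
#' is consistent for the per-frame SD.
#'
#' @param dff A `dff_trace` (or numeric vector).
#' @return Noise SD in delta-f/f units; 0 (with a warning) for a constant
#'   trace.
#' @export
estimate_noise_sd <- function(dff) {
  x <- if (is.list(dff)) dff$dff else dff
  if (length(x) < 50) stop("need >= 50 frames to estimate noise", call. = FALSE)
  d <- diff(x)
  s <- stats::mad(d, constant = 1.4826) / sqrt(2)
  if (s == 0) warning("constant trace: noise SD is 0")
  s
}
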