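#' Calcium-indicator transient kernel
#'
#' Unit-peak double-exponential impulse response used by the forward model,
#' `h(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / N` for `t >= 0`, with
#' `N` chosen so that `max h = 1`. The defaults (rise 0.07 s, decay 0.7 s)
#' emulate a fast synthetic indicator such as Cal-520 reporting one to a
#' few action potentials.
#'
#' @param t Times in seconds relative to kernel onset (values < 0 give 0).
#' @param tau_rise,tau_decay Rise and decay time constants in seconds;
#'   `tau_decay > tau_rise > 0`.
#' @return Kernel values, peak normalized to 1.
#' @examples
#' max(calcium_kernel(seq(0, 5, by = 0.001))) # 1
#' @export
calcium_kernel <- function(t, tau_rise = 0.07, tau_decay = 0.7) {
  if (tau_rise <= 0 || tau_decay <= tau_rise)
    stop("need tau_decay > tau_rise > 0", call. = FALSE)
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  out[pos] <- (exp(-tp / tau_decay) - exp(-tp / tau_rise)) / kernel_peak(tau_rise, tau_decay)
  out
}

# raw (un-normalized) peak value and its time
kernel_time_to_peak <- function(tau_rise = 0.07, tau_decay = 0.7) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

kernel_peak <- function(tau_rise = 0.07, tau_decay = 0.7) {
  tp <- kernel_time_to_peak(tau_rise, tau_decay)
  exp(-tp / tau_decay) - exp(-tp / tau_rise)
}

#' Closed-form integral of the transient kernel
#'
#' Integral of [calcium_kernel()] over `[0, t_end]`, used as the analytic
#' oracle for trapezoidal response integrals.
#'
#' @param t_end Upper integration limit in seconds.
#' @inheritParams calcium_kernel
#' @return The integral in units of peak-normalized amplitude times seconds.
#' @export
kernel_integral <- function(t_end, tau_rise = 0.07, tau_decay = 0.7) {
  if (any(t_end < 0)) stop("`t_end` must be >= 0", call. = FALSE)
  (tau_decay * (1 - exp(-t_end / tau_decay)) -
     tau_rise * (1 - exp(-t_end / tau_rise))) / kernel_peak(tau_rise, tau_decay)
}
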