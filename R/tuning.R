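#' Build a frequency tuning curve from 500-ms response integrals
#'
#' For each stimulus frequency, integrates the delta-f/f trace over
#' `integral_win_s` (default 500 ms) from each of the train's tone onsets
#' (trapezoidal rule) and averages over the `n_reps` tones. The normalized
#' curve rescales the mean responses to a maximum of 1.
#'
#' @param dff A `dff_trace`.
#' @param protocol A `stim_protocol` whose trains are covered by the trace.
#' @param integral_win_s Integration window in seconds.
#' @return A `tuning_curve`: list with `neuron_id`, `freqs_hz`,
#'   `mean_resp`, `sem_resp` and `norm_resp`.
#' @export
build_tuning_curve <- function(dff, protocol, integral_win_s = 0.5) {
  freqs <- protocol$frequencies_hz
  t_end <- trace_times(dff)[length(dff$dff)]
  if (max(train_end_onsets(protocol)) + integral_win_s > t_end)
    stop("trains extend beyond the trace", call. = FALSE)
  mean_resp <- sem_resp <- numeric(length(freqs))
  for (tr in seq_along(freqs)) {
    on <- tone_onsets(protocol, tr)
    w <- data.frame(ref_time_s = on, start_s = on,
                    end_s = on + integral_win_s)
    vals <- measure_windows(dff, w, NULL, mode = "integral",
                            integral_win_s = integral_win_s)$amplitude
    mean_resp[tr] <- mean(vals)
    sem_resp[tr] <- stats::sd(vals) / sqrt(length(vals))
  }
  norm <- if (max(mean_resp) > 0) mean_resp / max(mean_resp) else
    rep(0, length(freqs))
  structure(list(neuron_id = dff$neuron_id, freqs_hz = freqs,
                 mean_resp = mean_resp, sem_resp = sem_resp,
                 norm_resp = norm), class = "tuning_curve")
}

#' Fit a Gaussian to a tuning curve on the log2-frequency axis
#'
#' Least-squares fit of `amp * exp(-(x - mu)^2 / (2 sigma^2)) + offset`
#' with `x = log2(freq_hz / 1000)`, via Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) with multi-start initialization (centre at the
#' curve argmax and at the response-weighted centroid). When the optimizer
#' fails, the fitted width exceeds the stimulus band, or the curve is flat,
#' the fit is flagged `converged = FALSE` and the argmax frequency serves
#' as the fallback centre.
#'
#' @param curve A `tuning_curve` (or any list with `freqs_hz` and a
#'   response vector in `mean_resp`).
#' @return A `gaussian_fit`: list with `amp`, `mu_log2`, `sigma_log2`,
#'   `offset`, `rss`, `converged`.
#' @export
fit_gaussian <- function(curve) {
  x <- log2(curve$freqs_hz / 1000)
  y <- curve$mean_resp
  if (length(unique(curve$freqs_hz)) < 4)
    stop("need >= 4 distinct frequencies for a Gaussian fit", call. = FALSE)
  band <- diff(range(x))
  fallback <- list(amp = max(y) - min(y), mu_log2 = x[which.max(y)],
                   sigma_log2 = NA_real_, offset = min(y), rss = NA_real_,
                   converged = FALSE)
  if (diff(range(y)) <= 0)
    return(structure(fallback, class = "gaussian_fit"))

  w <- y - min(y)
  centroid <- sum(x * w) / max(sum(w), .Machine$double.eps)
  starts <- list(
    c(mu = x[which.max(y)], sigma = band / 4),
    c(mu = centroid, sigma = band / 2))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ amp * exp(-(x - mu)^2 / (2 * sigma^2)) + offset,
        start = list(amp = max(y) - min(y), mu = s[["mu"]],
                     sigma = s[["sigma"]], offset = min(y)),
        lower = c(amp = 0, mu = min(x) - band, sigma = 1e-3,
                  offset = -Inf),
        upper = c(amp = Inf, mu = max(x) + band, sigma = 10 * band,
                  offset = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- c(as.list(stats::coef(fit)), list(rss = rss))
    }
  }
  if (is.null(best) || best$sigma > band)
    return(structure(fallback, class = "gaussian_fit"))
  structure(list(amp = best$amp, mu_log2 = best$mu, sigma_log2 = best$sigma,
                 offset = best$offset, rss = best$rss, converged = TRUE),
            class = "gaussian_fit")
}

#' Best frequency of a neuron
#'
#' The Gaussian-fit centre converted back to Hz (`2^mu_log2 * 1000`) and
#' clamped to the stimulus band when the fit converged; otherwise the
#' argmax stimulus frequency. An all-zero curve has no best frequency.
#'
#' @param curve A `tuning_curve`.
#' @param fit A `gaussian_fit` for the curve; computed when missing.
#' @return Best frequency in Hz, or `NA` for a flat/all-zero curve.
#' @export
best_frequency <- function(curve, fit = NULL) {
  if (max(curve$norm_resp) <= 0) return(NA_real_)
  if (is.null(fit)) fit <- fit_gaussian(curve)
  if (isTRUE(fit$converged)) {
    bf <- 2^fit$mu_log2 * 1000
    return(min(max(bf, min(curve$freqs_hz)), max(curve$freqs_hz)))
  }
  curve$freqs_hz[which.max(curve$mean_resp)]
}

#' Delta-frequency records for an echo neuron
#'
#' One record per distinct echo-evoking frequency:
#' `delta_oct = log2(echo_freq_hz / bf_hz)`, the octave distance between
#' the frequency whose train elicited the echo and the tone-evoked best
#' frequency.
#'
#' @param bf_hz Best frequency in Hz (from [best_frequency()]).
#' @param cls An `echo_classification` with `is_echo = TRUE`.
#' @return A data.frame (`neuron_id`, `bf_hz`, `echo_freq_hz`,
#'   `delta_oct`), empty (with a warning) when the best frequency is
#'   missing.
#' @export
delta_frequency <- function(bf_hz, cls) {
  empty <- data.frame(neuron_id = character(), bf_hz = numeric(),
                      echo_freq_hz = numeric(), delta_oct = numeric())
  if (!isTRUE(cls$is_echo) || !length(cls$echo_freqs_hz)) return(empty)
  if (is.na(bf_hz)) {
    warning("missing best frequency; skipping neuron ", cls$neuron_id)
    return(empty)
  }
  data.frame(neuron_id = cls$neuron_id, bf_hz = bf_hz,
             echo_freq_hz = cls$echo_freqs_hz,
             delta_oct = log2(cls$echo_freqs_hz / bf_hz))
}

#' Histogram and Gaussian fit of the delta-frequency distribution
#'
#' Bins the octave differences into bins of width `bin_oct` centred on 0
#' and fits a Gaussian to the bin counts. With fewer than `min_fit`
#' records, or fewer than 4 occupied-range bins, only the histogram and
#' the count-weighted mean are returned and the fit is flagged
#' unavailable.
#'
#' @param records Data.frame of delta-frequency records (column
#'   `delta_oct`), as from [delta_frequency()].
#' @param bin_oct Bin width in octaves; the default is one stimulus step
#'   of the 11-tone 2-40 kHz grid, `log2(20)/10`.
#' @param min_fit Minimum records for fitting.
#' @return A list with `breaks`, `mids`, `counts`, `center_oct` (Gaussian
#'   centre, or the count-weighted mean when no fit), `fit` (a
#'   `gaussian_fit` or `NULL`) and `fit_available`.
#' @export
delta_histogram <- function(records, bin_oct = log2(20) / 10, min_fit = 5) {
  d <- records$delta_oct
  if (!length(d)) stop("no delta-frequency records", call. = FALSE)
  m <- max(abs(d), bin_oct)
  half <- (floor(m / bin_oct) + 1)
  breaks <- seq(-half * bin_oct - bin_oct / 2, half * bin_oct + bin_oct / 2,
                by = bin_oct)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  fit <- NULL
  center <- sum(h$mids * h$counts) / sum(h$counts)
  if (length(d) >= min_fit && sum(h$counts > 0) >= 4) {
    fit <- tryCatch(fit_gaussian(list(freqs_hz = 1000 * 2^h$mids,
                                      mean_resp = h$counts)),
                    error = function(e) NULL)
    if (!is.null(fit) && isTRUE(fit$converged)) center <- fit$mu_log2
  }
  list(breaks = h$breaks, mids = h$mids, counts = h$counts,
       center_oct = center, fit = fit,
       fit_available = !is.null(fit) && isTRUE(fit$converged))
}

#' Population-average tuning curve aligned on best frequency
#'
#' Averages normalized tuning curves after centring each neuron's
#' frequency axis on its best frequency, the standard way of displaying
#' the population tuning of echo neurons.
#'
#' @param curves List of `tuning_curve` objects.
#' @param bfs_hz Best frequencies, one per curve (Hz); curves with `NA`
#'   are dropped.
#' @param step_oct Octave grid step for alignment.
#' @return A data.frame with `delta_oct`, `mean_norm_resp`, `n`.
#' @export
average_tuning <- function(curves, bfs_hz, step_oct = log2(20) / 10) {
  stopifnot(length(curves) == length(bfs_hz))
  keep <- !is.na(bfs_hz)
  rows <- lapply(which(keep), function(i) {
    d <- log2(curves[[i]]$freqs_hz / bfs_hz[i])
    data.frame(bin = round(d / step_oct), resp = curves[[i]]$norm_resp)
  })
  if (!length(rows)) stop("no curves with a defined best frequency", call. = FALSE)
  all <- do.call(rbind, rows)
  agg <- stats::aggregate(resp ~ bin, data = all, FUN = mean)
  n <- stats::aggregate(resp ~ bin, data = all, FUN = length)
  data.frame(delta_oct = agg$bin * step_oct, mean_norm_resp = agg$resp,
             n = n$resp)
}
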