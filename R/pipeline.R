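#' Analysis settings
#'
#' Every tunable threshold of the analysis stages, with the package
#' defaults. These are the pipeline's operationalization of criteria the
#' underlying experimental literature names but does not quantify; all are
#' overridable here and from the CLI config.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of settings.
#' @export
echotune_settings <- function(...) {
  s <- list(
    amp_thresh_sd = 3,        # transient amplitude threshold, x noise SD
    rise_thresh = 0.1,        # onset-to-peak rise rate, df/f per s
    min_dur_s = 0.1,          # minimum supra-threshold duration, s
    min_separation_s = 0.2,   # minimum onset-to-onset separation, s
    sound_win_s = 0.5,        # sound-response window, s
    echo_halfwidth_s = 0.75,  # anticipated-time window half-width, s
    k_max = 5,                # anticipated times tested per train
    alpha = 0.05,             # echo-classification significance level
    prior_count = 0.5,        # Jeffreys pseudo-count for the null rate
    integral_win_s = 0.5,     # tuning-curve integration window, s
    r_um = 50,                # spatial neighbourhood radius, um
    n_perm = 9999,            # spatial permutation count
    bin_oct = log2(20) / 10,  # delta-frequency bin width, octaves
    min_delta_records = 5     # records needed for the delta-frequency fit
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(s))
  if (length(bad)) stop("unknown settings: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  s[names(ov)] <- ov
  s
}

#' Analyze one imaging session
#'
#' Runs the full per-session pipeline on raw ROI traces: delta-f/f
#' normalization, transient detection, spontaneous-rate estimation, echo
#' classification, per-neuron response summaries, frequency tuning with
#' Gaussian fits and best frequencies, delta-frequency records for the
#' echo neurons, and (when centroid coordinates are supplied) the spatial
#' heterogeneity permutation test on the echo-frequency map.
#'
#' @param traces Named list of `roi_trace` objects (or an `echo_session`,
#'   whose traces, protocol and coordinates are used).
#' @param protocol A `stim_protocol` (taken from the session when omitted).
#' @param settings Analysis settings, see [echotune_settings()].
#' @param xy Optional data.frame with `neuron_id`, `x_um`, `y_um`.
#' @param with_tuning Compute tuning curves/fits (the slowest stage).
#' @param seed Seed for the spatial permutation test.
#' @return A list with `summaries` (one row per neuron), `transients`,
#'   `classifications`, `tuning` (curves, fits data.frame with `bf_hz`),
#'   `delta` (delta-frequency records), `spatial` and `settings`.
#' @export
analyze_session <- function(traces, protocol = NULL,
                            settings = echotune_settings(), xy = NULL,
                            with_tuning = TRUE, seed = 1) {
  if (inherits(traces, "echo_session")) {
    ses <- traces
    protocol <- protocol %||% ses$protocol
    if (is.null(xy)) xy <- ses$ground_truth[c("neuron_id", "x_um", "y_um")]
    traces <- ses$traces
  }
  if (is.null(protocol)) stop("`protocol` is required", call. = FALSE)
  windows <- build_windows(protocol, sound_win_s = settings$sound_win_s,
                           echo_halfwidth_s = settings$echo_halfwidth_s,
                           k_max = settings$k_max)
  summaries <- vector("list", length(traces))
  trans_all <- vector("list", length(traces))
  cls_all <- vector("list", length(traces))
  curves <- vector("list", length(traces))
  fits <- vector("list", length(traces))
  delta <- vector("list", length(traces))

  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    dff <- compute_dff(tr)
    tt <- trace_times(dff)
    trans <- detect_transients(dff, amp_thresh_sd = settings$amp_thresh_sd,
                               rise_thresh = settings$rise_thresh,
                               min_dur_s = settings$min_dur_s,
                               min_separation_s = settings$min_separation_s)
    rate <- estimate_spont_rate(trans, protocol,
                                trace_extent = c(tt[1], tt[length(tt)]),
                                k_max = settings$k_max,
                                echo_halfwidth_s = settings$echo_halfwidth_s,
                                prior_count = settings$prior_count)
    cls <- classify_echo(trans, windows, spont_rate_hz = rate,
                         alpha = settings$alpha, neuron_id = tr$neuron_id)
    sm <- summarize_neuron(dff, trans, windows, cls)
    sm$spont_rate_hz <- rate
    if (with_tuning) {
      curve <- build_tuning_curve(dff, protocol,
                                  integral_win_s = settings$integral_win_s)
      # protocols with < 4 tones cannot support a Gaussian fit; fall back
      # to the argmax best frequency
      fit <- if (length(unique(protocol$frequencies_hz)) >= 4)
        fit_gaussian(curve)
      else structure(list(amp = max(curve$mean_resp) - min(curve$mean_resp),
                          mu_log2 = log2(curve$freqs_hz[
                            which.max(curve$mean_resp)] / 1000),
                          sigma_log2 = NA_real_, offset = min(curve$mean_resp),
                          rss = NA_real_, converged = FALSE),
                     class = "gaussian_fit")
      bf <- best_frequency(curve, fit)
      curves[[i]] <- curve
      fits[[i]] <- data.frame(neuron_id = tr$neuron_id, amp = fit$amp,
                              mu_log2 = fit$mu_log2,
                              sigma_log2 = fit$sigma_log2,
                              offset = fit$offset, rss = fit$rss,
                              converged = fit$converged, bf_hz = bf)
      sm$bf_hz <- bf
      if (cls$is_echo)
        delta[[i]] <- suppressWarnings(delta_frequency(bf, cls))
    }
    summaries[[i]] <- sm
    trans_all[[i]] <- trans
    cls_all[[i]] <- cls
  }
  summaries <- do.call(rbind, summaries)
  res <- list(
    summaries = summaries,
    transients = do.call(rbind, trans_all),
    classifications = stats::setNames(cls_all, summaries$neuron_id),
    tuning = if (with_tuning)
      list(curves = stats::setNames(curves, summaries$neuron_id),
           fits = do.call(rbind, fits)) else NULL,
    delta = if (with_tuning) {
      d <- delta[!vapply(delta, is.null, TRUE)]
      if (length(d)) do.call(rbind, d) else NULL
    } else NULL,
    spatial = NULL, settings = settings)

  if (!is.null(xy)) {
    echo <- summaries$neuron_id[summaries$is_echo]
    m <- merge(data.frame(neuron_id = echo),
               merge(xy, summaries[c("neuron_id", "echo_freq_hz")]))
    m <- m[!is.na(m$echo_freq_hz), , drop = FALSE]
    res$spatial <- spatial_heterogeneity(m$x_um, m$y_um, m$echo_freq_hz,
                                         r_um = settings$r_um,
                                         n_perm = settings$n_perm,
                                         seed = seed)
  }
  res
}

#' Simulate and analyze a multi-session synthetic study
#'
#' Generates `n_sessions` independent synthetic imaging sessions from a
#' calibration preset and runs the analysis pipeline on each, pooling the
#' per-neuron summaries into a population summary and the echo neurons
#' into a delta-frequency distribution. This is the package's end-to-end
#' parameter-recovery harness.
#'
#' @param n_sessions,n_neurons Study size.
#' @param seed Integer master seed; each session derives its own seed from
#'   it (kept within the 32-bit integer range).
#' @param calib Calibration preset.
#' @param protocol A `stim_protocol`.
#' @param settings Analysis settings.
#' @param with_tuning Compute tuning and delta-frequency stages.
#' @return A list with `population` ([summarize_population()] output),
#'   `delta` (pooled records), `delta_center_oct` and `delta_center_se`
#'   (Gaussian-fit centre of the delta histogram and the SE of the record
#'   mean), `session_summaries`, and `ground_truth` (pooled).
#' @export
run_synthetic_study <- function(n_sessions = 8, n_neurons = 100, seed = 1,
                                calib = calibration_preset(),
                                protocol = make_protocol(),
                                settings = echotune_settings(),
                                with_tuning = TRUE) {
  per_session <- vector("list", n_sessions)
  delta <- vector("list", n_sessions)
  gt <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    seed_s <- (abs(seed) %% 1000003) * 1000 + s  # stays below 2^31
    ses <- synthesize_session(n_neurons = n_neurons, protocol = protocol,
                              calib = calib, seed = seed_s)
    res <- analyze_session(ses, settings = settings,
                           with_tuning = with_tuning, seed = seed_s)
    per_session[[s]] <- res$summaries
    delta[[s]] <- res$delta
    g <- ses$ground_truth
    g$session <- s
    gt[[s]] <- g
  }
  delta <- do.call(rbind, delta[!vapply(delta, is.null, TRUE)])
  out <- list(population = summarize_population(per_session),
              delta = delta, session_summaries = per_session,
              ground_truth = do.call(rbind, gt))
  if (!is.null(delta) && nrow(delta) >= 5) {
    dh <- delta_histogram(delta, bin_oct = settings$bin_oct,
                          min_fit = settings$min_delta_records)
    out$delta_center_oct <- dh$center_oct
    out$delta_center_se <- stats::sd(delta$delta_oct) / sqrt(nrow(delta))
  }
  out
}
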