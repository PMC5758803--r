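#' Wilcoxon tests used by the population comparisons
#'
#' Thin, argument-checked fronts over [stats::wilcox.test()].
#' `wilcoxon_signed_rank` is the paired two-sided signed-rank test (exact
#' null for n <= 25 without ties or zero differences, otherwise the
#' normal approximation with continuity correction);
#' `wilcoxon_rank_sum` is the unpaired two-sided Mann-Whitney test (exact
#' for small tie-free samples, tie-corrected normal approximation
#' otherwise).
#'
#' @param x,y Paired (signed-rank) or independent (rank-sum) samples.
#' @return The two-sided p-value.
#' @examples
#' wilcoxon_signed_rank(1:6 + c(1, 2, 3, 4, 5, 6), 1:6) # 2/2^6
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length",
                                   call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero: test undefined",
                       call. = FALSE)
  if (length(d) < 5)
    stop("need >= 5 non-zero paired differences", call. = FALSE)
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = exact,
                       correct = TRUE)$p.value)
}

#' @rdname wilcoxon_signed_rank
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group", call. = FALSE)
  if (length(x) < 4 || length(y) < 4)
    stop("each group needs >= 4 observations", call. = FALSE)
  exact <- length(x) <= 25 && length(y) <= 25 &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Pool per-neuron summaries into population statistics
#'
#' The echo-neuron fraction is computed per session and then averaged
#' (mean and SEM across sessions, the per-animal semantics of the
#' population percentage). Amplitudes are pooled over all neurons across
#' sessions: a neuron contributes its response amplitude where responses
#' exist (classified echo events; responsive sound windows) and its
#' unconditional window amplitude (the activity level at the matched
#' times) otherwise. Latencies are pooled over neurons with defined
#' responses only. Three Wilcoxon comparisons accompany the means: paired
#' signed-rank for echo amplitude against baseline activity over all
#' neurons, unpaired rank-sum for sound against echo amplitude and for
#' sound against echo latency.
#'
#' @param sessions A list of per-session data.frames of neuron summaries
#'   (rows from [summarize_neuron()]).
#' @return A `population_summary` list; SEMs accompany every mean, and
#'   echo fields are `NA` when no echo neurons exist.
#' @export
summarize_population <- function(sessions) {
  if (!length(sessions)) stop("need >= 1 session", call. = FALSE)
  frac <- vapply(sessions, function(s) 100 * mean(s$is_echo), 1)
  all <- do.call(rbind, sessions)
  n <- nrow(all)

  # all-neuron amplitude pooling with window-level fallback
  amp_echo_all <- ifelse(all$is_echo & !is.na(all$echo_amp), all$echo_amp,
                         all$echo_win_amp)
  amp_sound_all <- ifelse(!is.na(all$sound_amp), all$sound_amp,
                          all$sound_win_amp)
  lat_sound <- all$sound_latency_s[!is.na(all$sound_latency_s)]
  lat_echo <- all$echo_latency_s[all$is_echo & !is.na(all$echo_latency_s)]
  amp_echo_neurons <- all$echo_amp[all$is_echo & !is.na(all$echo_amp)]

  p_eb <- tryCatch(wilcoxon_signed_rank(amp_echo_all, all$baseline_amp),
                   error = function(e) NA_real_)
  p_se <- tryCatch(wilcoxon_rank_sum(amp_sound_all, amp_echo_all),
                   error = function(e) NA_real_)
  p_lat <- tryCatch(wilcoxon_rank_sum(lat_sound, lat_echo),
                    error = function(e) NA_real_)

  structure(list(
    n_neurons = n, n_sessions = length(sessions),
    echo_fraction_mean = mean(frac), echo_fraction_sem = sem(frac),
    amp_echo_mean = mean(amp_echo_all, na.rm = TRUE),
    amp_echo_sem = sem(amp_echo_all),
    amp_echo_event_mean = if (length(amp_echo_neurons))
      mean(amp_echo_neurons) else NA_real_,
    amp_baseline_mean = mean(all$baseline_amp, na.rm = TRUE),
    amp_baseline_sem = sem(all$baseline_amp),
    amp_sound_mean = mean(amp_sound_all, na.rm = TRUE),
    amp_sound_sem = sem(amp_sound_all),
    lat_sound_mean = if (length(lat_sound)) mean(lat_sound) else NA_real_,
    lat_sound_sem = sem(lat_sound),
    lat_echo_mean = if (length(lat_echo)) mean(lat_echo) else NA_real_,
    lat_echo_sem = sem(lat_echo),
    p_amp_echo_vs_baseline = p_eb,
    p_amp_sound_vs_echo = p_se,
    p_lat_sound_vs_echo = p_lat), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<population_summary> %d neurons / %d sessions\n",
    "  echo fraction  %.1f%% +/- %.1f%%\n",
    "  amplitudes (df/f): echo %.4f, baseline %.4f, sound %.4f\n",
    "  latencies (s): sound %.3f, echo %.3f\n"),
    x$n_neurons, x$n_sessions, x$echo_fraction_mean, x$echo_fraction_sem,
    x$amp_echo_mean, x$amp_baseline_mean, x$amp_sound_mean,
    x$lat_sound_mean, x$lat_echo_mean))
  invisible(x)
}

#' Permutation test for spatial heterogeneity of the echo-frequency map
#'
#' The statistic is the mean absolute octave difference
#' `|log2(f_i / f_j)|` of echo-evoking frequencies over all pairs of echo
#' neurons closer than `r_um`. The null distribution is built by
#' shuffling the frequency labels across the echo-neuron positions; the
#' p-value `(1 + #{null <= observed}) / (n_perm + 1)` tests the local
#' *similarity* alternative, so small p means tonotopic clustering and a
#' large p means the map is locally mixed (heterogeneous).
#'
#' @param x_um,y_um Echo-neuron centroid coordinates in micrometres.
#' @param freq_hz Echo-evoking frequency of each neuron (Hz).
#' @param r_um Neighbourhood radius in micrometres.
#' @param n_perm Number of label permutations (>= 999).
#' @param seed Optional integer seed.
#' @return A `spatial_heterogeneity` list with `statistic`, `null_mean`,
#'   `null_sd`, `p_perm`, `n_pairs`, `n_neurons`, `available`.
#' @export
spatial_heterogeneity <- function(x_um, y_um, freq_hz, r_um = 50,
                                  n_perm = 9999, seed = NULL) {
  if (n_perm < 999) stop("`n_perm` must be >= 999", call. = FALSE)
  n <- length(freq_hz)
  unavailable <- list(statistic = NA_real_, null_mean = NA_real_,
                      null_sd = NA_real_, p_perm = NA_real_, n_pairs = 0L,
                      n_neurons = n, available = FALSE)
  if (n < 5) return(structure(unavailable, class = "spatial_heterogeneity"))
  if (!is.null(seed)) set.seed(seed)
  dmat <- as.matrix(stats::dist(cbind(x_um, y_um)))
  pair <- which(upper.tri(dmat) & dmat <= r_um, arr.ind = TRUE)
  if (nrow(pair) < 1)
    return(structure(unavailable, class = "spatial_heterogeneity"))
  lf <- log2(freq_hz)
  stat_of <- function(l) mean(abs(l[pair[, 1]] - l[pair[, 2]]))
  obs <- stat_of(lf)
  null <- vapply(seq_len(n_perm), function(i) stat_of(sample(lf)), 1)
  structure(list(statistic = obs, null_mean = mean(null),
                 null_sd = stats::sd(null),
                 p_perm = (1 + sum(null <= obs)) / (n_perm + 1),
                 n_pairs = nrow(pair), n_neurons = n, available = TRUE),
            class = "spatial_heterogeneity")
}
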