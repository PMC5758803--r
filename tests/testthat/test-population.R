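test_that("signed-rank p-values match brute-force enumeration", {
  # all-positive differences, n = 6: p = 2 / 2^6
  x <- c(2, 4, 6, 8, 10, 12); y <- c(1, 2, 3, 4, 5, 6)
  expect_equal(wilcoxon_signed_rank(x, y), 2 / 64)
  expect_equal(exact_signed_rank_p(x, y), 2 / 64)
  set.seed(21)
  for (i in 1:15) {
    n <- sample(6:10, 1)
    a <- stats::rnorm(n)
    b <- a + stats::rnorm(n, mean = 0.3)
    expect_equal(wilcoxon_signed_rank(a, b), exact_signed_rank_p(a, b),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "zero")
  expect_error(wilcoxon_signed_rank(1:3, 3:1 + 0.5), ">= 5")
})

test_that("rank-sum p-values match brute-force enumeration", {
  expect_equal(wilcoxon_rank_sum(1:4, 5:8), 2 / 70)
  expect_equal(exact_rank_sum_p(1:4, 5:8), 2 / 70)
  set.seed(22)
  for (i in 1:15) {
    a <- stats::rnorm(sample(4:7, 1))
    b <- stats::rnorm(sample(4:7, 1), mean = 0.5)
    expect_equal(wilcoxon_rank_sum(a, b), exact_rank_sum_p(a, b),
                 tolerance = 1e-12)
  }
  # identical distributions: no evidence of separation
  expect_gt(wilcoxon_rank_sum(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 3.9)), 0.5)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:5), "empty")
  expect_error(wilcoxon_rank_sum(1:3, 1:5 + 0.5), ">= 4")
})

make_summary_row <- function(id, is_echo = FALSE, echo_amp = NA,
                             base = 0.014, sound = 0.08, lat_s = 0.08,
                             lat_e = NA) {
  data.frame(neuron_id = id, is_echo = is_echo, p_spont = 1,
             n_echo_events = 0, n_echo_events_max = 0, echo_freq_hz = NA,
             sound_amp = sound, sound_win_amp = 0.014, n_sound_resp = 10,
             sound_latency_s = lat_s, echo_amp = echo_amp,
             echo_win_amp = 0.013, echo_latency_s = lat_e,
             baseline_amp = base, stringsAsFactors = FALSE)
}

test_that("population pooling handles sessions without echo neurons", {
  s <- make_summary_row("a")
  pop <- summarize_population(list(s))
  expect_equal(pop$echo_fraction_mean, 0)
  expect_true(is.na(pop$lat_echo_mean))
  expect_equal(pop$n_neurons, 1)
})

test_that("duplicating sessions preserves means and shrinks the fraction SEM", {
  set.seed(23)
  sessions <- lapply(1:4, function(s) {
    rows <- do.call(rbind, lapply(1:20, function(i) {
      ech <- i <= s  # different echo fraction per session
      make_summary_row(sprintf("s%dn%d", s, i), is_echo = ech,
                       echo_amp = if (ech) stats::runif(1, 0.2, 0.4) else NA,
                       base = stats::runif(1, 0.010, 0.018),
                       sound = stats::runif(1, 0.06, 0.1),
                       lat_s = stats::runif(1, 0.06, 0.1),
                       lat_e = if (ech) stats::runif(1, 0.1, 0.4) else NA)
    }))
    rows
  })
  p1 <- summarize_population(sessions)
  p2 <- summarize_population(c(sessions, sessions))
  expect_equal(p2$echo_fraction_mean, p1$echo_fraction_mean)
  expect_equal(p2$amp_sound_mean, p1$amp_sound_mean)
  expect_equal(p2$lat_echo_mean, p1$lat_echo_mean)
  frac <- vapply(sessions, function(s) 100 * mean(s$is_echo), 1)
  expected_sem <- stats::sd(rep(frac, 2)) / sqrt(8)
  expect_equal(p2$echo_fraction_sem, expected_sem)
  expect_lt(p2$echo_fraction_sem, p1$echo_fraction_sem)
})

test_that("population pooling is invariant to neuron and session order", {
  set.seed(24)
  sessions <- lapply(1:3, function(s) {
    do.call(rbind, lapply(1:15, function(i) {
      ech <- stats::runif(1) < 0.3
      make_summary_row(sprintf("s%dn%d", s, i), is_echo = ech,
                       echo_amp = if (ech) stats::runif(1, 0.2, 0.4) else NA,
                       lat_e = if (ech) stats::runif(1, 0.1, 0.4) else NA)
    }))
  })
  p1 <- summarize_population(sessions)
  shuffled <- lapply(rev(sessions), function(s) s[sample(nrow(s)), ])
  p2 <- summarize_population(shuffled)
  for (f in c("amp_echo_mean", "amp_sound_mean", "lat_echo_mean",
              "echo_fraction_mean", "p_amp_echo_vs_baseline"))
    expect_equal(p2[[f]], p1[[f]])
})

test_that("identical echo frequencies give zero spatial statistic", {
  set.seed(25)
  r <- spatial_heterogeneity(stats::runif(10, 0, 100),
                             stats::runif(10, 0, 100),
                             rep(8000, 10), r_um = 200, n_perm = 999)
  expect_true(r$available)
  expect_equal(r$statistic, 0)
})

test_that("spatial permutation p-values are valid under the null", {
  freqs <- make_protocol()$frequencies_hz
  set.seed(26)
  pvals <- vapply(1:60, function(i) {
    n <- 30
    spatial_heterogeneity(stats::runif(n, 0, 200), stats::runif(n, 0, 200),
                          sample(freqs, n, replace = TRUE), r_um = 50,
                          n_perm = 999)$p_perm
  }, 1)
  # uniform on (0, 1]: Kolmogorov-Smirnov should not reject
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pvals), 0.35)  # no wholesale anti-conservatism
})

test_that("a smooth tonotopic gradient is detected as clustered", {
  freqs <- make_protocol()$frequencies_hz
  set.seed(27)
  hits <- vapply(1:10, function(i) {
    n <- 40
    x <- stats::runif(n, 0, 200); y <- stats::runif(n, 0, 200)
    f <- freqs[pmin(11, pmax(1, round(x / 200 * 10) + 1))]  # gradient in x
    spatial_heterogeneity(x, y, f, r_um = 50, n_perm = 999)$p_perm < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate spatial inputs are flagged unavailable", {
  r <- spatial_heterogeneity(1:3, 1:3, c(2, 4, 8) * 1000, n_perm = 999)
  expect_false(r$available)
  far <- spatial_heterogeneity(c(0, 100, 200, 300, 400),
                               rep(0, 5), rep(8000, 5), r_um = 10,
                               n_perm = 999)
  expect_false(far$available)
  expect_error(spatial_heterogeneity(1:9, 1:9, rep(1, 9), n_perm = 10),
               "n_perm")
})
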