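# hand-built cycle sets for direct feature arithmetic
fake_cycles <- function(amplitudes = numeric(0), peak_times = numeric(0),
                        cas = NULL, cms = NULL) {
  m <- length(peak_times)
  if (is.null(cas)) cas <- rep(1, max(m - 1L, 0L))
  if (is.null(cms)) cms <- rep(1, max(m - 1L, 0L))
  peaks <- seq_len(max(m, length(amplitudes)))
  structure(list(peak_indices = peaks,
                 trough_indices = peaks - 0.5,
                 peak_times = peak_times,
                 amplitudes = amplitudes,
                 amplitude_peaks = seq_along(amplitudes),
                 durations = diff(peak_times),
                 cas = cas, cms = cms, fps = 50),
            class = "cycle_set")
}

test_that("average amplitude is the mean over computed amplitudes", {
  expect_equal(hypokinesia_features(fake_cycles(c(1, 1, 1)))[["amp_avg"]], 1)
  expect_equal(hypokinesia_features(fake_cycles(c(0.8, 1.0, 1.2)))[["amp_avg"]],
               1)
})

test_that("average cycle duration is the mean peak-to-peak time", {
  expect_equal(bradykinesia_features(fake_cycles(peak_times = c(0, 0.5, 1)))[["cd_avg"]],
               0.5)
  expect_equal(bradykinesia_features(fake_cycles(peak_times = c(0, 0.3, 0.9)))[["cd_avg"]],
               0.45)
})

test_that("combined speed features average CAS and CMS across cycles", {
  cyc <- fake_cycles(peak_times = c(0, 1, 2), cas = c(4, 4), cms = c(5, 7))
  v <- combined_speed_features(cyc)
  expect_equal(v[["cas_avg"]], 4)
  expect_equal(v[["cms_avg"]], 6)
})

test_that("sequence-effect slopes are exact OLS on collinear points", {
  cyc <- fake_cycles(amplitudes = c(1.0, 0.9, 0.8, 0.7),
                     peak_times = c(0, 0.4, 0.8, 1.2))
  v <- sequence_effect_features(cyc)
  expect_equal(v[["amp_slope"]], -0.1)
  expect_equal(v[["cd_slope"]], 0)
  cyc2 <- fake_cycles(amplitudes = rep(1, 5), peak_times = cumsum(c(0, 1:4)) / 5)
  expect_equal(sequence_effect_features(cyc2)[["amp_slope"]], 0)
  # durations 0.2, 0.4, 0.6, 0.8 against index 0:3
  expect_equal(sequence_effect_features(cyc2)[["cd_slope"]], 0.2)
})

test_that("slopes need at least three values", {
  cyc <- fake_cycles(amplitudes = c(1, 0.5), peak_times = c(0, 0.5))
  expect_true(is.na(sequence_effect_features(cyc)[["amp_slope"]]))
})

test_that("coefficients of variation follow the population convention", {
  cyc <- fake_cycles(amplitudes = rep(1, 4), peak_times = c(0, 0.4, 0.8, 1.2))
  v <- hesitation_halt_features(cyc)
  expect_equal(unname(v[c("amp_cv", "cd_cv")]), c(0, 0))
  expect_equal(v[["n_interruptions"]], 0)
  # durations 0.4, 0.6: mean 0.5, population sd sqrt(0.02/2) = 0.1
  cyc2 <- fake_cycles(peak_times = c(0, 0.4, 1.0))
  expect_equal(hesitation_halt_features(cyc2)[["cd_cv"]], 0.2)
  # the sample convention divides by one fewer
  expect_equal(hesitation_halt_features(cyc2, cv_method = "sample")[["cd_cv"]],
               sqrt(0.02 / 1) / 0.5)
})

test_that("interruptions are durations beyond twice the median", {
  pt <- cumsum(c(0, rep(0.3, 9), 0.7))
  cyc <- fake_cycles(peak_times = pt)
  expect_equal(hesitation_halt_features(cyc)[["n_interruptions"]], 1)
  expect_equal(count_interruptions(cyc), 1L)
  # invariant under uniform time scaling
  expect_equal(count_interruptions(fake_cycles(peak_times = 3 * pt)), 1L)
})

test_that("full extraction on a sinusoid recovers the analytic features", {
  fv <- tap_features(make_sine_signal(freq = 2, amp = 0.5, offset = 1))
  expect_true(fv$valid)
  f <- fv$features
  expect_equal(f[["amp_avg"]], 1.0, tolerance = 0.02)
  expect_equal(f[["cd_avg"]], 0.5, tolerance = 0.01)
  expect_equal(unname(f[c("amp_slope", "cd_slope", "speed_slope")]),
               c(0, 0, 0), tolerance = 1e-6)
  expect_true(all(f[c("amp_cv", "cd_cv", "cms_cv", "cas_cv")] < 1e-6))
  expect_equal(f[["n_interruptions"]], 0)
  expect_equal(f[["n_cycles"]], 20)
})

test_that("extraction failures yield an invalid vector, not an error", {
  fv <- tap_features(make_signal(seq(0, 1, length.out = 50)))
  expect_false(fv$valid)
  expect_match(fv$reason, "insufficient cycles")
  expect_true(all(is.na(fv$features)))
  df <- as.data.frame(fv)
  expect_true(is.na(df$amp_avg))
  expect_false(df$valid)
})

test_that("CVs and slopes are invariant to a constant signal offset", {
  base <- make_sine_signal(freq = 2, amp = 0.4, offset = 1)
  set.seed(9)
  noise <- rnorm(length(base$values), 0, 0.01)
  a <- tap_features(make_signal(base$values + noise))
  b <- tap_features(make_signal(base$values + noise + 5))
  keys <- c("amp_avg", "amp_slope", "cd_slope", "speed_slope",
            "amp_cv", "cd_cv", "cms_cv", "cas_cv", "n_interruptions")
  expect_equal(a$features[keys], b$features[keys], tolerance = 1e-10)
})

test_that("features cohere across frame rates", {
  t50 <- seq(0, 10 - 1 / 50, by = 1 / 50)
  t25 <- seq(0, 10 - 1 / 25, by = 1 / 25)
  wave <- function(t) 1 + 0.5 * sin(2 * pi * 2 * t)
  f50 <- tap_features(make_signal(wave(t50), fps = 50))$features
  f25 <- tap_features(make_signal(wave(t25), fps = 25))$features
  for (k in c("amp_avg", "cd_avg", "cas_avg")) {
    expect_lt(abs(f25[[k]] - f50[[k]]) / f50[[k]], 0.03)
  }
})

test_that("simulated deficits are recovered across the parameter grid", {
  set.seed(101)
  for (case in list(list(amp = 1.4, cd = 0.35), list(amp = 0.6, cd = 0.6))) {
    sim <- simulate_tapping(tap_sim_params(
      base_amplitude = case$amp, base_cycle_s = case$cd,
      amp_cv = 0.05, cd_cv = 0.05, noise_sd = 0.01))
    f <- tap_features(sim$signal)$features
    expect_equal(f[["amp_avg"]], mean(sim$truth$amplitudes), tolerance = 0.08)
    expect_equal(f[["cd_avg"]], mean(sim$truth$durations), tolerance = 0.05)
  }
})

test_that("programmed-vs-recovered rank correlation is high over a grid", {
  set.seed(77)
  amps <- runif(30, 0.4, 1.6)
  cds <- runif(30, 0.3, 0.7)
  rec <- t(vapply(seq_along(amps), function(i) {
    sim <- simulate_tapping(tap_sim_params(
      base_amplitude = amps[i], base_cycle_s = cds[i],
      amp_cv = 0.05, cd_cv = 0.05, noise_sd = 0.01))
    f <- tap_features(sim$signal)$features
    c(f[["amp_avg"]], f[["cd_avg"]])
  }, numeric(2)))
  expect_gt(cor(amps, rec[, 1], method = "spearman"), 0.95)
  expect_gt(cor(cds, rec[, 2], method = "spearman"), 0.95)
})
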