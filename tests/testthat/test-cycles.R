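test_that("a 2 Hz sinusoid yields alternating peaks and troughs", {
  sig <- make_sine_signal(freq = 2, duration = 10, fps = 50)
  ext <- detect_extrema(sig)
  expect_length(ext$peaks, 20)
  expect_length(ext$troughs, 20)
  merged <- sort(c(ext$peaks, ext$troughs))
  is_peak <- merged %in% ext$peaks
  expect_true(all(diff(is_peak) != 0))  # strictly alternating
})

test_that("a monotone ramp has no cycles", {
  sig <- make_signal(seq(0, 1, length.out = 100))
  err <- tryCatch(detect_extrema(sig), condition = function(c) c)
  expect_s3_class(err, "fingertap_insufficient_cycles")
  expect_equal(err$count, 0L)
})

test_that("mild noise does not change the detected peak count", {
  clean <- make_sine_signal(freq = 2, amp = 0.5, duration = 10, fps = 50)
  set.seed(11)
  noisy <- make_signal(clean$values + rnorm(length(clean$values),
                                            0, 0.02 * 0.5))
  expect_length(detect_extrema(noisy)$peaks,
                length(detect_extrema(clean)$peaks))
})

test_that("sinusoid cycles recover amplitude and period", {
  sig <- make_sine_signal(freq = 2, amp = 0.5, offset = 1)
  ext <- detect_extrema(sig)
  cyc <- segment_cycles(sig, peaks = ext$peaks, troughs = ext$troughs)
  expect_equal(mean(cyc$amplitudes), 1.0, tolerance = 0.02)
  expect_equal(mean(cyc$durations), 0.5, tolerance = 0.01)
  expect_length(cyc$durations, length(ext$peaks) - 1L)
})

test_that("triangle-wave speeds match the closed form 2A/D", {
  sig <- make_triangle_signal(lo = 0.2, hi = 1.2, period = 0.4)
  ext <- detect_extrema(sig)
  cyc <- segment_cycles(sig, peaks = ext$peaks, troughs = ext$troughs)
  # constant slope: speed = 2 * amplitude / period = 5 everywhere
  expect_equal(mean(cyc$cas), 5, tolerance = 0.02)
  expect_equal(mean(cyc$cms), 5, tolerance = 0.02)
})

test_that("cycle speed summaries match brute-force re-summation", {
  set.seed(21)
  t <- seq(0, 10 - 1 / 50, by = 1 / 50)
  vals <- 1 + 0.5 * sin(2 * pi * 2 * t) + 0.05 * rnorm(length(t)) +
    0.2 * sin(2 * pi * 0.3 * t)
  sig <- make_signal(vals)
  sp <- speed_signal(sig)
  ext <- detect_extrema(sig)
  cyc <- segment_cycles(sig, sp, ext$peaks, ext$troughs)
  pt <- sig$times[ext$peaks]
  for (j in seq_along(cyc$durations)) {
    in_open <- sp$times > pt[j] & sp$times <= pt[j + 1]
    in_closed <- sp$times >= pt[j] & sp$times <= pt[j + 1]
    expect_equal(cyc$cas[j], mean(sp$values[in_open]))
    expect_equal(cyc$cms[j],
                 as.numeric(quantile(sp$values[in_closed], 0.95)))
  }
})

test_that("the 95th percentile uses linear interpolation between order statistics", {
  set.seed(5)
  for (n in c(5, 20, 101)) {
    v <- rnorm(n)
    s <- sort(v)
    h <- (n - 1) * 0.95 + 1
    oracle <- s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
    expect_equal(as.numeric(quantile(v, 0.95, type = 7)), oracle)
  }
})

test_that("peak separation exceeds the configured minimum", {
  set.seed(33)
  sim <- simulate_tapping(tap_sim_params(cd_cv = 0.15, amp_cv = 0.1,
                                         noise_sd = 0.02, seed = 33))
  ext <- detect_extrema(sim$signal, peak_params(min_separation_s = 0.1))
  cyc <- segment_cycles(sim$signal, peaks = ext$peaks,
                        troughs = ext$troughs)
  expect_true(all(cyc$durations > 0.1))
  expect_length(cyc$durations, length(ext$peaks) - 1L)
})

test_that("amplitudes pair each peak with its nearest preceding trough", {
  # signal starting at a maximum: first peak has no preceding trough
  t <- seq(0, 3 - 1 / 50, by = 1 / 50)
  sig <- make_signal(1 + 0.5 * cos(2 * pi * t))
  ext <- detect_extrema(sig)
  cyc <- segment_cycles(sig, peaks = ext$peaks, troughs = ext$troughs)
  first_peak_has_trough <- any(ext$troughs < ext$peaks[1])
  expect_equal(length(cyc$amplitudes),
               length(ext$peaks) - !first_peak_has_trough)
  expect_true(all(cyc$amplitudes >= 0))
})

test_that("units behave under uniform time scaling", {
  sig50 <- make_sine_signal(freq = 2, duration = 10, fps = 50)
  # same samples declared at half the frame rate: durations double,
  # speeds halve, amplitudes unchanged
  sig25 <- fingertap:::new_distance_signal(sig50$values, fps = 25,
                                           source_id = "slow")
  c50 <- segment_cycles(sig50, peaks = detect_extrema(sig50)$peaks,
                        troughs = detect_extrema(sig50)$troughs)
  c25 <- segment_cycles(sig25, peaks = detect_extrema(sig25)$peaks,
                        troughs = detect_extrema(sig25)$troughs)
  expect_equal(c25$amplitudes, c50$amplitudes)
  expect_equal(c25$durations, 2 * c50$durations)
  expect_equal(c25$cas, c50$cas / 2)
  expect_equal(c25$cms, c50$cms / 2)
})
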