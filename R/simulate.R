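# Synthetic finger-tapping signals with known ground-truth deficit
# parameters, for validation and parameter-recovery testing.

#' Simulation parameters for a synthetic tapping recording
#'
#' Defines the statistical structure the feature set measures: per-cycle
#' amplitudes and durations with linear trends, multiplicative log-normal
#' cycle-to-cycle variability (which keeps both positive), inserted
#' interruptions, and additive observation noise.
#'
#' @param fps sampling rate, frames per second.
#' @param duration_s nominal tapping time, seconds (the task is 10 s).
#' @param base_amplitude amplitude of the first cycle, scaled-distance
#'   units.
#' @param base_cycle_s duration of the first cycle, seconds.
#' @param amp_slope_per_cycle,cd_slope_per_cycle fractional linear trends:
#'   cycle j (0-based) has amplitude `base * (1 + amp_slope * j)` and
#'   duration `base_cycle * (1 + cd_slope * j)` before noise.
#' @param amp_cv,cd_cv cycle-to-cycle log-normal variability (sd of the
#'   log-multiplier).
#' @param n_interruptions number of flat pauses to insert at cycle
#'   boundaries.
#' @param interruption_factor pause length as a multiple of the median
#'   cycle duration; must exceed 2 so pauses are detectable by the
#'   2 x median rule.
#' @param waveform cycle shape: `"sinusoid"` (half-sine), `"raised_cosine"`
#'   or `"triangle"`; all start and end at the trough baseline.
#' @param noise_sd additive Gaussian observation noise.
#' @param baseline trough level of the signal (fingers closed).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return An object of class `tap_sim_params`.
#' @export
tap_sim_params <- function(fps = 50, duration_s = 10, base_amplitude = 1,
                           base_cycle_s = 0.4, amp_slope_per_cycle = 0,
                           cd_slope_per_cycle = 0, amp_cv = 0, cd_cv = 0,
                           n_interruptions = 0L, interruption_factor = 3,
                           waveform = c("sinusoid", "raised_cosine",
                                        "triangle"),
                           noise_sd = 0, baseline = 0.2, seed = NULL) {
  waveform <- match.arg(waveform)
  stopifnot(fps > 0, duration_s > 0, base_amplitude > 0, base_cycle_s > 0,
            amp_cv >= 0, cd_cv >= 0, n_interruptions >= 0, noise_sd >= 0)
  if (interruption_factor <= 2)
    stop("interruption_factor must exceed 2 (the detection threshold)")
  if (duration_s / base_cycle_s < 3)
    stop("parameters allow fewer than 3 cycles")
  structure(list(fps = fps, duration_s = duration_s,
                 base_amplitude = base_amplitude,
                 base_cycle_s = base_cycle_s,
                 amp_slope_per_cycle = amp_slope_per_cycle,
                 cd_slope_per_cycle = cd_slope_per_cycle,
                 amp_cv = amp_cv, cd_cv = cd_cv,
                 n_interruptions = as.integer(n_interruptions),
                 interruption_factor = interruption_factor,
                 waveform = waveform, noise_sd = noise_sd,
                 baseline = baseline, seed = seed),
            class = "tap_sim_params")
}

.cycle_shape <- function(waveform, u) {
  # u in [0, 1); 0 at trough, maximum 1 at mid-cycle, back to trough
  switch(waveform,
         sinusoid = sin(pi * u),
         raised_cosine = (1 - cos(2 * pi * u)) / 2,
         triangle = 1 - abs(2 * u - 1))
}

#' Simulate a tapping distance signal
#'
#' Draws per-cycle amplitudes and durations according to the programmed
#' trends and variability, concatenates the chosen waveform cycle by cycle
#' from the trough baseline, inserts flat interruptions at uniformly chosen
#' interior cycle boundaries (pause length = `interruption_factor` x median
#' cycle duration), samples the result at `fps`, and adds Gaussian noise.
#' Deterministic for a fixed seed.
#'
#' @param params a [tap_sim_params()].
#' @return An object of class `tap_sim`: `signal` (a [distance_signal()])
#'   and `truth`, a list carrying every programmed quantity plus the
#'   realized per-cycle amplitudes/durations and their means.
#' @export
simulate_tapping <- function(params = tap_sim_params()) {
  stopifnot(inherits(params, "tap_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  p <- params
  amps <- numeric(0)
  durs <- numeric(0)
  total <- 0
  j <- 0L
  while (total < p$duration_s) {
    fa <- 1 + p$amp_slope_per_cycle * j
    fd <- 1 + p$cd_slope_per_cycle * j
    if (fa <= 0.05 || fd <= 0.05) break
    a <- p$base_amplitude * fa * exp(rnorm(1L, 0, p$amp_cv))
    d <- p$base_cycle_s * fd * exp(rnorm(1L, 0, p$cd_cv))
    d <- max(d, 3 / p$fps)  # a cycle must span a few samples
    amps <- c(amps, a)
    durs <- c(durs, d)
    total <- total + d
    j <- j + 1L
  }
  n_cyc <- length(durs)
  if (n_cyc < 3L) stop("parameters produced fewer than 3 cycles")
  n_int <- min(p$n_interruptions, n_cyc - 2L)
  pause_len <- p$interruption_factor * median(durs)
  pause_after <- if (n_int > 0L)
    sort(sample(seq_len(n_cyc - 2L), n_int)) else integer(0)

  # piecewise segments in continuous time
  seg_dur <- numeric(0)
  seg_amp <- numeric(0)   # 0 encodes a flat pause
  for (i in seq_len(n_cyc)) {
    seg_dur <- c(seg_dur, durs[i])
    seg_amp <- c(seg_amp, amps[i])
    if (i %in% pause_after) {
      seg_dur <- c(seg_dur, pause_len)
      seg_amp <- c(seg_amp, 0)
    }
  }
  ends <- cumsum(seg_dur)
  starts <- c(0, ends[-length(ends)])
  t <- seq(0, ends[length(ends)] - 1e-9, by = 1 / p$fps)
  seg_of <- findInterval(t, starts)
  u <- (t - starts[seg_of]) / seg_dur[seg_of]
  values <- p$baseline + seg_amp[seg_of] * .cycle_shape(p$waveform, u)
  if (p$noise_sd > 0)
    values <- values + rnorm(length(values), 0, p$noise_sd)
  values <- pmax(values, 0)
  signal <- new_distance_signal(values, fps = p$fps,
                                source_id = "simulated")
  truth <- list(amplitudes = amps, durations = durs,
                amp_avg = mean(amps), cd_avg = mean(durs),
                amp_slope = p$base_amplitude * p$amp_slope_per_cycle,
                cd_slope = p$base_cycle_s * p$cd_slope_per_cycle,
                n_interruptions = n_int, n_cycles = n_cyc,
                pause_after = pause_after, pause_len = pause_len,
                params = p)
  structure(list(signal = signal, truth = truth), class = "tap_sim")
}

#' @export
print.tap_sim <- function(x, ...) {
  cat("<tap_sim>", x$truth$n_cycles, "cycles,",
      x$truth$n_interruptions, "interruption(s)\n")
  print(x$signal)
  invisible(x)
}

#' Per-class simulation profiles
#'
#' Parameter ranges per severity class from which subject-level values are
#' drawn. The `"overlapping"` default mimics the graded, overlapping
#' distributions of real severity groups (reduced amplitude, longer
#' cycles, higher variability and more interruptions with severity);
#' `"well_separated"` uses disjoint ranges so classes are separable by
#' construction.
#'
#' @param separation `"overlapping"` or `"well_separated"`.
#' @return Named list (`Mild`, `Moderate`, `Severe`) of range lists.
#' @export
class_profiles <- function(separation = c("overlapping", "well_separated")) {
  separation <- match.arg(separation)
  rng <- function(lo, hi) c(lo, hi)
  if (separation == "overlapping") {
    list(
      Mild = list(base_amplitude = rng(1.0, 1.5),
                  base_cycle_s = rng(0.28, 0.40),
                  amp_cv = rng(0.02, 0.08), cd_cv = rng(0.02, 0.08),
                  amp_slope_per_cycle = rng(-0.004, 0),
                  cd_slope_per_cycle = rng(0, 0.003),
                  n_interruptions = c(0L, 0L)),
      Moderate = list(base_amplitude = rng(0.7, 1.1),
                      base_cycle_s = rng(0.36, 0.52),
                      amp_cv = rng(0.06, 0.14), cd_cv = rng(0.05, 0.12),
                      amp_slope_per_cycle = rng(-0.010, -0.002),
                      cd_slope_per_cycle = rng(0, 0.006),
                      n_interruptions = c(0L, 2L)),
      Severe = list(base_amplitude = rng(0.35, 0.8),
                    base_cycle_s = rng(0.48, 0.72),
                    amp_cv = rng(0.12, 0.26), cd_cv = rng(0.10, 0.22),
                    amp_slope_per_cycle = rng(-0.020, -0.005),
                    cd_slope_per_cycle = rng(0.002, 0.010),
                    n_interruptions = c(1L, 5L)))
  } else {
    list(
      Mild = list(base_amplitude = rng(1.4, 1.6),
                  base_cycle_s = rng(0.28, 0.32),
                  amp_cv = rng(0.02, 0.04), cd_cv = rng(0.02, 0.04),
                  amp_slope_per_cycle = rng(-0.001, 0),
                  cd_slope_per_cycle = rng(0, 0.001),
                  n_interruptions = c(0L, 0L)),
      Moderate = list(base_amplitude = rng(0.9, 1.0),
                      base_cycle_s = rng(0.42, 0.48),
                      amp_cv = rng(0.08, 0.10), cd_cv = rng(0.06, 0.08),
                      amp_slope_per_cycle = rng(-0.008, -0.006),
                      cd_slope_per_cycle = rng(0.002, 0.003),
                      n_interruptions = c(0L, 0L)),
      Severe = list(base_amplitude = rng(0.40, 0.50),
                    base_cycle_s = rng(0.60, 0.70),
                    amp_cv = rng(0.15, 0.20), cd_cv = rng(0.12, 0.16),
                    amp_slope_per_cycle = rng(-0.018, -0.012),
                    cd_slope_per_cycle = rng(0.004, 0.006),
                    n_interruptions = c(2L, 4L)))
  }
}

#' Simulate a cohort of subjects with severity labels
#'
#' Subjects are assigned classes round-robin (so every class is populated).
#' Per subject, one value of each profile parameter is drawn uniformly
#' within its class range (the subject-level random effect); per recording
#' the amplitude and cycle duration are additionally jittered by a small
#' log-normal factor. Features are extracted from each simulated signal
#' with [tap_features()].
#'
#' @param n_subjects number of subjects.
#' @param recordings_per_subject recordings per subject.
#' @param profiles class profiles as from [class_profiles()].
#' @param fps,duration_s recording parameters.
#' @param recording_jitter sd of the per-recording log-normal jitter on
#'   amplitude and cycle duration.
#' @param seed integer seed.
#' @return A [severity_dataset()] whose `truth` attribute is a data.frame
#'   of the programmed per-recording parameters.
#' @export
simulate_cohort <- function(n_subjects = 60L, recordings_per_subject = 2L,
                            profiles = class_profiles(), fps = 50,
                            duration_s = 10, recording_jitter = 0.03,
                            seed = 1L) {
  stopifnot(n_subjects >= length(profiles), recordings_per_subject >= 1L)
  if (length(profiles) < 2L) stop("need at least 2 class profiles")
  if (any(!vapply(profiles, length, 1L) > 0)) stop("empty class profile")
  set.seed(seed)
  classes <- names(profiles)
  rows <- list()
  truth <- list()
  for (s in seq_len(n_subjects)) {
    cl <- classes[((s - 1L) %% length(classes)) + 1L]
    prof <- profiles[[cl]]
    draw <- function(nm) runif(1L, prof[[nm]][1L], prof[[nm]][2L])
    subj <- list(base_amplitude = draw("base_amplitude"),
                 base_cycle_s = draw("base_cycle_s"),
                 amp_cv = draw("amp_cv"), cd_cv = draw("cd_cv"),
                 amp_slope = draw("amp_slope_per_cycle"),
                 cd_slope = draw("cd_slope_per_cycle"),
                 n_int = sample(seq(prof$n_interruptions[1L],
                                    prof$n_interruptions[2L]), 1L))
    for (r in seq_len(recordings_per_subject)) {
      pars <- tap_sim_params(
        fps = fps, duration_s = duration_s,
        base_amplitude = subj$base_amplitude * exp(rnorm(1, 0, recording_jitter)),
        base_cycle_s = subj$base_cycle_s * exp(rnorm(1, 0, recording_jitter)),
        amp_slope_per_cycle = subj$amp_slope,
        cd_slope_per_cycle = subj$cd_slope,
        amp_cv = subj$amp_cv, cd_cv = subj$cd_cv,
        n_interruptions = subj$n_int, interruption_factor = 3,
        noise_sd = 0.01)
      sim <- simulate_tapping(pars)
      fv <- tap_features(sim$signal)
      rows[[length(rows) + 1L]] <- list(
        subject = sprintf("S%03d", s), class = cl, features = fv)
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = sprintf("S%03d", s), recording = r, class = cl,
        base_amplitude = pars$base_amplitude,
        base_cycle_s = pars$base_cycle_s,
        amp_cv = pars$amp_cv, cd_cv = pars$cd_cv,
        n_interruptions = sim$truth$n_interruptions)
    }
  }
  valid <- vapply(rows, function(r) r$features$valid, logical(1))
  rows <- rows[valid]
  truth <- truth[valid]
  X <- do.call(rbind, lapply(rows, function(r) r$features$features))
  colnames(X) <- FEATURE_NAMES
  ds <- severity_dataset(
    X, vapply(rows, function(r) r$class, character(1)),
    vapply(rows, function(r) r$subject, character(1)))
  attr(ds, "truth") <- do.call(rbind, truth)
  ds
}
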