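# Feature extraction against closed-form constructions and the simulator's
# ground truth.

test_that("spikes are interpolated upward 0 mV crossings", {
  v <- rep(-67, 400)
  v[102:103] <- 5   # crossing between samples 101 and 102 (1-based)
  v[302:303] <- 5   # and between 301 and 302
  tr <- detect_spikes(sweep_trace(v, dt = 0.05, mode = "current_clamp"))
  expect_length(tr$times, 2L)
  expect_equal(tr$times, c(5.0, 15.0), tolerance = 0.01)
  expect_length(tr$inst_freq, 1L)

  expect_length(detect_spikes(sweep_trace(rep(-67, 100), dt = 0.05,
                                          mode = "current_clamp"))$times, 0L)
  expect_error(detect_spikes(sweep_trace(rep(0.1, 100), dt = 0.05,
                                         mode = "voltage_clamp")),
               "current-clamp")
  # crossings within 1 ms are merged by the refractory guard
  v2 <- rep(-67, 200)
  v2[50:51] <- 5; v2[53] <- -1; v2[55:56] <- 5
  tr2 <- detect_spikes(sweep_trace(v2, dt = 0.05, mode = "current_clamp"))
  expect_length(tr2$times, 1L)
})

test_that("detected spikes match the simulator log to 0.1 ms", {
  sim <- simulate_current_clamp(neuron_presets("young"), seed = 5)
  trains <- lapply(sim$recording$sweeps, detect_spikes)
  for (i in seq_along(trains)) {
    truth <- sim$ground_truth$spike_times[[i]]
    expect_length(trains[[i]]$times, length(truth))
    if (length(truth))
      expect_lt(max(abs(trains[[i]]$times - truth)), 0.1)
  }
})

test_that("resting potential is the mean of a stimulus-free segment", {
  sw <- sweep_trace(rep(-67, 3000), dt = 0.1, mode = "current_clamp")
  expect_equal(resting_potential(sw), -67)
  set.seed(1)
  swn <- sweep_trace(-67 + rnorm(2000, sd = 0.5), dt = 0.1,
                     mode = "current_clamp")
  expect_lt(abs(resting_potential(swn) + 67), 0.05)
  expect_error(resting_potential(sweep_trace(rep(-67, 50), dt = 1,
                                             mode = "current_clamp"),
                                 from_ms = 0, to_ms = 49), "100 ms")
  swstim <- sweep_trace(rep(-67, 3000), dt = 0.1,
                        stimulus = stimulus_step(100, onset = 50),
                        mode = "current_clamp")
  expect_error(resting_potential(swstim, 0, 200), "stimulus")
})

step_sweep <- function(v_base, v_step, dt = 0.05, onset = 100, dur = 250,
                       post = 300, amp = -50, shape = NULL) {
  n <- round((onset + dur + post) / dt) + 1L
  tt <- (seq_len(n) - 1L) * dt
  v <- rep(v_base, n)
  during <- tt >= onset & tt <= onset + dur
  if (is.null(shape)) v[during] <- v_step
  else v[during] <- shape(tt[during] - onset)
  sweep_trace(v, dt = dt,
              stimulus = stimulus_step(amp, onset = onset, duration = dur),
              mode = "current_clamp")
}

test_that("input resistance follows Ohm's law on the -50 pA step", {
  sw <- step_sweep(-67, -72)
  expect_equal(input_resistance(sw), 100)
  expect_warning(r0 <- input_resistance(step_sweep(-67, -67)), "zero")
  expect_equal(r0, 0)
  rec <- recording_of(step_sweep(-67, -72, amp = 100))
  expect_error(input_resistance(rec), "-50 pA")
  # simulator, noiseless: true Rin = 150 MOhm
  sim <- simulate_current_clamp(neuron_params(g_l = 6.667, noise_sigma = 0),
                                seed = 0)
  expect_equal(input_resistance(sim$recording), 150, tolerance = 0.01)
})

test_that("membrane time constant: 63% crossing of the steady-state change", {
  sw <- step_sweep(-67, NA, shape = function(t) -67 - 5 * (1 - exp(-t / 20)))
  expect_equal(membrane_time_constant(sw), -20 * log(1 - 0.63),
               tolerance = 0.01)
  # instant settle: the literal (unsmoothed) crossing is at or before one
  # sample; the default smoother exists for noisy data only
  expect_lte(membrane_time_constant(step_sweep(-67, -72), smooth_ms = 0), 0.05)
  expect_error(membrane_time_constant(step_sweep(-67, -67)), "zero")
  sim <- simulate_current_clamp(neuron_params(g_l = 6.667, c_m = 100,
                                              noise_sigma = 0), seed = 0)
  expect_equal(membrane_time_constant(sim$recording), 15, tolerance = 0.5 / 15)
})

# Piecewise waveform with a cubic onset ramp spliced to a steep linear rise:
# the third derivative of the cubic is constant, so its maximum (an impulse)
# sits at the splice, whose voltage is the expected threshold. Built on a
# fine grid so the one-sample localisation of the impulse stays well inside
# the 0.5 mV voltage tolerance.
make_splice_recording <- function(v_thr = -50, dt = 0.005) {
  onset <- 50; t0 <- 80; T_c <- 2
  n <- round(200 / dt) + 1L
  tt <- (seq_len(n) - 1L) * dt
  v <- rep(-67, n)
  cub <- tt >= t0 & tt < t0 + T_c
  v[cub] <- -67 + (v_thr + 67) * ((tt[cub] - t0) / T_c)^3
  rise <- tt >= t0 + T_c & tt < t0 + T_c + 0.6
  v[rise] <- v_thr + 140 * (tt[rise] - t0 - T_c)
  fall <- tt >= t0 + T_c + 0.6 & tt < t0 + T_c + 2.1
  v[fall] <- (v_thr + 84) - 60 * (tt[fall] - t0 - T_c - 0.6)
  after <- tt >= t0 + T_c + 2.1
  v[after] <- -67
  recording_of(sweep_trace(v, dt = dt,
                           stimulus = stimulus_step(200, onset = onset,
                                                    duration = 100),
                           mode = "current_clamp"))
}

test_that("AP threshold sits at the maximal third derivative before the peak", {
  rec <- make_splice_recording(v_thr = -50)
  thr <- ap_threshold(rec)
  expect_equal(thr$threshold, -50, tolerance = 0.5 / 50)
  expect_error(ap_threshold(recording_of(step_sweep(-67, -60))), "undefined")
})

test_that("AP threshold equals a raw finite-difference oracle on simulated spikes", {
  set.seed(7)
  for (i in 1:50) {
    p <- neuron_params(g_l = runif(1, 5, 9), c_m = runif(1, 80, 140),
                       b_ahp = runif(1, 0, 0.4), noise_sigma = 0)
    sim <- simulate_current_clamp(p, step_protocol(seq(100, 400, by = 50)),
                                  seed = i, ground_truth = FALSE)
    rec <- sim$recording
    thr <- ap_threshold(rec)
    sweep <- rec$sweeps[[thr$sweep]]
    pk <- round(thr$peak_time / sweep$dt) + 1L
    oracle_idx <- oracle_threshold_index(sweep$samples, sweep$dt, pk)
    impl_idx <- round(thr$threshold_time / sweep$dt) + 1L
    expect_lte(abs(impl_idx - oracle_idx), 1L)
  }
})

test_that("amplitude and half-width follow from the waveform geometry", {
  # triangle: rise -50 -> +30 in 1 ms, fall back in 2 ms; half level -10 mV
  dt <- 0.05
  tt <- seq(0, 200, by = dt)
  v <- rep(-67, length(tt))
  seg <- tt >= 100 & tt < 101
  v[seg] <- -50 + 80 * (tt[seg] - 100)
  seg <- tt >= 101 & tt < 103
  v[seg] <- 30 - 40 * (tt[seg] - 101)
  rec <- recording_of(sweep_trace(v, dt = dt,
                                  stimulus = stimulus_step(200, 50, 100),
                                  mode = "current_clamp"))
  thr <- list(threshold = -50, sweep = 1L,
              peak_time = 101, peak_v = 30, threshold_time = 100)
  expect_equal(ap_amplitude(rec, thr = thr), 80)
  expect_equal(ap_half_width(rec, thr = thr), 1.5, tolerance = 0.01)
  # degenerate: threshold equal to peak
  thr0 <- list(threshold = 30, sweep = 1L, peak_time = 101, peak_v = 30)
  expect_equal(ap_amplitude(rec, thr = thr0), 0)
  # symmetric triangle: half-width equals half the base
  v2 <- rep(-67, length(tt))
  seg <- tt >= 100 & tt < 101; v2[seg] <- -50 + 80 * (tt[seg] - 100)
  seg <- tt >= 101 & tt < 102; v2[seg] <- 30 - 80 * (tt[seg] - 101)
  rec2 <- recording_of(sweep_trace(v2, dt = dt,
                                   stimulus = stimulus_step(200, 50, 100),
                                   mode = "current_clamp"))
  thr2 <- list(threshold = -50, sweep = 1L, peak_time = 101, peak_v = 30)
  expect_equal(ap_half_width(rec2, thr = thr2), 1.0, tolerance = 0.01)
})

test_that("half-width matches a dense-resample oracle on simulated spikes", {
  set.seed(17)
  for (i in 1:20) {
    p <- neuron_params(v_reset = runif(1, -60, -50), noise_sigma = 0)
    sim <- simulate_current_clamp(p, step_protocol(seq(100, 300, by = 100)),
                                  seed = i, ground_truth = FALSE)
    thr <- ap_threshold(sim$recording)
    hw <- ap_half_width(sim$recording, thr = thr)
    sweep <- sim$recording$sweeps[[thr$sweep]]
    level <- thr$threshold + (thr$peak_v - thr$threshold) / 2
    hw_o <- oracle_half_width(sweep$samples, sweep$dt,
                              round(thr$peak_time / sweep$dt) + 1L, level)
    expect_lt(abs(hw - hw_o), 0.05)
  }
})

test_that("max firing frequency is the highest instantaneous frequency anywhere", {
  rec <- dummy_step_rec(c(200, 300, 400))
  trains <- list(make_train(c(110, 120)),       # ISI 10 ms
                 make_train(c(110, 115)),       # ISI 5 ms -> 200 Hz
                 make_train(c(110, 130)))       # ISI 20 ms
  expect_equal(firing_metrics(rec, trains)$max_freq_hz, 200)
})

test_that("firing metrics: F/I slope and adaptation index", {
  amps <- seq(150, 700, by = 50)
  rec <- dummy_step_rec(amps)
  # exact linear F/I: first frequency 0.2 * (I - 100); the 400 pA train has
  # first frequency 60 Hz and last frequency 30 Hz (adaptation index 0.5)
  trains <- lapply(amps, function(a) {
    f1 <- 0.2 * (a - 100)
    if (a == 400) make_train(c(110, 110 + 1000 / 60, 110 + 1000 / 60 + 1000 / 30))
    else make_train(c(110, 110 + 1000 / f1))
  })
  fm <- firing_metrics(rec, trains)
  expect_equal(fm$fi_slope_hz_pa, 0.2, tolerance = 1e-9)
  expect_equal(fm$max_freq_hz, 0.2 * (700 - 100), tolerance = 1e-9)
  # first spiking step is 150 pA -> adaptation sweep 400 pA
  expect_equal(fm$adaptation_index, 0.5, tolerance = 1e-9)
  expect_length(fm$undefined, 0L)

  # independent oracle for the slope on random F/I data
  set.seed(3)
  f1 <- pmax(0, 0.3 * (amps - 200) + rnorm(length(amps), 0, 5))
  trains2 <- lapply(seq_along(amps), function(i) {
    if (f1[i] > 0) make_train(c(110, 110 + 1000 / f1[i])) else make_train(numeric(0))
  })
  fm2 <- firing_metrics(rec, trains2)
  pos <- f1 > 0
  expect_equal(fm2$fi_slope_hz_pa, oracle_fi_slope(amps[pos], f1[pos]),
               tolerance = 1e-9)

  # metrics fail independently
  fm3 <- firing_metrics(rec, lapply(amps, function(a) make_train(numeric(0))))
  expect_true(is.na(fm3$max_freq_hz) && is.na(fm3$fi_slope_hz_pa) &&
                is.na(fm3$adaptation_index))
  expect_setequal(names(fm3$undefined),
                  c("max_freq_hz", "fi_slope_hz_pa", "adaptation_index"))
})

test_that("the AHP qualifying sweep is the lowest step with >= 12 spikes", {
  amps <- c(300, 350, 400, 450, 500)
  rec <- dummy_step_rec(amps)
  counts <- c(5, 9, 11, 13, 18)
  trains <- lapply(counts, function(k)
    make_train(seq(110, 340, length.out = k)))
  ahp <- measure_ahp(rec, trains)
  expect_equal(ahp$current_pa, 450)
  expect_equal(ahp$sweep, 4L)
})

test_that("AHP windows are applied literally to an imposed decay", {
  # flat post-step trace: amplitude exactly 0
  flat <- recording_of(make_decay_sweep(amp_mv = 0))
  expect_equal(measure_ahp(flat)$amplitude, 0)
  # -4 mV, tau = 150 ms: baseline integrates to -0.0534 mV, trough -4 mV
  rec <- recording_of(make_decay_sweep(amp_mv = -4, tau_ms = 150))
  ahp <- measure_ahp(rec)
  expect_equal(ahp$trough_mv, -67 - 4, tolerance = 1e-9)
  expect_equal(ahp$amplitude, 3.9466, tolerance = 0.01 / 3.9466)
  # additivity: constant offsets cancel; scaling the deflection scales it
  off <- recording_of(make_decay_sweep(amp_mv = -4, v0 = -60))
  expect_equal(measure_ahp(off)$amplitude, ahp$amplitude, tolerance = 1e-9)
  scaled <- recording_of(make_decay_sweep(amp_mv = -8))
  expect_equal(measure_ahp(scaled)$amplitude, 2 * ahp$amplitude,
               tolerance = 1e-9)
  # insufficient spiking
  few <- recording_of(make_decay_sweep(n_spikes = 11))
  expect_error(measure_ahp(few), "insufficient_spiking")
  # post-step epoch too short for the baseline window
  short <- recording_of(make_decay_sweep(post = 400))
  expect_error(measure_ahp(short), "post-step")
})

test_that("QC flags insufficient spiking and synaptic contamination, and only those", {
  few <- recording_of(make_decay_sweep(n_spikes = 11))
  qc <- qc_intrinsic(few)
  expect_true(qc$excluded)
  expect_identical(qc$reasons, "insufficient_spiking")

  clean <- simulate_current_clamp(neuron_presets("young"), seed = 2)$recording
  qc2 <- qc_intrinsic(clean)
  expect_false(qc2$excluded)

  # inject 2 mV synaptic-like bumps into the AHP epoch of the qualifying sweep
  bumpy <- clean
  ahp <- measure_ahp(bumpy)
  sw <- bumpy$sweeps[[ahp$sweep]]
  t_end <- sw$stimulus$onset + sw$stimulus$duration
  tt <- sweep_times(sw)
  for (t0 in seq(t_end + 20, t_end + 680, by = 35)) {
    idx <- tt >= t0 & tt < t0 + 30
    bumpy$sweeps[[ahp$sweep]]$samples[idx] <-
      sw$samples[idx] + 2 * exp(-(tt[idx] - t0) / 5)
  }
  qc3 <- qc_intrinsic(bumpy)
  expect_true(qc3$excluded)
  expect_identical(qc3$reasons, "excessive_synaptic_input")
})

test_that("extract_all reports per-metric undefined states without failing the cell", {
  sim <- simulate_current_clamp(neuron_presets("young"),
                                step_protocol(seq(100, 700, by = 50)),
                                seed = 1)
  f <- extract_all(sim$recording)
  expect_true(is.na(f$rin_mohm) && is.na(f$tau_ms))
  expect_false(is.na(f$ahp_mv))
  expect_false(is.na(f$threshold_mv))
  expect_true(any(grepl("-50 pA", attr(f, "undefined"))))
  # a cohort of 10 cells gives a 10-row feature table on disk
  coh <- simulate_intrinsic_cohort(c(young = 5, old = 5), seed = 1,
                                   ground_truth = FALSE)
  feats <- do.call(rbind, lapply(coh, function(x)
    extract_all(x$recording, features = "ahp")))
  path <- file.path(tempdir(), "cohort.csv")
  write_feature_table(feats, path)
  expect_length(readLines(path), 11L)
  unlink(path)
})
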