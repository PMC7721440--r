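# Synthetic voltage-clamp data: homogeneous Poisson train of inward sEPSC-like
# events on a noisy, optionally drifting baseline, with an access-resistance
# trajectory for the QC gates.

#' Parameters of the synthetic sEPSC train
#'
#' @param rate_hz Poisson event rate, Hz.
#' @param amp_median_pa Median of the log-normal event amplitude
#'   distribution, pA (amplitudes are stored positive; inward polarity is
#'   applied at synthesis).
#' @param amp_shape Log-SD (shape) of the amplitude distribution.
#' @param tau_r,tau_d Rise and decay time constants of the event kernel, ms;
#'   `tau_d > tau_r > 0`.
#' @param duration_s Recording duration in seconds (default 240 s, the
#'   standard 4-minute voltage-clamp epoch).
#' @param noise_rms_pa RMS of the additive Gaussian baseline noise, pA.
#' @param drift_pa Linear baseline drift accumulated over the whole
#'   recording, pA.
#' @param ra_start_mohm,ra_end_mohm Access resistance at the start and end of
#'   the recording, MOhm (sampled every 10 s, linear trajectory).
#' @return An object of class `event_train_params`.
#' @export
event_train_params <- function(rate_hz = 2, amp_median_pa = 20,
                               amp_shape = 0.5, tau_r = 0.7, tau_d = 5,
                               duration_s = 240, noise_rms_pa = 2,
                               drift_pa = 0, ra_start_mohm = 12,
                               ra_end_mohm = 12) {
  if (rate_hz < 0) stop("event_train_params: rate_hz must be >= 0", call. = FALSE)
  if (!(tau_d > tau_r && tau_r > 0))
    stop("event_train_params: require tau_d > tau_r > 0", call. = FALSE)
  if (duration_s <= 0)
    stop("event_train_params: duration_s must be > 0", call. = FALSE)
  structure(list(rate_hz = rate_hz, amp_median_pa = amp_median_pa,
                 amp_shape = amp_shape, tau_r = tau_r, tau_d = tau_d,
                 duration_s = duration_s, noise_rms_pa = noise_rms_pa,
                 drift_pa = drift_pa, ra_start_mohm = ra_start_mohm,
                 ra_end_mohm = ra_end_mohm),
            class = "event_train_params")
}

# Peak-normalised difference-of-exponentials kernel on the dt grid.
# Support is truncated where the decay falls below 1% of peak.
epsc_kernel <- function(tau_r, tau_d, dt) {
  t_peak <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  t_end <- t_peak + tau_d * log(100)
  tt <- seq(0, t_end, by = dt)
  k <- exp(-tt / tau_d) - exp(-tt / tau_r)
  k / max(k)
}

#' Simulate a voltage-clamp recording of spontaneous inward events
#'
#' The trace is `sum_i -A_i k(t - t_i)` plus white Gaussian noise and a
#' linear drift, with `k` the peak-normalised difference of exponentials and
#' `t_i` a homogeneous Poisson process. Event onset times and amplitudes are
#' returned as ground truth.
#'
#' @param params An [event_train_params()].
#' @param seed Integer RNG seed.
#' @param cell_id,animal_id,group Metadata stored on the recording.
#' @return A list with `recording` (single voltage-clamp sweep at
#'   `dt = 0.05` ms, holding potential -75 mV) and `ground_truth`
#'   (`event_times_ms`, `event_amplitudes_pa`).
#' @export
simulate_voltage_clamp <- function(params, seed = 0, cell_id = "sim",
                                   animal_id = "sim", group = "synthetic") {
  stopifnot(inherits(params, "event_train_params"))
  set.seed(seed)
  dt <- 0.05
  dur_ms <- params$duration_s * 1000
  n <- round(dur_ms / dt)
  n_ev <- rpois(1, params$rate_hz * params$duration_s)
  t_ev <- sort(runif(n_ev, 0, dur_ms))
  a_ev <- rlnorm(n_ev, meanlog = log(params$amp_median_pa),
                 sdlog = params$amp_shape)
  trace <- numeric(n)
  if (n_ev > 0) {
    k <- epsc_kernel(params$tau_r, params$tau_d, dt)
    nk <- length(k)
    for (i in seq_len(n_ev)) {
      i0 <- floor(t_ev[i] / dt) + 1L
      idx <- i0:min(i0 + nk - 1L, n)
      trace[idx] <- trace[idx] - a_ev[i] * k[seq_along(idx)]
    }
  }
  if (params$noise_rms_pa > 0)
    trace <- trace + rnorm(n, sd = params$noise_rms_pa)
  if (params$drift_pa != 0)
    trace <- trace + params$drift_pa * (seq_len(n) - 1L) / (n - 1L)
  ra_t <- seq(0, params$duration_s, by = 10)
  ra <- data.frame(
    time_s = ra_t,
    ra_mohm = params$ra_start_mohm +
      (params$ra_end_mohm - params$ra_start_mohm) * ra_t / params$duration_s)
  rec <- recording(list(sweep_trace(trace, dt = dt, mode = "voltage_clamp")),
                   cell_id = cell_id, animal_id = animal_id, group = group,
                   holding_potential = -75, ra_series = ra)
  list(recording = rec,
       ground_truth = list(event_times_ms = t_ev, event_amplitudes_pa = a_ev))
}
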