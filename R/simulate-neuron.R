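# Synthetic current-clamp data: an exponential integrate-and-fire (EIF)
# neuron with a spike-triggered AHP conductance. The model is an emulation
# chosen so that the quantities the extractor must recover (Rin = 1/g_l,
# tau_m = c_m/g_l, spike times, AHP magnitude) are known exactly; it is not a
# biophysical claim about CA1 neurons.

#' Parameters of the synthetic integrate-and-fire neuron
#'
#' @param g_l Leak conductance in nS (input resistance is `1000 / g_l` MOhm
#'   when `a_w = 0`).
#' @param c_m Membrane capacitance in pF (`tau_m = c_m / g_l` ms).
#' @param e_l Resting potential in mV.
#' @param v_t Spike-initiation threshold of the exponential term, mV.
#' @param delta_t Slope factor of the exponential term, mV.
#' @param v_reset Post-spike reset potential, mV.
#' @param v_cut Numerical spike cutoff, mV; crossing it triggers the pasted
#'   stereotyped action-potential waveform (2 ms, peak +30 mV).
#' @param b_ahp AHP conductance increment per spike, nS.
#' @param tau_ahp AHP conductance decay time constant, ms.
#' @param e_k AHP reversal potential, mV.
#' @param a_w Subthreshold adaptation coupling, nS.
#' @param tau_w Adaptation time constant, ms.
#' @param noise_sigma Stationary SD of the additive band-limited (OU,
#'   2 ms correlation time) recording noise, mV.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(g_l = 6.667, c_m = 100, e_l = -67, v_t = -45,
                          delta_t = 2, v_reset = -55, v_cut = -40,
                          b_ahp = 0.15, tau_ahp = 150, e_k = -90,
                          a_w = 0, tau_w = 100, noise_sigma = 0.1) {
  p <- list(g_l = g_l, c_m = c_m, e_l = e_l, v_t = v_t, delta_t = delta_t,
            v_reset = v_reset, v_cut = v_cut, b_ahp = b_ahp,
            tau_ahp = tau_ahp, e_k = e_k, a_w = a_w, tau_w = tau_w,
            noise_sigma = noise_sigma)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1L ||
                   !is.finite(x), logical(1))))
    stop("neuron_params: all parameters must be single finite numbers",
         call. = FALSE)
  if (g_l <= 0 || c_m <= 0 || tau_ahp <= 0 || tau_w <= 0)
    stop("neuron_params: g_l, c_m, tau_ahp, tau_w must be > 0", call. = FALSE)
  if (!(e_k < e_l && e_l < v_t && v_t < v_cut))
    stop("neuron_params: require e_k < e_l < v_t < v_cut", call. = FALSE)
  if (noise_sigma < 0)
    stop("neuron_params: noise_sigma must be >= 0", call. = FALSE)
  structure(p, class = "neuron_params")
}

#' Named neuron presets
#'
#' `"young"` and `"old"` presets differ only in the AHP conductance
#' increment; they were calibrated once against the package's own AHP
#' extractor (on noiseless traces) so that the old-minus-young AHP magnitude
#' difference is about 2 mV, the effect scale the cohort statistics must
#' detect. The presets are synthetic: the underlying study reports AHP group
#' differences only graphically, so no printed value anchors them.
#'
#' @param name `"young"` or `"old"`.
#' @param ... Overrides passed to [neuron_params()].
#' @return A [neuron_params()].
#' @export
neuron_presets <- function(name = c("young", "old"), ...) {
  name <- match.arg(name)
  b <- switch(name, young = PRESET_B_AHP_YOUNG, old = PRESET_B_AHP_OLD)
  neuron_params(b_ahp = b, ...)
}

# Calibrated against the noiseless extractor (see methods vignette): with the
# across-neuron jitter below, cohort mean AHP is ~2.0 mV (young) vs ~4.0 mV
# (old), SD ~1.5 mV.
PRESET_B_AHP_YOUNG <- 0.14
PRESET_B_AHP_OLD <- 0.35
# Across-neuron SD of b_ahp used by simulate_intrinsic_cohort(); chosen so the
# induced SD of measured AHP is ~1.5 mV (AHP is ~ locally linear in b_ahp).
PRESET_B_AHP_SD <- 0.16

# Stereotyped action-potential waveform pasted at each spike: linear rise
# from v_cut to +30 mV in 0.5 ms, linear fall to v_reset over 1.5 ms. The
# fixed shape means AP amplitude/half-width are known constants and the
# upward 0 mV crossing exercises the spike detector.
ap_waveform <- function(params, dt = 0.05, peak = 30,
                        rise_ms = 0.5, total_ms = 2) {
  tw <- seq(0, total_ms - dt, by = dt)
  ifelse(tw <= rise_ms,
         params$v_cut + (peak - params$v_cut) * tw / rise_ms,
         peak - (peak - params$v_reset) * (tw - rise_ms) / (total_ms - rise_ms))
}


#' Simulate a current-clamp step-protocol recording
#'
#' Integrates the EIF model (fixed-step Euler at `dt = 0.05` ms, i.e. the
#' 20 kHz acquisition rate) for one sweep per protocol amplitude and returns
#' the recording together with its ground truth. The integrator itself is
#' deterministic; recording noise is added to the returned traces, so the
#' ground-truth spike times and the noiseless replicate used for the true AHP
#' are exact.
#'
#' @param params A [neuron_params()].
#' @param protocol A [step_protocol()].
#' @param seed Integer RNG seed (noise only).
#' @param pre_ms,post_ms Epochs before step onset and after step end, ms.
#'   `post_ms` must be at least 700 so the AHP windows fit.
#' @param cell_id,animal_id,group Metadata stored on the recording.
#' @param ground_truth Compute the full ground truth (including the AHP of
#'   the noiseless replicate, which requires running the AHP extractor);
#'   `FALSE` skips the replicate and leaves `ahp_mv`/`noiseless` unset,
#'   which is useful in large simulation sweeps.
#' @return A list with elements `recording` (a [recording()]) and
#'   `ground_truth` (spike times per sweep, true Rin/tau/AHP and spike counts).
#' @export
simulate_current_clamp <- function(params, protocol = step_protocol(),
                                   seed = 0, pre_ms = 150, post_ms = 720,
                                   cell_id = "sim", animal_id = "sim",
                                   group = "synthetic", ground_truth = TRUE) {
  stopifnot(inherits(params, "neuron_params"), inherits(protocol, "step_protocol"))
  dt <- 0.05
  n_pre <- round(pre_ms / dt); n_step <- round(protocol$step_duration / dt)
  n_post <- round(post_ms / dt)
  wave <- ap_waveform(params, dt)
  set.seed(seed)
  sim <- .eif_integrate(protocol$amplitudes, 0, n_pre, n_step, n_post, dt,
                        unclass(params), wave, params$noise_sigma, 2)
  make_rec <- function(vmat) {
    sw <- lapply(seq_along(protocol$amplitudes), function(i) {
      structure(list(samples = vmat[, i], dt = dt,
                     stimulus = stimulus_step(protocol$amplitudes[i],
                                              onset = pre_ms,
                                              duration = protocol$step_duration),
                     mode = "current_clamp"),
                class = "sweep_trace")  # integrator output is validated already
    })
    recording(sw, cell_id = cell_id, animal_id = animal_id, group = group,
              holding_potential = params$e_l)
  }
  rec <- make_rec(sim$v)
  step_end <- pre_ms + protocol$step_duration
  spike_counts <- vapply(sim$spike_times, function(st)
    sum(st >= pre_ms & st <= step_end), integer(1))
  gt <- list(
    spike_times = sim$spike_times,
    spike_counts = spike_counts,
    rin_mohm = 1000 / (params$g_l + params$a_w),
    tau_ms = params$c_m / params$g_l)
  if (ground_truth) {
    rec_clean <- if (is.null(sim$v_clean)) rec else make_rec(sim$v_clean)
    gt$ahp_mv <- tryCatch(
      measure_ahp(rec_clean, detect_spikes_all(rec_clean))$amplitude,
      error = function(e) NA_real_)
    gt$noiseless <- rec_clean
  }
  list(recording = rec, ground_truth = gt)
}
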