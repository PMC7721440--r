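# Current-clamp feature extraction: spike times, passive properties, AP
# waveform metrics, firing metrics, and the post-burst AHP, with the
# qualification and exclusion rules of the standard CA1 aging protocol:
#   - spikes are upward 0 mV crossings of the membrane potential;
#   - passive properties come from the -50 pA sweep;
#   - AP threshold is the voltage at maximal d3V/dt3 just before the first
#     elicited action potential's peak;
#   - the AHP qualifying sweep is the lowest-amplitude step firing at least
#     12 spikes (~50 Hz over 250 ms); baseline is the mean over a 100 ms
#     window starting 600 ms after step end, trough the minimum over the
#     first 175 ms after step end;
#   - cells failing the 12-spike rule, or with excessive synaptic input in
#     the AHP epoch, are flagged for exclusion but still reported.

# ---- spike detection --------------------------------------------------------

#' Detect action potentials as upward 0 mV crossings
#'
#' Each spike time is the linear interpolation between the two samples that
#' bracket an upward 0 mV crossing. Crossings closer than `refractory_ms`
#' are merged (the first is kept), guarding against noise-split crossings.
#'
#' @param sweep A current-clamp [sweep_trace()].
#' @param refractory_ms Minimum separation between reported spikes, ms.
#' @return An object of class `spike_train`: list with `times` (ms, strictly
#'   increasing) and `inst_freq` (Hz, `1/ISI` per consecutive pair; empty if
#'   fewer than two spikes).
#' @export
detect_spikes <- function(sweep, refractory_ms = 1) {
  if (!inherits(sweep, "sweep_trace") || sweep$mode != "current_clamp")
    stop("detect_spikes: requires a current-clamp sweep", call. = FALSE)
  pos <- .upward_crossings(matrix(sweep$samples, ncol = 1), 0)[[1]]
  spike_train_from_positions(pos, sweep$dt, refractory_ms)
}

spike_train_from_positions <- function(pos, dt, refractory_ms = 1) {
  times <- pos * dt
  if (length(times) > 1L) times <- times[c(TRUE, diff(times) >= refractory_ms)]
  freq <- if (length(times) >= 2L) 1000 / diff(times) else numeric(0)
  structure(list(times = times, inst_freq = freq), class = "spike_train")
}

# Spike trains for every sweep of a recording in one pass.
detect_spikes_all <- function(rec, refractory_ms = 1) {
  lens <- lengths(lapply(rec$sweeps, `[[`, "samples"))
  if (length(unique(lens)) != 1L)
    return(lapply(rec$sweeps, detect_spikes, refractory_ms = refractory_ms))
  vmat <- vapply(rec$sweeps, `[[`, numeric(lens[1]), "samples")
  lapply(.upward_crossings(vmat, 0), spike_train_from_positions,
         dt = rec$sweeps[[1]]$dt, refractory_ms = refractory_ms)
}

# Spikes occurring during the stimulus step of a sweep.
spikes_in_step <- function(train, stim) {
  train$times[train$times >= stim$onset &
              train$times <= stim$onset + stim$duration]
}

# ---- passive properties -----------------------------------------------------

#' Resting membrane potential from a stimulus-free segment
#'
#' @param sweep A current-clamp [sweep_trace()].
#' @param from_ms,to_ms Segment bounds, ms. The segment must not overlap the
#'   sweep's stimulus and must span at least 100 ms.
#' @return Mean voltage over the segment, mV.
#' @export
resting_potential <- function(sweep, from_ms = 0,
                              to_ms = if (is.null(sweep$stimulus))
                                sweep_span(sweep) else sweep$stimulus$onset) {
  if (!inherits(sweep, "sweep_trace") || sweep$mode != "current_clamp")
    stop("resting_potential: requires a current-clamp sweep", call. = FALSE)
  if (to_ms - from_ms < 100)
    stop("resting_potential: segment must span at least 100 ms", call. = FALSE)
  st <- sweep$stimulus
  if (!is.null(st) && st$amplitude != 0 &&
      from_ms < st$onset + st$duration && to_ms > st$onset)
    stop("resting_potential: segment overlaps the stimulus", call. = FALSE)
  idx <- window_index(sweep, from_ms, to_ms)
  mean(sweep$samples[idx])
}

# Inclusive sample indices covering [from_ms, to_ms].
window_index <- function(sweep, from_ms, to_ms) {
  i0 <- max(1L, ceiling(from_ms / sweep$dt - 1e-9) + 1L)
  i1 <- min(length(sweep$samples), floor(to_ms / sweep$dt + 1e-9) + 1L)
  if (i1 < i0) stop("window outside sweep", call. = FALSE)
  i0:i1
}

find_sweep_at <- function(rec, amplitude_pa, tol = 1e-6) {
  amps <- sweep_amplitudes(rec)
  i <- which(!is.na(amps) & abs(amps - amplitude_pa) < tol)
  if (!length(i)) return(NA_integer_)
  i[1]
}

# Pre-step baseline and final-20%-of-step steady state for a step sweep.
step_levels <- function(sweep) {
  st <- sweep$stimulus
  base <- mean(sweep$samples[window_index(sweep, 0, st$onset - sweep$dt)])
  t1 <- st$onset + st$duration
  steady <- mean(sweep$samples[window_index(sweep, t1 - 0.2 * st$duration, t1)])
  list(baseline = base, steady = steady)
}

#' Input resistance from the -50 pA step
#'
#' `Rin = dV / I` with `dV` the steady-state deflection, taken as the mean
#' over the final 20% of the step minus the pre-step baseline.
#'
#' @param rec A current-clamp [recording()] containing a -50 pA sweep, or
#'   that sweep directly.
#' @return Input resistance in MOhm (warns and returns 0 when the deflection
#'   is zero).
#' @export
input_resistance <- function(rec) {
  sweep <- passive_sweep(rec, "input_resistance")
  lv <- step_levels(sweep)
  dv <- lv$steady - lv$baseline
  if (dv == 0) {
    warning("input_resistance: zero deflection (non-physiological)",
            call. = FALSE)
    return(0)
  }
  1000 * dv / sweep$stimulus$amplitude  # mV/pA = GOhm -> MOhm
}

passive_sweep <- function(rec, who) {
  if (inherits(rec, "sweep_trace")) {
    if (is.null(rec$stimulus) || abs(rec$stimulus$amplitude - (-50)) > 1e-6)
      stop(who, ": sweep stimulus must be -50 pA", call. = FALSE)
    return(rec)
  }
  i <- find_sweep_at(rec, -50)
  if (is.na(i))
    stop(who, ": no -50 pA sweep in recording", call. = FALSE)
  rec$sweeps[[i]]
}

# Centred moving average over 2k+1 samples (w rounded to odd), computed by
# cumulative sums; edge samples keep their raw values.
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  k <- w %/% 2L
  w <- 2L * k + 1L
  n <- length(x)
  if (n < w) return(x)
  cs <- c(0, cumsum(x))
  sm <- x
  i <- (k + 1L):(n - k)
  sm[i] <- (cs[i + k + 1L] - cs[i - k]) / w
  sm
}

#' Membrane time constant from the -50 pA step
#'
#' The first time after step onset at which the voltage change reaches 63%
#' of the maximum (steady-state) change, linearly interpolated between
#' samples. To keep the crossing robust to recording noise the trace is
#' first smoothed with a centred moving average (`smooth_ms`, default 4 ms)
#' and the maximum change is taken as the steady-state deflection (final
#' 20% of the step minus baseline); both choices are exact on noiseless
#' exponential input.
#'
#' @inheritParams input_resistance
#' @param smooth_ms Width of the centred moving-average smoother, ms; 0
#'   disables smoothing.
#' @return Time constant in ms.
#' @export
membrane_time_constant <- function(rec, smooth_ms = 4) {
  sweep <- passive_sweep(rec, "membrane_time_constant")
  lv <- step_levels(sweep)
  dv <- lv$steady - lv$baseline
  if (dv == 0)
    stop("membrane_time_constant: maximum voltage change is zero", call. = FALSE)
  st <- sweep$stimulus
  idx <- window_index(sweep, st$onset, st$onset + st$duration)
  v <- moving_average(sweep$samples, max(1L, round(smooth_ms / sweep$dt)))[idx]
  defl <- (v - lv$baseline) / dv  # fraction of steady-state change, sign-free
  target <- 0.63
  hit <- which(defl >= target)
  if (!length(hit))
    stop("membrane_time_constant: 63% level never reached during step",
         call. = FALSE)
  j <- hit[1]
  t_idx <- (idx - 1) * sweep$dt - st$onset  # time from step onset
  if (j == 1L) return(max(t_idx[1], sweep$dt))
  frac <- (target - defl[j - 1]) / (defl[j] - defl[j - 1])
  t_idx[j - 1] + frac * sweep$dt
}

# ---- AP waveform metrics ----------------------------------------------------

# The first action potential elicited across the protocol: first spike of the
# lowest-amplitude sweep that spikes. Returns sweep index and spike time.
first_ap <- function(rec, trains) {
  amps <- sweep_amplitudes(rec)
  ord <- order(amps)
  for (i in ord) {
    if (length(trains[[i]]$times))
      return(list(sweep = i, time = trains[[i]]$times[1]))
  }
  NULL
}

# Index of the AP peak sample near a spike time.
ap_peak_index <- function(sweep, spike_time, search_ms = 2) {
  idx <- window_index(sweep, max(0, spike_time - 1),
                      min(sweep_span(sweep), spike_time + search_ms))
  idx[which.max(sweep$samples[idx])]
}

# Third finite difference of v via repeated central differences, each stage
# optionally smoothed with a w-point moving average (w = 1 disables).
third_derivative <- function(v, dt, smooth_pts = 3) {
  d <- v
  for (k in 1:3) {
    n <- length(d)
    d <- c(NA, (d[3:n] - d[1:(n - 2)]) / (2 * dt), NA)
    if (smooth_pts > 1L) {
      ok <- !is.na(d)
      d[ok] <- moving_average(d[ok], smooth_pts)
    }
  }
  d
}

#' Action-potential threshold (maximal third derivative)
#'
#' Threshold is the voltage at which `d3V/dt3` is maximal in a short window
#' just before the peak of the first elicited action potential. Derivatives
#' are repeated central differences with a light 3-point moving-average
#' smoothing per stage (configurable; disable with `smooth_pts = 1` for raw
#' differences).
#'
#' @param rec A current-clamp [recording()].
#' @param trains Optional list of [detect_spikes()] results, one per sweep.
#' @param window_ms Search window before the AP peak, ms.
#' @param smooth_pts Moving-average width (samples) applied per derivative
#'   stage.
#' @return List with `threshold` (mV), `sweep`, `peak_time` (ms),
#'   `peak_v` (mV), `threshold_time` (ms).
#' @export
ap_threshold <- function(rec, trains = NULL, window_ms = 2, smooth_pts = 3) {
  if (is.null(trains)) trains <- lapply(rec$sweeps, detect_spikes)
  fa <- first_ap(rec, trains)
  if (is.null(fa))
    stop("ap_threshold: threshold undefined (no spikes in recording)",
         call. = FALSE)
  sweep <- rec$sweeps[[fa$sweep]]
  ip <- ap_peak_index(sweep, fa$time)
  i0 <- max(1L, ip - round(window_ms / sweep$dt))
  d3 <- third_derivative(sweep$samples[i0:ip], sweep$dt, smooth_pts)
  j <- which.max(d3)
  list(threshold = sweep$samples[i0 + j - 1L], sweep = fa$sweep,
       peak_time = (ip - 1L) * sweep$dt, peak_v = sweep$samples[ip],
       threshold_time = (i0 + j - 2L) * sweep$dt)
}

#' Action-potential amplitude
#'
#' Peak voltage of the first elicited action potential minus its threshold.
#'
#' @inheritParams ap_threshold
#' @param thr Optional result of [ap_threshold()] (computed if missing).
#' @return Amplitude in mV.
#' @export
ap_amplitude <- function(rec, trains = NULL, thr = NULL) {
  if (is.null(thr)) thr <- ap_threshold(rec, trains)
  thr$peak_v - thr$threshold
}

#' Action-potential half-width
#'
#' Duration of the first elicited action potential at half its amplitude:
#' the time between the interpolated upward and downward crossings of
#' `threshold + amplitude/2` around the peak.
#'
#' @inheritParams ap_amplitude
#' @param max_fall_ms Maximum time after the peak to search for the downward
#'   crossing.
#' @return Half-width in ms.
#' @export
ap_half_width <- function(rec, trains = NULL, thr = NULL, max_fall_ms = 10) {
  if (is.null(thr)) thr <- ap_threshold(rec, trains)
  sweep <- rec$sweeps[[thr$sweep]]
  half <- thr$threshold + (thr$peak_v - thr$threshold) / 2
  v <- sweep$samples
  ip <- round(thr$peak_time / sweep$dt) + 1L
  # upward crossing: last pass through `half` before the peak
  iu <- which(v[seq_len(ip - 1L)] < half & v[2:ip] >= half)
  if (!length(iu))
    stop("ap_half_width: no upward half-amplitude crossing", call. = FALSE)
  iu <- iu[length(iu)]
  t_up <- (iu - 1L + (half - v[iu]) / (v[iu + 1L] - v[iu])) * sweep$dt
  # downward crossing: first pass below `half` after the peak
  i_end <- min(length(v) - 1L, ip + round(max_fall_ms / sweep$dt))
  seg <- ip:i_end
  idn <- seg[v[seg] >= half & v[seg + 1L] < half]
  if (!length(idn))
    stop("ap_half_width: no downward crossing within ", max_fall_ms,
         " ms of peak", call. = FALSE)
  idn <- idn[1]
  t_dn <- (idn - 1L + (v[idn] - half) / (v[idn] - v[idn + 1L])) * sweep$dt
  t_dn - t_up
}

# ---- firing metrics ---------------------------------------------------------

#' Firing metrics across the step protocol
#'
#' Maximum firing frequency (highest instantaneous frequency over all
#' sweeps), F/I slope (ordinary least squares of first instantaneous
#' frequency on step amplitude, restricted to sweeps with a defined positive
#' first frequency, i.e. at least two spikes), and adaptation index
#' (last/first instantaneous frequency of the sweep whose amplitude is
#' nearest to 250 pA above the first spiking step). Each metric reports
#' `NA` with a reason when its precondition fails, without failing the
#' others.
#'
#' @param rec A current-clamp [recording()].
#' @param trains Optional list of [detect_spikes()] results per sweep.
#' @return List with `max_freq_hz`, `fi_slope_hz_pa`, `adaptation_index`,
#'   and `undefined` (named character vector of reasons for NA metrics).
#' @export
firing_metrics <- function(rec, trains = NULL) {
  if (is.null(trains)) trains <- lapply(rec$sweeps, detect_spikes)
  amps <- sweep_amplitudes(rec)
  undefined <- character(0)

  all_freq <- unlist(lapply(trains, `[[`, "inst_freq"))
  if (length(all_freq)) max_freq <- max(all_freq)
  else {
    max_freq <- NA_real_
    undefined["max_freq_hz"] <- "no sweep with >= 2 spikes"
  }

  first_freq <- vapply(trains, function(tr)
    if (length(tr$inst_freq)) tr$inst_freq[1] else NA_real_, numeric(1))
  pos <- which(!is.na(first_freq) & first_freq > 0)
  if (length(pos) >= 2L) {
    fit <- lm(first_freq[pos] ~ amps[pos])
    fi_slope <- unname(coef(fit)[2])
  } else {
    fi_slope <- NA_real_
    undefined["fi_slope_hz_pa"] <- "fewer than 2 positive F/I points"
  }

  spiking <- which(vapply(trains, function(tr) length(tr$times) > 0, logical(1)))
  adapt <- NA_real_
  if (!length(spiking)) {
    undefined["adaptation_index"] <- "no spiking sweep"
  } else {
    i_first <- spiking[which.min(amps[spiking])]
    target <- amps[i_first] + 250
    i_ad <- which.min(abs(amps - target))
    fr <- trains[[i_ad]]$inst_freq
    if (length(fr) < 1L) {
      undefined["adaptation_index"] <-
        sprintf("adaptation sweep (%g pA) has < 2 spikes", amps[i_ad])
    } else adapt <- fr[length(fr)] / fr[1]
  }

  list(max_freq_hz = max_freq, fi_slope_hz_pa = fi_slope,
       adaptation_index = adapt, undefined = undefined)
}

# ---- AHP --------------------------------------------------------------------

#' Post-burst afterhyperpolarization
#'
#' The qualifying sweep is the lowest-amplitude step that elicits at least
#' `min_spikes` spikes during the step (12 spikes in 250 ms is ~50 Hz).
#' Baseline is the mean voltage over a `baseline_len_ms` window starting
#' `baseline_start_ms` after step end; the trough is the minimum voltage in
#' the first `trough_len_ms` after step end. Amplitude is reported as the
#' positive magnitude `baseline - trough`.
#'
#' @param rec A current-clamp [recording()].
#' @param trains Optional list of [detect_spikes()] results per sweep.
#' @param min_spikes Qualification rule: minimum spikes within the step.
#' @param trough_len_ms,baseline_start_ms,baseline_len_ms AHP windows, ms.
#' @return An object of class `ahp_measure`: list with `sweep`,
#'   `current_pa`, `baseline_mv`, `trough_mv`, `amplitude` (mV).
#' @export
measure_ahp <- function(rec, trains = NULL, min_spikes = 12,
                        trough_len_ms = 175, baseline_start_ms = 600,
                        baseline_len_ms = 100) {
  if (is.null(trains)) trains <- lapply(rec$sweeps, detect_spikes)
  amps <- sweep_amplitudes(rec)
  counts <- vapply(seq_along(trains), function(i) {
    st <- rec$sweeps[[i]]$stimulus
    if (is.null(st)) return(0L)
    length(spikes_in_step(trains[[i]], st))
  }, integer(1))
  qual <- which(counts >= min_spikes)
  if (!length(qual))
    stop("measure_ahp: no sweep fires at least ", min_spikes,
         " spikes (insufficient_spiking)", call. = FALSE)
  i <- qual[which.min(amps[qual])]
  sweep <- rec$sweeps[[i]]
  st <- sweep$stimulus
  t_end <- st$onset + st$duration
  if (sweep_span(sweep) - t_end < baseline_start_ms + baseline_len_ms)
    stop("measure_ahp: post-step epoch shorter than ",
         baseline_start_ms + baseline_len_ms, " ms", call. = FALSE)
  trough_idx <- window_index(sweep, t_end, t_end + trough_len_ms)
  base_idx <- window_index(sweep, t_end + baseline_start_ms,
                           t_end + baseline_start_ms + baseline_len_ms)
  trough <- min(sweep$samples[trough_idx])
  baseline <- mean(sweep$samples[base_idx])
  structure(list(sweep = i, current_pa = amps[i], baseline_mv = baseline,
                 trough_mv = trough, amplitude = baseline - trough),
            class = "ahp_measure")
}

# ---- QC ---------------------------------------------------------------------

#' Intrinsic-recording quality control
#'
#' A cell is flagged `insufficient_spiking` when no sweep reaches
#' `min_spikes` spikes during its step, and `excessive_synaptic_input` when
#' the high-pass residual RMS (trace minus a 50 ms moving average, i.e.
#' fluctuations faster than ~20 Hz) within the AHP measurement epoch of the
#' qualifying sweep exceeds `synaptic_rms_mv`.
#'
#' @inheritParams measure_ahp
#' @param synaptic_rms_mv High-pass residual RMS threshold, mV.
#' @return List with `excluded` (flag) and `reasons` (character vector drawn
#'   from `insufficient_spiking`, `excessive_synaptic_input`).
#' @export
qc_intrinsic <- function(rec, trains = NULL, min_spikes = 12,
                         synaptic_rms_mv = 0.5) {
  if (is.null(trains)) trains <- lapply(rec$sweeps, detect_spikes)
  reasons <- character(0)
  ahp <- tryCatch(measure_ahp(rec, trains, min_spikes = min_spikes),
                  error = function(e) NULL)
  if (is.null(ahp)) {
    reasons <- c(reasons, "insufficient_spiking")
  } else {
    sweep <- rec$sweeps[[ahp$sweep]]
    st <- sweep$stimulus
    t_end <- st$onset + st$duration
    idx <- window_index(sweep, t_end,
                        min(sweep_span(sweep), t_end + 700))
    v <- sweep$samples[idx]
    resid <- v - moving_average(v, round(50 / sweep$dt))
    if (sqrt(mean(resid^2)) > synaptic_rms_mv)
      reasons <- c(reasons, "excessive_synaptic_input")
  }
  list(excluded = length(reasons) > 0, reasons = reasons)
}

# ---- aggregation ------------------------------------------------------------

#' Extract all intrinsic features of a recording
#'
#' Runs spike detection on every sweep and computes passive properties, AP
#' waveform metrics, firing metrics, the AHP and the QC verdict. Metrics
#' whose preconditions fail are reported as `NA` (with the reason in
#' `undefined`) rather than aborting the cell; excluded cells are flagged
#' but still reported.
#'
#' @param rec A current-clamp [recording()].
#' @param features Character vector selecting feature families to compute
#'   (any of `"passive"`, `"ap"`, `"firing"`, `"ahp"`); default all.
#' @return A one-row data.frame (class `intrinsic_features`) with columns
#'   `cell_id`, `animal_id`, `group`, `v_rest_mv`, `rin_mohm`, `tau_ms`,
#'   `threshold_mv`, `amplitude_mv`, `half_width_ms`, `max_freq_hz`,
#'   `fi_slope_hz_pa`, `adaptation_index`, `ahp_mv`, `ahp_current_pa`,
#'   `excluded`, `qc_reasons`; the `undefined` attribute maps NA metrics to
#'   reasons.
#' @export
extract_all <- function(rec, features = c("passive", "ap", "firing", "ahp")) {
  if (!inherits(rec, "recording"))
    stop("extract_all: 'rec' must be a recording", call. = FALSE)
  if (rec$sweeps[[1]]$mode != "current_clamp")
    stop("extract_all: requires a current-clamp recording (cell ",
         rec$cell_id, ")", call. = FALSE)
  features <- match.arg(features, several.ok = TRUE)
  trains <- detect_spikes_all(rec)
  undefined <- character(0)
  grab <- function(expr, name) {
    tryCatch(expr, error = function(e) {
      undefined[name] <<- conditionMessage(e)
      NA_real_
    })
  }
  v_rest <- rin <- tau <- thr_v <- amp <- hw <- NA_real_
  max_f <- fi <- adapt <- ahp_amp <- ahp_cur <- NA_real_
  if ("passive" %in% features) {
    v_rest <- grab(resting_potential(rec$sweeps[[1]]), "v_rest_mv")
    rin <- grab(input_resistance(rec), "rin_mohm")
    tau <- grab(membrane_time_constant(rec), "tau_ms")
  }
  if ("ap" %in% features) {
    thr <- tryCatch(ap_threshold(rec, trains), error = function(e) {
      undefined["threshold_mv"] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(thr)) {
      thr_v <- thr$threshold
      amp <- grab(ap_amplitude(rec, trains, thr), "amplitude_mv")
      hw <- grab(ap_half_width(rec, trains, thr), "half_width_ms")
    }
  }
  if ("firing" %in% features) {
    fm <- firing_metrics(rec, trains)
    max_f <- fm$max_freq_hz; fi <- fm$fi_slope_hz_pa
    adapt <- fm$adaptation_index
    undefined <- c(undefined, fm$undefined)
  }
  qc <- list(excluded = FALSE, reasons = character(0))
  if ("ahp" %in% features) {
    ahp <- tryCatch(measure_ahp(rec, trains), error = function(e) {
      undefined["ahp_mv"] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(ahp)) {
      ahp_amp <- ahp$amplitude
      ahp_cur <- ahp$current_pa
    }
    qc <- qc_intrinsic(rec, trains)
  }
  out <- data.frame(
    cell_id = rec$cell_id, animal_id = rec$animal_id, group = rec$group,
    v_rest_mv = v_rest, rin_mohm = rin, tau_ms = tau,
    threshold_mv = thr_v, amplitude_mv = amp, half_width_ms = hw,
    max_freq_hz = max_f, fi_slope_hz_pa = fi, adaptation_index = adapt,
    ahp_mv = ahp_amp, ahp_current_pa = ahp_cur,
    excluded = qc$excluded,
    qc_reasons = paste(qc$reasons, collapse = ";"),
    stringsAsFactors = FALSE)
  attr(out, "undefined") <- undefined
  class(out) <- c("intrinsic_features", class(out))
  out
}
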