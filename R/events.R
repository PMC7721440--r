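# Scaled-template sEPSC detection (Clements-Bekkers): at every lag the
# template is fitted to the trace by least squares in scale and offset; the
# detection criterion is the fitted scale divided by its standard error.
# Local maxima of the criterion above threshold become events.

#' Build a detection template from aligned event snippets
#'
#' Pointwise mean of at least 10 equal-length snippets aligned at event
#' onset, baseline-subtracted (the pre-onset level, taken from the first
#' sample of the averaged snippet) and normalised to unit peak magnitude.
#'
#' @param snippets List (or matrix, snippets in columns) of equal-length
#'   numeric traces.
#' @param dt Sampling interval, ms.
#' @param tau_r,tau_d Optional rise/decay descriptors stored on the
#'   template (ms), used for the event-separation guard.
#' @return An object of class `epsc_template`: `waveform` (unit peak
#'   magnitude), `dt`, `tau_r`, `tau_d`, `provenance`.
#' @export
build_template <- function(snippets, dt, tau_r = NA, tau_d = NA) {
  if (is.matrix(snippets)) snippets <- asplit(snippets, 2)
  if (length(snippets) < 10L)
    stop("build_template: need at least 10 snippets", call. = FALSE)
  len <- lengths(snippets)
  if (length(unique(len)) != 1L)
    stop("build_template: snippets must have equal length", call. = FALSE)
  w <- Reduce(`+`, lapply(snippets, as.numeric)) / length(snippets)
  w <- w - w[1]
  pk <- max(abs(w))
  if (pk == 0) stop("build_template: zero peak after baseline subtraction",
                    call. = FALSE)
  new_template(w / pk, dt, tau_r, tau_d, "averaged_events")
}

new_template <- function(waveform, dt, tau_r, tau_d, provenance) {
  structure(list(waveform = waveform, dt = dt, tau_r = tau_r, tau_d = tau_d,
                 provenance = provenance),
            class = "epsc_template")
}

#' Synthetic sEPSC detection template
#'
#' Difference-of-exponentials kernel (default rise 0.7 ms, decay 5 ms,
#' typical of CA1 sEPSCs at 32-34 degrees C), peak-normalised; used when no
#' averaged-event template is available.
#'
#' @param dt Sampling interval, ms.
#' @param tau_r,tau_d Rise and decay time constants, ms.
#' @return An `epsc_template`.
#' @export
synthetic_template <- function(dt = 0.05, tau_r = 0.7, tau_d = 5) {
  new_template(epsc_kernel(tau_r, tau_d, dt), dt, tau_r, tau_d,
               "synthetic_kernel")
}

#' Detect inward synaptic events by scaled-template matching
#'
#' Slides the (inward-oriented) template along the trace, fitting scale and
#' offset by least squares at each lag; the detection criterion is the
#' fitted scale over the standard error of the fit. Criterion local maxima
#' at or above `criterion_threshold`, separated by at least the template's
#' rise+decay span, are reported as events; the fitted scale is the event
#' amplitude (positive magnitude of the inward deflection). Running sums are
#' computed by FFT cross-correlation, so a 4-minute 20 kHz trace is
#' processed in seconds.
#'
#' Candidates falling inside the template span of an already-accepted event
#' are kept only if their fitted amplitude reaches `tail_guard` times the
#' accepted amplitude: this discards the small spurious fits that the
#' template's own decay tail produces (prominent on very low-noise traces)
#' while retaining genuinely overlapping events.
#'
#' @param trace A voltage-clamp [sweep_trace()] (or a [recording()] whose
#'   first sweep is used).
#' @param template An `epsc_template` with the same `dt` as the trace.
#' @param criterion_threshold Detection-criterion threshold (default 4).
#' @param tail_guard Relative amplitude floor applied within an accepted
#'   event's template span.
#' @param min_above_ms Debounce: a candidate peak is only counted if the
#'   criterion stays at or above threshold for at least this long around it
#'   (single-sample noise excursions cross the threshold for far less time
#'   than a real event does).
#' @return A data.frame with columns `time_ms` (event onset), `amplitude_pa`
#'   (positive), `criterion`.
#' @export
detect_events <- function(trace, template = NULL, criterion_threshold = 4,
                          tail_guard = 0.2, min_above_ms = 0.5) {
  if (inherits(trace, "recording")) trace <- trace$sweeps[[1]]
  if (!inherits(trace, "sweep_trace") || trace$mode != "voltage_clamp")
    stop("detect_events: requires a voltage-clamp trace", call. = FALSE)
  if (is.null(template)) template <- synthetic_template(trace$dt)
  if (abs(template$dt - trace$dt) > 1e-12)
    stop("detect_events: template dt (", template$dt,
         ") does not match trace dt (", trace$dt, ")", call. = FALSE)
  y <- -trace$samples  # inward (negative) deflections become positive
  w <- template$waveform
  N <- length(w)
  M <- length(y)
  if (M <= N) return(empty_events())
  n_lag <- M - N + 1L

  fit <- .cb_criterion(y, w)
  scale <- fit$scale
  crit <- fit$criterion

  above <- which(crit >= criterion_threshold)
  if (!length(above)) return(empty_events())
  # debounce: drop above-threshold runs shorter than min_above_ms
  min_run <- max(1L, round(min_above_ms / trace$dt))
  run_id <- cumsum(c(1L, diff(above) > 1L))
  run_len <- tabulate(run_id)
  above <- above[run_len[run_id] >= min_run]
  if (!length(above)) return(empty_events())
  is_peak <- above[crit[above] >= crit[pmax(above - 1L, 1L)] &
                   crit[above] >= crit[pmin(above + 1L, n_lag)]]
  if (!length(is_peak)) return(empty_events())
  sep_ms <- if (is.finite(template$tau_r + template$tau_d))
    template$tau_r + template$tau_d else N * trace$dt / 4
  sep <- max(1L, round(sep_ms / trace$dt))
  # Merge candidate peaks that sit on one criterion ridge: two peaks are
  # distinct events only if separated by at least the rise+decay span AND
  # the criterion dips between them (below threshold, or below half the
  # smaller peak); otherwise the stronger peak wins.
  keep <- integer(0)
  for (i in is_peak) {
    if (length(keep)) {
      last <- keep[length(keep)]
      dip <- min(crit[last:i])
      distinct <- (i - last >= sep) &&
        (dip < criterion_threshold || dip < 0.75 * min(crit[i], crit[last]))
      if (!distinct) {
        if (crit[i] > crit[last]) keep[length(keep)] <- i
        next
      }
      if (i - last < N && scale[i] < tail_guard * scale[last])
        next  # decay-tail artifact of the previous event
    }
    keep <- c(keep, i)
  }
  data.frame(time_ms = (keep - 1L) * trace$dt,
             amplitude_pa = scale[keep] * max(abs(w)),
             criterion = crit[keep])
}

empty_events <- function() {
  data.frame(time_ms = numeric(0), amplitude_pa = numeric(0),
             criterion = numeric(0))
}

#' Voltage-clamp recording quality control
#'
#' Applies the three standard gates: access resistance must never exceed
#' `ra_limit_mohm` (30 MOhm); the baseline must be stable (absolute change
#' between the median of the first and last `edge_s` seconds below
#' `baseline_limit_pa`, 50 pA); and the event-free baseline noise must stay
#' below `noise_limit_pa` (8 pA RMS). Noise is estimated robustly as
#' 1.4826 x the median absolute deviation of the high-pass residual (trace
#' minus a 1 s moving average, i.e. fluctuations faster than ~1 Hz), so
#' synaptic events do not inflate the estimate.
#'
#' @param rec A voltage-clamp [recording()] (with optional `ra_series`).
#' @param ra_limit_mohm,baseline_limit_pa,noise_limit_pa QC thresholds.
#' @param edge_s Length of the leading/trailing baseline windows, s.
#' @return List with `pass` (flag), `reasons` (subset of `ra_exceeded`,
#'   `baseline_unstable`, `noise_excessive`), and `measured` (named list:
#'   `ra_max_mohm`, `baseline_change_pa`, `noise_rms_pa`).
#' @export
qc_voltage_clamp <- function(rec, ra_limit_mohm = 30, baseline_limit_pa = 50,
                             noise_limit_pa = 8, edge_s = 10) {
  if (!inherits(rec, "recording"))
    stop("qc_voltage_clamp: 'rec' must be a recording", call. = FALSE)
  trace <- rec$sweeps[[1]]
  reasons <- character(0)
  ra_max <- NA_real_
  if (!is.null(rec$ra_series)) {
    ra_max <- max(rec$ra_series$ra_mohm)
    if (ra_max > ra_limit_mohm) reasons <- c(reasons, "ra_exceeded")
  }
  y <- trace$samples
  n_edge <- min(length(y), round(edge_s * 1000 / trace$dt))
  base_change <- abs(median(y[(length(y) - n_edge + 1L):length(y)]) -
                     median(y[seq_len(n_edge)]))
  if (base_change >= baseline_limit_pa)
    reasons <- c(reasons, "baseline_unstable")
  w <- max(3L, round(1000 / trace$dt))  # 1 s moving average (~1 Hz corner)
  resid <- y - moving_average(y, min(w, length(y) - 1L))
  noise <- 1.4826 * median(abs(resid - median(resid)))
  if (noise >= noise_limit_pa) reasons <- c(reasons, "noise_excessive")
  list(pass = length(reasons) == 0L, reasons = reasons,
       measured = list(ra_max_mohm = ra_max, baseline_change_pa = base_change,
                       noise_rms_pa = noise))
}

#' Summarise a detected event series
#'
#' Applies the first-250-events rule: if more than 250 events were detected,
#' only the first 250 are analysed and the analysed duration is the time of
#' the 250th event; otherwise all events are analysed over the full trace
#' duration. Frequency is analysed events / analysed duration; amplitude is
#' the mean over the analysed set (NA when empty).
#'
#' @param events data.frame from [detect_events()], time-sorted.
#' @param duration_s Trace duration in seconds.
#' @param cap Maximum number of analysed events (default 250).
#' @return List with `n_events`, `frequency_hz`, `mean_amplitude_pa`,
#'   `analyzed_duration_s`.
#' @export
summarize_events <- function(events, duration_s, cap = 250) {
  if (is.unsorted(events$time_ms))
    stop("summarize_events: events must be time-sorted", call. = FALSE)
  n <- nrow(events)
  if (n > cap) {
    events <- events[seq_len(cap), ]
    dur <- events$time_ms[cap] / 1000
    n <- cap
  } else dur <- duration_s
  list(n_events = n,
       frequency_hz = if (dur > 0) n / dur else NA_real_,
       mean_amplitude_pa = if (n > 0) mean(events$amplitude_pa) else NA_real_,
       analyzed_duration_s = dur)
}
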