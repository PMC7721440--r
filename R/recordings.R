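#' @useDynLib patchstats, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aov cor.test median oneway.test pf ptukey pt qt rnorm
#'   runif rpois rlnorm sd setNames t.test coef lm filter
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# Canonical internal units: mV (voltage), pA (current), ms (time), MOhm
# (resistance). Conversion happens only at I/O boundaries.

#' Stimulus step metadata
#'
#' Describes a rectangular current step delivered during a sweep.
#'
#' @param amplitude Step amplitude in pA.
#' @param onset Step onset in ms from the start of the sweep (sample 0 is
#'   time 0).
#' @param duration Step duration in ms (default 250).
#' @param holding_current Holding current in pA applied outside the step.
#' @return An object of class `stimulus_step`.
#' @export
stimulus_step <- function(amplitude, onset, duration = 250, holding_current = 0) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude))
  if (!is.numeric(duration) || duration <= 0)
    stop("stimulus_step: 'duration' must be > 0", call. = FALSE)
  if (!is.numeric(onset) || onset < 0)
    stop("stimulus_step: 'onset' must be >= 0", call. = FALSE)
  structure(
    list(amplitude = as.numeric(amplitude), onset = as.numeric(onset),
         duration = as.numeric(duration),
         holding_current = as.numeric(holding_current)),
    class = "stimulus_step")
}

#' A single sweep of uniformly sampled data
#'
#' @param samples Numeric vector of samples: membrane potential in mV for
#'   current clamp, membrane current in pA for voltage clamp. Sample `i`
#'   sits at time `(i - 1) * dt` ms.
#' @param dt Sampling interval in ms (0.05 ms corresponds to 20 kHz).
#' @param stimulus A [stimulus_step()], or `NULL` for continuous
#'   (voltage-clamp) sweeps.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @return An object of class `sweep_trace`.
#' @export
sweep_trace <- function(samples, dt, stimulus = NULL,
                        mode = c("current_clamp", "voltage_clamp")) {
  mode <- match.arg(mode)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("sweep_trace: 'dt' must be a single positive number", call. = FALSE)
  if (!is.numeric(samples) || length(samples) < 2L)
    stop("sweep_trace: 'samples' must be a numeric vector", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("sweep_trace: 'samples' must all be finite", call. = FALSE)
  if (!is.null(stimulus) && !inherits(stimulus, "stimulus_step"))
    stop("sweep_trace: 'stimulus' must be a stimulus_step or NULL", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), dt = as.numeric(dt),
         stimulus = stimulus, mode = mode),
    class = "sweep_trace")
}

#' Sweep time axis
#' @param sweep A [sweep_trace()].
#' @return Numeric vector of sample times in ms.
#' @export
sweep_times <- function(sweep) {
  (seq_along(sweep$samples) - 1L) * sweep$dt
}

#' Sweep duration in ms
#' @param sweep A [sweep_trace()].
#' @return Total sweep span in ms.
#' @export
sweep_span <- function(sweep) (length(sweep$samples) - 1L) * sweep$dt

#' A whole-cell recording: a bundle of sweeps plus cell metadata
#'
#' @param sweeps List of [sweep_trace()] objects sharing `dt` and `mode`.
#' @param cell_id,animal_id Identifiers.
#' @param group Non-empty group label (e.g. `"Young"`, `"Old"`,
#'   `"Old+ISRIB"`).
#' @param holding_potential Command potential in mV (voltage clamp) or the
#'   maintained potential (current clamp); metadata only.
#' @param ra_series Optional data.frame with columns `time_s` and `ra_mohm`:
#'   access-resistance samples logged during the recording.
#' @return An object of class `recording`.
#' @export
recording <- function(sweeps, cell_id = "cell", animal_id = "animal",
                      group = "unassigned", holding_potential = NA_real_,
                      ra_series = NULL) {
  if (!is.list(sweeps) || length(sweeps) == 0L ||
      !all(vapply(sweeps, inherits, logical(1), "sweep_trace")))
    stop("recording: 'sweeps' must be a non-empty list of sweep_trace", call. = FALSE)
  dts <- vapply(sweeps, `[[`, numeric(1), "dt")
  if (length(unique(dts)) != 1L)
    stop("recording: all sweeps must share the same 'dt'", call. = FALSE)
  modes <- vapply(sweeps, `[[`, character(1), "mode")
  if (length(unique(modes)) != 1L)
    stop("recording: all sweeps must share the same 'mode'", call. = FALSE)
  if (!is.character(group) || length(group) != 1L || !nzchar(group))
    stop("recording: 'group' label must be non-empty", call. = FALSE)
  if (!is.null(ra_series)) {
    if (!is.data.frame(ra_series) ||
        !all(c("time_s", "ra_mohm") %in% names(ra_series)))
      stop("recording: 'ra_series' needs columns time_s, ra_mohm", call. = FALSE)
  }
  structure(
    list(cell_id = cell_id, animal_id = animal_id, group = group,
         sweeps = sweeps, holding_potential = as.numeric(holding_potential),
         ra_series = ra_series),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> cell %s (animal %s, group %s): %d %s sweep(s), dt %g ms\n",
              x$cell_id, x$animal_id, x$group, length(x$sweeps),
              x$sweeps[[1]]$mode, x$sweeps[[1]]$dt))
  invisible(x)
}

#' Current-step protocol
#'
#' @param amplitudes Strictly increasing step amplitudes in pA. Default is the
#'   standard 20-step protocol, -250 to 700 pA in 50 pA increments.
#' @param step_duration Step duration in ms.
#' @param description Free-text note on inter-step handling.
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(amplitudes = seq(-250, 700, by = 50),
                          step_duration = 250,
                          description = "inter-step interval at holding") {
  if (any(diff(amplitudes) <= 0))
    stop("step_protocol: 'amplitudes' must be strictly increasing", call. = FALSE)
  if (step_duration <= 0)
    stop("step_protocol: 'step_duration' must be > 0", call. = FALSE)
  structure(
    list(amplitudes = as.numeric(amplitudes),
         step_duration = as.numeric(step_duration),
         description = description),
    class = "step_protocol")
}

#' Stimulus amplitudes of a recording's sweeps
#' @param rec A [recording()].
#' @return Numeric vector, NA for sweeps without a stimulus.
#' @export
sweep_amplitudes <- function(rec) {
  vapply(rec$sweeps, function(s)
    if (is.null(s$stimulus)) NA_real_ else s$stimulus$amplitude, numeric(1))
}
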