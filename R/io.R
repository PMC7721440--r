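# On-disk dialect: a recording is a directory holding manifest.json plus one
# CSV per sweep (columns time_ms,value). Values are written with 17
# significant digits so that write -> read round-trips doubles exactly.

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a recording to disk
#'
#' Serialises a [recording()] as a directory containing `manifest.json` and
#' one `sweep_NNN.csv` (`time_ms,value`) per sweep. The written values
#' round-trip exactly through [read_recording()].
#'
#' @param rec A valid [recording()].
#' @param path Directory to create (or reuse) for the bundle.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "recording"))
    stop("write_recording: 'rec' must be a recording", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path))
    stop("write_recording: cannot create directory ", path, call. = FALSE)
  dt <- rec$sweeps[[1]]$dt
  mode <- rec$sweeps[[1]]$mode
  if (mode == "current_clamp") {
    post <- vapply(rec$sweeps, function(s) {
      if (is.null(s$stimulus)) return(Inf)
      sweep_span(s) - (s$stimulus$onset + s$stimulus$duration)
    }, numeric(1))
    if (any(post < 700))
      warning("write_recording: current-clamp sweep(s) retain < 700 ms after ",
              "the step; AHP measurement will not be possible", call. = FALSE)
  }
  sweep_meta <- lapply(seq_along(rec$sweeps), function(i) {
    s <- rec$sweeps[[i]]
    m <- list(file = sprintf("sweep_%03d.csv", i), n_samples = length(s$samples))
    if (!is.null(s$stimulus)) m$stimulus <- unclass(s$stimulus)
    m
  })
  manifest <- list(
    format = "patchstats-recording",
    version = 1L,
    cell_id = rec$cell_id, animal_id = rec$animal_id, group = rec$group,
    mode = mode, dt_ms = dt,
    units = list(voltage = "mV", current = "pA", time = "ms"),
    holding_potential_mv = rec$holding_potential,
    sweeps = sweep_meta)
  if (!is.null(rec$ra_series))
    manifest$ra_series <- list(time_s = rec$ra_series$time_s,
                               ra_mohm = rec$ra_series$ra_mohm)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  for (i in seq_along(rec$sweeps)) {
    s <- rec$sweeps[[i]]
    con <- file(file.path(path, sprintf("sweep_%03d.csv", i)), "w")
    writeLines("time_ms,value", con)
    writeLines(paste(fmt17(sweep_times(s)), fmt17(s$samples), sep = ","), con)
    close(con)
  }
  invisible(path)
}

#' Read a recording bundle from disk
#'
#' Reads a directory written by [write_recording()] (or assembled by hand in
#' the same dialect). Units are normalised to mV/pA/ms: a manifest declaring
#' `"V"` or `"nA"` has its samples rescaled on read.
#'
#' @param path Directory containing `manifest.json` and sweep CSVs.
#' @return A validated [recording()].
#' @export
read_recording <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!dir.exists(path) || !file.exists(mf))
    stop("read_recording: no recording bundle at ", path,
         " (missing manifest.json)", call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  required <- c("mode", "dt_ms", "sweeps", "group")
  missing <- setdiff(required, names(manifest))
  if (length(missing))
    stop("read_recording: manifest missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!identical(manifest$format, "patchstats-recording"))
    stop("read_recording: unknown dialect (format tag ",
         deparse(manifest$format), ")", call. = FALSE)
  mode <- manifest$mode
  dt <- as.numeric(manifest$dt_ms)
  scale <- unit_scale(manifest$units, mode)
  sweeps <- lapply(manifest$sweeps, function(m) {
    f <- file.path(path, m$file)
    if (!file.exists(f))
      stop("read_recording: sweep file missing: ", m$file, call. = FALSE)
    tab <- read.csv(f, colClasses = "numeric")
    if (!all(c("time_ms", "value") %in% names(tab)))
      stop("read_recording: sweep file ", m$file,
           " lacks time_ms,value columns", call. = FALSE)
    if (!is.null(m$n_samples) && nrow(tab) != m$n_samples)
      stop("read_recording: ", m$file, " is truncated (", nrow(tab),
           " of ", m$n_samples, " samples)", call. = FALSE)
    stim <- NULL
    if (!is.null(m$stimulus))
      stim <- stimulus_step(
        amplitude = as.numeric(m$stimulus$amplitude) * scale$current,
        onset = as.numeric(m$stimulus$onset),
        duration = as.numeric(m$stimulus$duration),
        holding_current = as.numeric(m$stimulus$holding_current) * scale$current)
    value_scale <- if (mode == "current_clamp") scale$voltage else scale$current
    sweep_trace(tab$value * value_scale, dt = dt, stimulus = stim, mode = mode)
  })
  ra <- NULL
  if (!is.null(manifest$ra_series))
    ra <- data.frame(time_s = unlist(manifest$ra_series$time_s),
                     ra_mohm = unlist(manifest$ra_series$ra_mohm))
  hp <- manifest$holding_potential_mv
  recording(sweeps,
            cell_id = manifest$cell_id %||% "cell",
            animal_id = manifest$animal_id %||% "animal",
            group = manifest$group,
            holding_potential = if (is.null(hp)) NA_real_ else as.numeric(hp),
            ra_series = ra)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scale factors taking declared units to the canonical mV / pA.
unit_scale <- function(units, mode) {
  v <- (units$voltage %||% "mV")
  i <- (units$current %||% "pA")
  vscale <- switch(v, mV = 1, V = 1000,
                   stop("read_recording: unsupported voltage unit '", v, "'",
                        call. = FALSE))
  iscale <- switch(i, pA = 1, nA = 1000,
                   stop("read_recording: unsupported current unit '", i, "'",
                        call. = FALSE))
  list(voltage = vscale, current = iscale)
}

#' Write a per-cell feature table as CSV
#'
#' @param rows A data.frame (possibly 0-row), or a list of named lists/vectors
#'   sharing one schema; one row per cell.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  df <- as_feature_frame(rows)
  out <- df
  for (j in seq_along(out))  # 17 significant digits: doubles round-trip
    if (is.double(out[[j]])) out[[j]] <- fmt17(out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

as_feature_frame <- function(rows) {
  if (is.data.frame(rows)) return(rows)
  if (!is.list(rows) || length(rows) == 0L)
    stop("write_feature_table: 'rows' must be a data.frame or non-empty list",
         call. = FALSE)
  schemas <- lapply(rows, names)
  if (any(vapply(schemas, function(s) !identical(s, schemas[[1]]), logical(1))))
    stop("write_feature_table: records do not share a single schema",
         call. = FALSE)
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) read.csv(path, stringsAsFactors = FALSE)
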