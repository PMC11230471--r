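#' Photometry session container
#'
#' A demodulated two-channel photometry recording: signal channel (465 nm
#' GCaMP8s or 560 nm rDA3m) plus the 405 nm UV isosbestic reference, on a
#' uniform time base, with optional event trains (TTL timestamps) and free-form
#' metadata. Traces are recorded at a nominal 1 kHz.
#'
#' Invariants enforced: strictly increasing time with constant step
#' `1/sampling_rate` (relative tolerance 1e-9), equal trace lengths, positive
#' sampling rate, finite fluorescence values, and event timestamps inside the
#' session.
#'
#' @param signal numeric, demodulated signal-channel fluorescence (a.u.).
#' @param reference numeric, demodulated isosbestic fluorescence (a.u.), same
#'   length as `signal`.
#' @param sampling_rate sampling rate in Hz.
#' @param sensor_kind `"gcamp"` or `"rdam"`.
#' @param time optional time vector in seconds; defaults to
#'   `(0:(n-1))/sampling_rate`.
#' @param events list of [event_train()] objects.
#' @param meta named list of free-form metadata (animal id, hemisphere, seed, ...).
#' @return An object of class `"photometry_session"`.
#' @export
photometry_session <- function(signal, reference, sampling_rate,
                               sensor_kind = c("gcamp", "rdam"),
                               time = NULL, events = list(), meta = list()) {
  sensor_kind <- match.arg(sensor_kind)
  n <- length(signal)
  if (is.null(time)) time <- seq(0, length.out = n, by = 1 / sampling_rate)
  s <- structure(
    list(time = as.numeric(time), signal = as.numeric(signal),
         reference = as.numeric(reference),
         sampling_rate = as.numeric(sampling_rate),
         sensor_kind = sensor_kind, events = events, meta = meta),
    class = "photometry_session")
  validate_session(s)
}

validate_session <- function(s) {
  n <- length(s$time)
  if (length(s$signal) != n || length(s$reference) != n) {
    stop("data error: signal/reference length must match time (",
         length(s$signal), ", ", length(s$reference), " vs ", n, ")")
  }
  if (!is.numeric(s$sampling_rate) || s$sampling_rate <= 0) {
    stop("sampling error: sampling_rate must be > 0")
  }
  check_uniform_time(s$time, s$sampling_rate)
  for (tr in list(signal = s$signal, reference = s$reference)) {
    bad <- which(!is.finite(tr))
    if (length(bad)) {
      stop("data error: non-finite fluorescence value at row ", bad[1])
    }
  }
  for (ev in s$events) {
    if (!inherits(ev, "event_train")) stop("events must be event_train objects")
    tmin <- s$time[1]
    tmax <- s$time[n]
    stamps <- c(ev$onsets, ev$offsets)
    if (length(stamps) && (min(stamps) < tmin || max(stamps) > tmax)) {
      stop("data error: event '", ev$label, "' has timestamps outside [",
           tmin, ", ", tmax, "]")
    }
  }
  invisible(s)
}

check_uniform_time <- function(time, sampling_rate, rel_tol = 1e-9) {
  n <- length(time)
  if (n < 2) return(invisible(time))
  dt <- diff(time)
  step <- 1 / sampling_rate
  dev <- max(abs(dt - step))
  if (dev > rel_tol * step) {
    stop(sprintf(paste0("sampling error: non-uniform time step ",
                        "(expected %.9g s, observed min %.9g / max %.9g / ",
                        "mean %.9g s)"),
                 step, min(dt), max(dt), mean(dt)))
  }
  invisible(time)
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf("<photometry_session> %s, %d samples @ %g Hz (%.1f s), %d event train(s)\n",
              x$sensor_kind, length(x$time), x$sampling_rate,
              length(x$time) / x$sampling_rate, length(x$events)))
  invisible(x)
}

#' Event train
#'
#' A labelled train of TTL-style event timestamps. Interval events carry
#' matched onsets and offsets; point events leave `offsets` empty. Onsets must
#' be sorted ascending, each offset must follow its onset, and intervals must
#' not overlap.
#'
#' @param label event label, e.g. `"stim"` or `"locomotion_onset"`.
#' @param onsets onset times (s).
#' @param offsets offset times (s), empty for point events.
#' @return An object of class `"event_train"`.
#' @export
event_train <- function(label, onsets, offsets = numeric(0)) {
  onsets <- as.numeric(onsets)
  offsets <- as.numeric(offsets)
  if (is.unsorted(onsets, strictly = FALSE)) {
    stop("event train '", label, "': onsets must be sorted ascending")
  }
  if (length(offsets)) {
    if (length(offsets) != length(onsets)) {
      stop("event train '", label, "': offsets must match onsets 1:1")
    }
    if (any(offsets <= onsets)) {
      stop("event train '", label, "': each offset must exceed its onset")
    }
    if (length(onsets) > 1 && any(onsets[-1] < offsets[-length(offsets)])) {
      stop("event train '", label, "': intervals must not overlap")
    }
  }
  structure(list(label = as.character(label), onsets = onsets,
                 offsets = offsets), class = "event_train")
}

#' Velocity trace
#'
#' Calibrated locomotion velocity (cm/s, signed; the sign encodes direction)
#' on a uniform time base, from a rotary encoder or video tracking.
#'
#' @param velocity velocity in cm/s.
#' @param sampling_rate Hz.
#' @param time optional time vector (s); defaults to a 0-based uniform grid.
#' @return An object of class `"velocity_trace"`.
#' @export
velocity_trace <- function(velocity, sampling_rate, time = NULL) {
  n <- length(velocity)
  if (is.null(time)) time <- seq(0, length.out = n, by = 1 / sampling_rate)
  if (length(time) != n) stop("data error: time/velocity length mismatch")
  bad <- which(!is.finite(velocity))
  if (length(bad)) stop("data error: non-finite velocity at row ", bad[1])
  check_uniform_time(time, sampling_rate)
  structure(list(time = as.numeric(time), velocity = as.numeric(velocity),
                 sampling_rate = as.numeric(sampling_rate)),
            class = "velocity_trace")
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("<velocity_trace> %d samples @ %g Hz (%.1f s)\n",
              length(x$time), x$sampling_rate, length(x$time) / x$sampling_rate))
  invisible(x)
}

companion_path <- function(path, suffix) {
  stem <- tools::file_path_sans_ext(path)
  paste0(stem, "_", suffix)
}

#' Read / write a photometry session as CSV
#'
#' The session CSV holds columns `time_s, signal, reference`; event trains go
#' to a companion `<stem>_events.csv` (`label, onset_s, offset_s`, blank
#' offset for point events) and metadata (including sensor kind and sampling
#' rate) to `<stem>_meta.json`. `read_session()` validates all session
#' invariants and names the offending column/row on failure. The pair
#' round-trips: a written session re-reads equal to the original.
#'
#' @param path session CSV path.
#' @param session a [photometry_session()].
#' @param sensor_kind fallback sensor kind when no meta companion exists.
#' @return `read_session()` returns a `photometry_session`; `write_session()`
#'   returns `path` invisibly.
#' @export
read_session <- function(path, sensor_kind = "gcamp") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  for (col in c("time_s", "signal", "reference")) {
    if (!col %in% names(df)) stop("schema error: missing required column '", col, "'")
  }
  meta <- list()
  sampling_rate <- NULL
  meta_path <- companion_path(path, "meta.json")
  if (file.exists(meta_path)) {
    m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    sensor_kind <- m$sensor_kind %||% sensor_kind
    sampling_rate <- m$sampling_rate
    meta <- m$meta %||% list()
  }
  if (is.null(sampling_rate)) {
    if (nrow(df) < 2) stop("sampling error: cannot infer sampling rate from < 2 rows")
    sampling_rate <- 1 / median(diff(df$time_s))
  }
  events <- list()
  ev_path <- companion_path(path, "events.csv")
  if (file.exists(ev_path)) {
    ev <- data.table::fread(ev_path, data.table = FALSE)
    for (col in c("label", "onset_s", "offset_s")) {
      if (!col %in% names(ev)) stop("schema error: missing required column '", col, "'")
    }
    events <- lapply(split(ev, factor(ev$label, levels = unique(ev$label))),
                     function(g) {
                       off <- g$offset_s
                       if (all(is.na(off))) off <- numeric(0)
                       event_train(g$label[1], g$onset_s, off)
                     })
    names(events) <- NULL
  }
  photometry_session(signal = df$signal, reference = df$reference,
                     sampling_rate = sampling_rate, sensor_kind = sensor_kind,
                     time = df$time_s, events = events, meta = meta)
}

#' @rdname read_session
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "photometry_session"))
  df <- data.frame(time_s = session$time, signal = session$signal,
                   reference = session$reference)
  data.table::fwrite(df, path)
  jsonlite::write_json(
    list(sensor_kind = session$sensor_kind,
         sampling_rate = session$sampling_rate, meta = session$meta),
    companion_path(path, "meta.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  if (length(session$events)) {
    ev <- do.call(rbind, lapply(session$events, function(e) {
      data.frame(label = e$label, onset_s = e$onsets,
                 offset_s = if (length(e$offsets)) e$offsets else NA_real_)
    }))
    data.table::fwrite(ev, companion_path(path, "events.csv"))
  }
  invisible(path)
}

#' Read / write a velocity trace as CSV
#'
#' Columns `time_s, velocity_cm_s`. Alternatively the CSV may hold raw encoder
#' volts (`time_s, volts`), in which case `read_velocity()` applies the
#' encoder calibration from `config`.
#'
#' @param path CSV path.
#' @param vel a [velocity_trace()].
#' @param config a [pipeline_config()] (used for encoder calibration).
#' @return `read_velocity()` returns a `velocity_trace`.
#' @export
read_velocity <- function(path, config = pipeline_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  if (!"time_s" %in% names(df)) stop("schema error: missing required column 'time_s'")
  if (nrow(df) < 2) stop("sampling error: need >= 2 rows")
  fs <- 1 / median(diff(df$time_s))
  if ("velocity_cm_s" %in% names(df)) {
    velocity_trace(df$velocity_cm_s, fs, time = df$time_s)
  } else if ("volts" %in% names(df)) {
    encoder_to_velocity(df$volts, sampling_rate = fs, time = df$time_s,
                        calibration_cms = config$calibration_cms,
                        calibration_volts = config$calibration_volts)
  } else {
    stop("schema error: missing required column 'velocity_cm_s' (or 'volts')")
  }
}

#' @rdname read_velocity
#' @export
write_velocity <- function(vel, path) {
  stopifnot(inherits(vel, "velocity_trace"))
  data.table::fwrite(data.frame(time_s = vel$time,
                                velocity_cm_s = vel$velocity), path)
  invisible(path)
}

#' Convert rotary-encoder voltage to velocity
#'
#' The treadmill rotary encoder emits a 0-3.3 V analog signal proportional to
#' belt speed, calibrated at 10 cm/s per 2.5 V; conversion is linear through
#' zero (4 cm/s per volt by default), and negative volts map to negative
#' (backward) velocity.
#'
#' @param volts encoder voltage time series.
#' @param sampling_rate Hz.
#' @param calibration_cms,calibration_volts the calibration point (speed in
#'   cm/s at a stated voltage).
#' @param time optional time vector (s).
#' @return A [velocity_trace()].
#' @export
encoder_to_velocity <- function(volts, sampling_rate,
                                calibration_cms = 10, calibration_volts = 2.5,
                                time = NULL) {
  if (!all(is.finite(volts))) {
    stop("data error: non-finite voltage at row ", which(!is.finite(volts))[1])
  }
  if (calibration_cms <= 0 || calibration_volts <= 0) {
    stop("parameter error: calibration speed and voltage must be > 0")
  }
  velocity_trace(volts * (calibration_cms / calibration_volts),
                 sampling_rate, time = time)
}
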