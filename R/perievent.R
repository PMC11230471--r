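#' Decimate a normalized trace
#'
#' Anti-aliased decimation to a lower rate (default 100 Hz) for peri-event
#' analysis: a zero-phase Butterworth low-pass at 45% of the target Nyquist-
#' doubling rate, then every `fs/target`-th sample. 1 kHz is needless for
#' second-scale indicator kernels; decimation keeps the peri-event matrices
#' small without shifting timing (zero-phase).
#'
#' @param norm a `"normalized_trace"`.
#' @param target_hz target rate; must divide the native rate.
#' @return A `"normalized_trace"` on the coarser grid.
#' @export
decimate_trace <- function(norm, target_hz = 100) {
  stopifnot(inherits(norm, "normalized_trace"))
  fs <- norm$sampling_rate
  if (target_hz >= fs) return(norm)
  factor <- fs / target_hz
  if (abs(factor - round(factor)) > 1e-9) {
    stop("parameter error: target rate must divide the native rate")
  }
  factor <- round(factor)
  idx <- seq(1, length(norm$time), by = factor)
  lp <- function(x) if (is.null(x)) NULL else
    zero_phase_lowpass(x, 0.45 * target_hz, 4, fs)[idx]
  out <- norm
  out$time <- norm$time[idx]
  out$sampling_rate <- target_hz
  for (f in c("dff", "zscore", "transformed_reference", "f0_signal",
              "f0_reference", "prenorm_signal", "prenorm_reference")) {
    out[[f]] <- lp(norm[[f]])
  }
  out
}

#' Align a trace to events
#'
#' Extracts one row per event: the trace on a uniform relative-time grid
#' `[window[1], window[2]]` around each event time (0 = event). Events whose
#' full window does not fit inside the session are dropped and counted in
#' `n_dropped`. With zero usable events an empty matrix with `empty = TRUE`
#' is returned rather than an error.
#'
#' @param norm a `"normalized_trace"`.
#' @param events event times in seconds.
#' @param window `c(pre, post)` in seconds, `pre < 0 < post` typically.
#' @param value which trace to align: `"zscore"` (locomotion analyses) or
#'   `"dff"` (stimulation dopamine metrics).
#' @param event_kind label stored with the matrix.
#' @return A list of class `"perievent_matrix"`: `values` (trials x time),
#'   `rel_time`, `event_kind`, `trial_ids`, `n_dropped`, `empty`.
#' @export
align_events <- function(norm, events, window = c(-1, 1),
                         value = c("zscore", "dff"),
                         event_kind = "event") {
  stopifnot(inherits(norm, "normalized_trace"))
  value <- match.arg(value)
  x <- norm[[value]]
  t0 <- norm$time[1]
  t_end <- norm$time[length(norm$time)]
  fs <- norm$sampling_rate
  rel <- seq(window[1], window[2], by = 1 / fs)
  ok <- events + window[1] >= t0 - 1e-9 & events + window[2] <= t_end + 1e-9
  usable <- events[ok]
  if (!length(usable)) {
    return(structure(list(values = matrix(numeric(0), 0, length(rel)),
                          rel_time = rel, event_kind = event_kind,
                          trial_ids = integer(0), n_dropped = sum(!ok),
                          empty = TRUE),
                     class = "perievent_matrix"))
  }
  rows <- t(vapply(usable, function(ev) {
    idx <- round((ev + rel - t0) * fs) + 1L
    idx <- pmin(pmax(idx, 1L), length(x))
    x[idx]
  }, numeric(length(rel))))
  structure(list(values = rows, rel_time = rel, event_kind = event_kind,
                 trial_ids = which(ok), n_dropped = sum(!ok), empty = FALSE),
            class = "perievent_matrix")
}

#' @export
print.perievent_matrix <- function(x, ...) {
  cat(sprintf("<perievent_matrix> %s: %d trial(s) x %d samples, rel time [%g, %g] s (%d dropped)\n",
              x$event_kind, nrow(x$values), length(x$rel_time),
              min(x$rel_time), max(x$rel_time), x$n_dropped))
  invisible(x)
}

#' Timing of maximum event-aligned activity
#'
#' Timestamp of the maximum of the session-mean aligned trace (and of each
#' trial) within a closed search window, default 1 s before to 1 s after the
#' event. Ties break to the earliest time.
#'
#' @param mat a `"perievent_matrix"`.
#' @param search `c(lo, hi)` in seconds, within the matrix's time span.
#' @return A list: `t_max` (session-mean timing, s), `per_trial` (one timing
#'   per row).
#' @export
max_timing <- function(mat, search = c(-1, 1)) {
  stopifnot(inherits(mat, "perievent_matrix"))
  if (mat$empty) return(list(t_max = NA_real_, per_trial = numeric(0)))
  sel <- mat$rel_time >= search[1] - 1e-12 & mat$rel_time <= search[2] + 1e-12
  if (!any(sel)) stop("parameter error: search window outside the matrix span")
  tt <- mat$rel_time[sel]
  mean_trace <- colMeans(mat$values[, sel, drop = FALSE])
  list(t_max = tt[which.max(mean_trace)],
       per_trial = tt[apply(mat$values[, sel, drop = FALSE], 1, which.max)])
}

#' Activity slope around an event
#'
#' Ordinary-least-squares slope of the session-mean aligned activity against
#' relative time over a half-open window, default 0.5 s before to 0.5 s after
#' the event (units: activity per second; z-units/s for z-scored input).
#'
#' @param mat a `"perievent_matrix"`.
#' @param window `c(lo, hi)` in seconds.
#' @return A list: `slope` (session-mean), `per_trial`.
#' @export
offset_slope <- function(mat, window = c(-0.5, 0.5)) {
  stopifnot(inherits(mat, "perievent_matrix"))
  if (mat$empty) return(list(slope = NA_real_, per_trial = numeric(0)))
  sel <- mat$rel_time >= window[1] - 1e-12 & mat$rel_time < window[2] - 1e-12
  if (sum(sel) < 3) stop("parameter error: fewer than 3 samples in the window")
  tt <- mat$rel_time[sel]
  fit_slope <- function(y) unname(coef(lm(y ~ tt))[2])
  list(slope = fit_slope(colMeans(mat$values[, sel, drop = FALSE])),
       per_trial = apply(mat$values[, sel, drop = FALSE], 1, fit_slope))
}

#' Stimulation-locked dopamine amplitude metrics
#'
#' Per stimulation trial, on the dF/F trace of an rDA3m session: the baseline
#' is the average dF/F in the 2 s preceding stimulation onset; the reduction
#' amplitude is the average over the 0.2 s before stimulus offset, the onset
#' peak over 0.35-0.45 s after onset, and the post-stimulus amplitude over
#' 3-8 s after offset — each reported relative to the baseline. With the
#' default `window_minus_baseline` convention sustained suppression is
#' negative and the onset peak positive (matching the one-sample left-/right-
#' tailed tests applied to them); `baseline_minus_window` gives the literal
#' opposite sign. All windows are half-open `[a, b)`. Trials whose windows
#' extend past the session are dropped and counted.
#'
#' @param norm a `"normalized_trace"` from [normalize_rdam()].
#' @param stim an [event_train()] with onsets and offsets.
#' @param config a [pipeline_config()] (analysis windows and sign convention).
#' @return A data.frame of class `"stim_metrics"`: one row per usable trial
#'   with `trial, duration_s, onset_s, offset_s, baseline_dff, reduction_amp,
#'   peak_amp, post_stim_amp`; attribute `n_dropped`.
#' @export
stim_metrics <- function(norm, stim, config = pipeline_config()) {
  stopifnot(inherits(norm, "normalized_trace"), inherits(stim, "event_train"))
  if (norm$chain != "rdam") {
    stop("precondition error: stim_metrics requires the rdam chain")
  }
  if (!length(stim$offsets)) {
    stop("precondition error: stim events must be intervals (onset + offset)")
  }
  t <- norm$time
  x <- norm$dff
  t0 <- t[1]
  t_end <- t[length(t)]
  sgn <- if (config$stim_sign_convention == "window_minus_baseline") 1 else -1
  rows <- lapply(seq_along(stim$onsets), function(i) {
    on <- stim$onsets[i]
    off <- stim$offsets[i]
    lo <- on + config$stim_baseline_s[1]
    hi <- off + config$stim_post_s[2]
    if (lo < t0 - 1e-9 || hi > t_end + 1e-9) return(NULL)
    base <- window_mean(x, t, on + config$stim_baseline_s[1],
                        on + config$stim_baseline_s[2])
    data.frame(
      trial = i, duration_s = off - on, onset_s = on, offset_s = off,
      baseline_dff = base,
      reduction_amp = sgn * (window_mean(x, t, off + config$stim_reduction_s[1],
                                         off + config$stim_reduction_s[2]) - base),
      peak_amp = sgn * (window_mean(x, t, on + config$stim_peak_s[1],
                                    on + config$stim_peak_s[2]) - base),
      post_stim_amp = sgn * (window_mean(x, t, off + config$stim_post_s[1],
                                         off + config$stim_post_s[2]) - base))
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(trial = integer(0), duration_s = numeric(0),
               onset_s = numeric(0), offset_s = numeric(0),
               baseline_dff = numeric(0), reduction_amp = numeric(0),
               peak_amp = numeric(0), post_stim_amp = numeric(0))
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("stim_metrics", "data.frame")
  out
}

#' Session-level locomotion peri-event statistics
#'
#' Convenience wrapper running the locomotion analysis for one session:
#' segment the treadmill velocity, align the z-scored activity on
#' non-excluded movement-bout onsets and offsets, and compute the timing of
#' maximum activity around each and the activity slope around offset.
#'
#' @param norm a `"normalized_trace"` (gcamp chain), already decimated if
#'   desired.
#' @param bout_set a `"bout_set"` from [segment_treadmill()].
#' @param config a [pipeline_config()].
#' @return A list: `onset` / `offset` (each a `"perievent_matrix"`),
#'   `t_max_onset`, `t_max_offset`, `offset_slope` (session-mean values).
#' @export
locomotion_perievent <- function(norm, bout_set, config = pipeline_config()) {
  stopifnot(inherits(bout_set, "bout_set"))
  b <- bout_set$bouts
  b <- b[b$kind == "movement" & !b$excluded, , drop = FALSE]
  w <- config$timing_search_s
  on_mat <- align_events(norm, b$onset_s, window = w, value = "zscore",
                         event_kind = "locomotion_onset")
  off_mat <- align_events(norm, b$offset_s, window = w, value = "zscore",
                          event_kind = "locomotion_offset")
  list(onset = on_mat, offset = off_mat,
       t_max_onset = max_timing(on_mat, config$timing_search_s)$t_max,
       t_max_offset = max_timing(off_mat, config$timing_search_s)$t_max,
       offset_slope = if (off_mat$empty) NA_real_ else
         offset_slope(off_mat, config$slope_window_s)$slope)
}
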