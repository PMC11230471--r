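# Sample i covers the half-open interval [t_i, t_i + dt). A run of samples
# a..b therefore maps to the interval [t_a, t_b + dt).
runs_to_intervals <- function(runs, time, dt) {
  data.frame(onset_s = time[runs$start], offset_s = time[runs$end] + dt)
}

new_bout_set <- function(bouts, session_duration_s, kind_default, meta = list()) {
  if (is.null(bouts) || nrow(bouts) == 0) {
    bouts <- data.frame(kind = character(0), onset_s = numeric(0),
                        offset_s = numeric(0), duration_s = numeric(0),
                        mean_velocity_cm_s = numeric(0), excluded = logical(0))
  }
  bouts <- bouts[order(bouts$onset_s), , drop = FALSE]
  rownames(bouts) <- NULL
  structure(list(bouts = bouts, session_duration_s = session_duration_s,
                 meta = meta),
            class = "bout_set")
}

#' @export
print.bout_set <- function(x, ...) {
  tab <- table(x$bouts$kind[!x$bouts$excluded])
  cat(sprintf("<bout_set> %.1f s session: %s (+%d excluded)\n",
              x$session_duration_s,
              if (length(tab)) paste(names(tab), tab, sep = "=", collapse = ", ")
              else "no bouts",
              sum(x$bouts$excluded)))
  invisible(x)
}

#' Segment a treadmill velocity trace into movement and rest bouts
#'
#' Movement versus rest is defined by a 0.25 cm/s threshold on the velocity
#' trace (absolute velocity by default). Sub-threshold runs count as rest only
#' if they last longer than 0.8 s; shorter dips are absorbed into the
#' surrounding movement, so they neither split a bout nor count as rest.
#' Movement periods shorter than 0.5 s or with mean velocity below 0.5 cm/s
#' are excluded from analysis: they are retained in the output with
#' `excluded = TRUE` so downstream peri-event analysis can skip them audibly.
#' A bout's initiation time is the threshold crossing that ends a rest period
#' and its termination the crossing followed by a rest period; all intervals
#' are half-open `[onset, offset)`, and a sample exactly at the threshold
#' counts as sub-threshold.
#'
#' @param velocity a [velocity_trace()].
#' @param config a [pipeline_config()] (threshold and duration rules;
#'   `velocity_mode` selects absolute or signed thresholding).
#' @return A `"bout_set"` whose movement, rest and excluded intervals
#'   partition the session.
#' @export
segment_treadmill <- function(velocity, config = pipeline_config()) {
  stopifnot(inherits(velocity, "velocity_trace"))
  v <- if (config$velocity_mode == "absolute") abs(velocity$velocity)
       else velocity$velocity
  n <- length(v)
  dt <- 1 / velocity$sampling_rate
  dur <- n * dt
  if (n == 0) return(new_bout_set(NULL, 0, "movement"))
  above <- v > config$treadmill_threshold_cms
  if (!any(above)) {
    bouts <- data.frame(kind = "rest", onset_s = velocity$time[1],
                        offset_s = velocity$time[1] + dur, duration_s = dur,
                        mean_velocity_cm_s = mean(v), excluded = FALSE)
    return(new_bout_set(bouts, dur, "rest"))
  }
  # below-threshold runs are rest only when >= min_rest; shorter interior
  # dips are absorbed into movement
  below_runs <- logical_runs(!above)
  is_move <- above
  if (nrow(below_runs)) {
    # rest only when strictly longer than min_rest ("longer than 0.8 s")
    short <- (below_runs$end - below_runs$start + 1L) * dt <=
      config$treadmill_min_rest_s
    for (i in which(short)) {
      is_move[below_runs$start[i]:below_runs$end[i]] <- TRUE
    }
  }
  move_runs <- logical_runs(is_move)
  rest_runs <- logical_runs(!is_move)
  mk <- function(runs, kind) {
    if (nrow(runs) == 0) return(NULL)
    iv <- runs_to_intervals(runs, velocity$time, dt)
    iv$kind <- kind
    iv$duration_s <- iv$offset_s - iv$onset_s
    iv$mean_velocity_cm_s <- vapply(seq_len(nrow(runs)), function(i) {
      mean(v[runs$start[i]:runs$end[i]])
    }, numeric(1))
    iv
  }
  mv <- mk(move_runs, "movement")
  mv$excluded <- mv$duration_s < config$treadmill_min_move_s |
    mv$mean_velocity_cm_s < config$treadmill_min_move_velocity_cms
  rs <- mk(rest_runs, "rest")
  if (!is.null(rs)) rs$excluded <- FALSE
  bouts <- rbind(mv[, c("kind", "onset_s", "offset_s", "duration_s",
                        "mean_velocity_cm_s", "excluded")],
                 if (!is.null(rs))
                   rs[, c("kind", "onset_s", "offset_s", "duration_s",
                          "mean_velocity_cm_s", "excluded")])
  new_bout_set(bouts, dur, "movement",
               meta = list(velocity_mode = config$velocity_mode))
}

# Shared run/merge/minimum-duration logic for open-field bouts: runs where
# `flag` holds, gaps shorter than min_separation merged, merged runs not
# exceeding min_duration dropped.
segment_runs_merge <- function(flag, time, sampling_rate, values, kind,
                               min_duration_s, min_separation_s) {
  n <- length(flag)
  dt <- 1 / sampling_rate
  dur <- n * dt
  runs <- logical_runs(flag)
  if (nrow(runs) == 0) return(new_bout_set(NULL, dur, kind))
  # merge runs separated by gaps < min_separation
  if (nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- (runs$start[i] - merged$end[nrow(merged)] - 1L) * dt
      if (gap < min_separation_s) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  iv <- runs_to_intervals(runs, time, dt)
  iv$duration_s <- iv$offset_s - iv$onset_s
  keep <- iv$duration_s > min_duration_s
  runs <- runs[keep, , drop = FALSE]
  iv <- iv[keep, , drop = FALSE]
  if (nrow(iv) == 0) return(new_bout_set(NULL, dur, kind))
  bouts <- data.frame(
    kind = kind, onset_s = iv$onset_s, offset_s = iv$offset_s,
    duration_s = iv$duration_s,
    mean_velocity_cm_s = vapply(seq_len(nrow(runs)), function(i) {
      mean(values[runs$start[i]:runs$end[i]])
    }, numeric(1)),
    excluded = FALSE)
  new_bout_set(bouts, dur, kind)
}

#' Segment open-field ambulation bouts
#'
#' Ambulation bouts are periods of movement above 2 cm/s lasting longer than
#' 0.5 s and separated by more than 0.5 s: sub-threshold gaps shorter than
#' the separation minimum merge adjacent runs, and merged runs not exceeding
#' the duration minimum are dropped.
#'
#' @param velocity a [velocity_trace()] (tracking-derived; resample to a
#'   uniform base first if needed).
#' @param config a [pipeline_config()].
#' @return A `"bout_set"` of ambulation bouts.
#' @export
segment_openfield_ambulation <- function(velocity, config = pipeline_config()) {
  stopifnot(inherits(velocity, "velocity_trace"))
  v <- if (config$velocity_mode == "absolute") abs(velocity$velocity)
       else velocity$velocity
  segment_runs_merge(v > config$ambulation_threshold_cms, velocity$time,
                     velocity$sampling_rate, v, "ambulation",
                     config$ambulation_min_duration_s,
                     config$ambulation_min_separation_s)
}

#' Segment immobility bouts from an activity series
#'
#' Immobility bouts are periods where the activity measure (percent pixel
#' change per video frame) stays below 2%, lasting longer than 0.5 s and
#' separated by more than 0.5 s — the ambulation logic with the inequality
#' inverted. When no pixel-change series is available a velocity-based proxy
#' (absolute velocity below a configured threshold) may be passed instead;
#' flag this in `proxy` so it is recorded in the output metadata.
#'
#' @param activity percent-change-per-frame series (or proxy series).
#' @param sampling_rate series rate in Hz (video frame rate, typically 15).
#' @param config a [pipeline_config()].
#' @param proxy set `TRUE` when `activity` is a velocity-derived stand-in.
#' @return A `"bout_set"` of immobility bouts.
#' @export
segment_immobility <- function(activity, sampling_rate,
                               config = pipeline_config(), proxy = FALSE) {
  if (!all(is.finite(activity))) {
    stop("data error: non-finite activity at row ",
         which(!is.finite(activity))[1])
  }
  time <- seq(0, length.out = length(activity), by = 1 / sampling_rate)
  bs <- segment_runs_merge(activity < config$immobility_activity_threshold_pct,
                           time, sampling_rate, activity, "immobility",
                           config$immobility_min_duration_s,
                           config$immobility_min_separation_s)
  bs$meta$activity_proxy <- proxy
  bs
}

#' Summarize a bout set
#'
#' Per-kind summaries over an analysis window: bout frequency (count per
#' second of window), mean bout duration, mean of per-bout mean velocities,
#' and percent of window time spent in the kind. Bouts are clipped at the
#' window edges; excluded bouts are not counted.
#'
#' @param bout_set a `"bout_set"`.
#' @param window `c(start, end)` in seconds, or `NULL` for the whole session.
#' @param kind which bout kind to summarize (default: the set's non-rest
#'   kind, or `"rest"` if that is all there is).
#' @return A one-row data.frame: `kind, n_bouts, frequency_hz,
#'   mean_duration_s, mean_velocity_cm_s, percent_time`.
#' @export
bout_summaries <- function(bout_set, window = NULL, kind = NULL) {
  stopifnot(inherits(bout_set, "bout_set"))
  if (is.null(window)) window <- c(0, bout_set$session_duration_s)
  if (length(window) != 2 || window[2] <= window[1]) {
    stop("parameter error: window must be an increasing pair")
  }
  b <- bout_set$bouts
  b <- b[!b$excluded, , drop = FALSE]
  if (is.null(kind)) {
    kinds <- setdiff(unique(b$kind), "rest")
    kind <- if (length(kinds)) kinds[1] else "rest"
  }
  b <- b[b$kind == kind, , drop = FALSE]
  on <- pmax(b$onset_s, window[1])
  off <- pmin(b$offset_s, window[2])
  keep <- off > on
  on <- on[keep]
  off <- off[keep]
  wlen <- window[2] - window[1]
  data.frame(
    kind = kind,
    n_bouts = length(on),
    frequency_hz = length(on) / wlen,
    mean_duration_s = if (length(on)) mean(off - on) else NA_real_,
    mean_velocity_cm_s = if (length(on)) mean(b$mean_velocity_cm_s[keep])
                         else NA_real_,
    percent_time = 100 * sum(off - on) / wlen)
}
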