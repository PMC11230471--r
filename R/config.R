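#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one flat list, with the
#' published analysis values as defaults. The configuration serializes to and
#' from YAML byte-identically (round-trip), so a config file fully documents a
#' run.
#'
#' Defaults:
#' * `f0_window_s = 5`, `f0_percentile = 10` — sliding-percentile baseline.
#' * `ref_corner_hz = 3`, `ref_filter_order = 2` — zero-phase Butterworth
#'   low-pass applied to the pre-normalized reference.
#' * `ransac_iterations = 100`, `ransac_min_samples = 2`,
#'   `ransac_residual_threshold = NA` (NA = 1 raw median absolute deviation of
#'   the ordinary-least-squares residuals), `ransac_seed = 42`.
#' * `qc_min_max_dff_percent = 1.5`, `qc_max_reference_corr = 0.6` — inclusion
#'   gate: maximum dF/F (percent) must exceed 1.5 and the Pearson correlation
#'   between the GCaMP trace and the transformed UV reference must stay below
#'   0.6; `qc_corr_operand = "prenorm"` correlates the pre-subtraction
#'   normalized signal with the UV dF/F (see [qc_gate()] for why), `"dff"`
#'   the final dF/F.
#' * `baseline_epsilon_rel = 1e-9` — divisor guard, relative to the session
#'   median of the baseline.
#' * Treadmill bouts: `treadmill_threshold_cms = 0.25`,
#'   `treadmill_min_move_s = 0.5`, `treadmill_min_move_velocity_cms = 0.5`,
#'   `treadmill_min_rest_s = 0.8`; open-field ambulation:
#'   `ambulation_threshold_cms = 2`, `ambulation_min_duration_s = 0.5`,
#'   `ambulation_min_separation_s = 0.5`; immobility:
#'   `immobility_activity_threshold_pct = 2`, with the same duration/separation
#'   minima.
#' * `velocity_mode = "absolute"` — bout detection thresholds the absolute
#'   velocity by default (the encoder reports speed and direction; the analyses
#'   use speed). Set `"signed"` to threshold the signed trace.
#' * Peri-event: `perievent_rate_hz = 100` (decimation target),
#'   `timing_search_s = c(-1, 1)`, `slope_window_s = c(-0.5, 0.5)`; stimulation
#'   windows `stim_baseline_s = c(-2, 0)` (pre-onset),
#'   `stim_reduction_s = c(-0.2, 0)` (pre-offset),
#'   `stim_peak_s = c(0.35, 0.45)` (post-onset), `stim_post_s = c(3, 8)`
#'   (post-offset). `stim_sign_convention = "window_minus_baseline"` makes
#'   sustained suppression negative and the onset peak positive; the literal
#'   `"baseline_minus_window"` reading is available.
#' * `calibration_cms = 10`, `calibration_volts = 2.5` — rotary-encoder
#'   velocity calibration (10 cm/s at 2.5 V).
#' * `seed = 1` — RNG seed for synthetic data and RANSAC sampling.
#'
#' @param ... named overrides of the defaults.
#' @return A named list with class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    f0_window_s = 5,
    f0_percentile = 10,
    ref_corner_hz = 3,
    ref_filter_order = 2L,
    ransac_iterations = 100L,
    ransac_min_samples = 2L,
    ransac_residual_threshold = NA_real_,
    ransac_seed = 42L,
    qc_min_max_dff_percent = 1.5,
    qc_max_reference_corr = 0.6,
    qc_corr_operand = "prenorm",
    baseline_epsilon_rel = 1e-9,
    treadmill_threshold_cms = 0.25,
    treadmill_min_move_s = 0.5,
    treadmill_min_move_velocity_cms = 0.5,
    treadmill_min_rest_s = 0.8,
    ambulation_threshold_cms = 2,
    ambulation_min_duration_s = 0.5,
    ambulation_min_separation_s = 0.5,
    immobility_activity_threshold_pct = 2,
    immobility_min_duration_s = 0.5,
    immobility_min_separation_s = 0.5,
    velocity_mode = "absolute",
    perievent_rate_hz = 100,
    timing_search_s = c(-1, 1),
    slope_window_s = c(-0.5, 0.5),
    stim_baseline_s = c(-2, 0),
    stim_reduction_s = c(-0.2, 0),
    stim_peak_s = c(0.35, 0.45),
    stim_post_s = c(3, 8),
    stim_sign_convention = "window_minus_baseline",
    calibration_cms = 10,
    calibration_volts = 2.5,
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    }
    cfg <- modifyList(cfg, overrides)
  }
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg)
  chk(cfg$f0_window_s > 0, "f0_window_s must be > 0")
  chk(cfg$f0_percentile > 0 && cfg$f0_percentile < 100,
      "f0_percentile must be in (0, 100)")
  chk(cfg$ref_corner_hz > 0, "ref_corner_hz must be > 0")
  chk(cfg$ref_filter_order >= 1, "ref_filter_order must be >= 1")
  chk(cfg$ransac_iterations >= 1, "ransac_iterations must be >= 1")
  chk(cfg$ransac_min_samples >= 2, "ransac_min_samples must be >= 2")
  chk(is.na(cfg$ransac_residual_threshold) ||
        cfg$ransac_residual_threshold >= 0,
      "ransac_residual_threshold must be NA or >= 0")
  chk(cfg$qc_min_max_dff_percent >= 0, "qc_min_max_dff_percent must be >= 0")
  chk(cfg$qc_max_reference_corr >= -1 && cfg$qc_max_reference_corr <= 1,
      "qc_max_reference_corr must be in [-1, 1]")
  chk(cfg$qc_corr_operand %in% c("prenorm", "dff"),
      "qc_corr_operand must be 'prenorm' or 'dff'")
  for (f in c("treadmill_threshold_cms", "treadmill_min_move_s",
              "treadmill_min_move_velocity_cms", "treadmill_min_rest_s",
              "ambulation_threshold_cms", "ambulation_min_duration_s",
              "ambulation_min_separation_s",
              "immobility_activity_threshold_pct",
              "immobility_min_duration_s", "immobility_min_separation_s",
              "perievent_rate_hz", "calibration_cms", "calibration_volts")) {
    chk(cfg[[f]] > 0, paste(f, "must be > 0"))
  }
  chk(cfg$velocity_mode %in% c("absolute", "signed"),
      "velocity_mode must be 'absolute' or 'signed'")
  chk(cfg$stim_sign_convention %in%
        c("window_minus_baseline", "baseline_minus_window"),
      "stim_sign_convention must name a subtraction order")
  for (f in c("timing_search_s", "slope_window_s", "stim_baseline_s",
              "stim_reduction_s", "stim_peak_s", "stim_post_s")) {
    w <- cfg[[f]]
    chk(length(w) == 2 && w[1] < w[2], paste(f, "must be an increasing pair"))
  }
  invisible(cfg)
}

#' Write / read a pipeline configuration as YAML
#'
#' `read_config()` applies the file's values on top of the defaults, so a
#' partial file is valid; `write_config()` writes every field. Writing the
#' result of `read_config()` reproduces the file byte-identically.
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  vals$ransac_residual_threshold <-
    as.numeric(vals$ransac_residual_threshold %||% NA_real_)
  do.call(pipeline_config, vals)
}
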